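lesion,sparse-hard,sparse-semisoft,sparse-soft,dense-hard,dense-semisoft,dense-soft
HE,93.1,97.8,95.5,94.5,95.6,95.6
RL,92.3,93.5,87.1,89.1,90.6,89.9
CS,82.1,90.8,84.9,84.5,90.4,90.3
D,66.5,82.8,62.6,84.1,82.5,75.5
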