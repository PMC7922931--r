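strain,A. radiobacter AR39,A. brasilense ATCC 29710,A. brasilense NCCB 78036,A. chroococcum DSM 2286,A. chroococcum LS132,A. chroococcum LS136,A. vinelandii DSM 2289,Bacillus sp. BV84,B. amyloliquefaciens BA41,B. amyloliquefaciens LMG 9814,B. licheniformis PS141,B. pumilus LMG 24415,B. subtilis LMG 23370,B. subtilis LMG 24418,B. ambifaria LMG 11351,B. ambifaria MCI 7,K. pastoris PP59,P. tropica MDIIIAzo225,Pseudomonas sp. PN53,P. fluorescens DR54,P. granadensis A23/T3c,R. aquatilis BB23/T4d,R. terrigena FS152
A. radiobacter AR39,,,,,,,,,,,,,,,,,,,,,,,
A. brasilense ATCC 29710,+,,,,,,,,,,,,,,,,,,,,,,
A. brasilense NCCB 78036,+,+,,,,,,,,,,,,,,,,,,,,,
A. chroococcum DSM 2286,-,-,-,,,,,,,,,,,,,,,,,,,,
A. chroococcum LS132,+,+,+,-,,,,,,,,,,,,,,,,,,,
A. chroococcum LS136,+,+,+,-,+,,,,,,,,,,,,,,,,,,
A. vinelandii DSM 2289,+,+,+,-,+,+,,,,,,,,,,,,,,,,,
Bacillus sp. BV84,+,-,+,+,+,+,+,,,,,,,,,,,,,,,,
B. amyloliquefaciens BA41,+,-,+,+,+,+,+,+,,,,,,,,,,,,,,,
B. amyloliquefaciens LMG 9814,+,nc,+,-,+,+,+,+,+,,,,,,,,,,,,,,
B. licheniformis PS141,+,+,+,-,+,+,+,-,-,-,,,,,,,,,,,,,
B. pumilus LMG 24415,+,+,+,+,+,+,+,-,-,-,-,,,,,,,,,,,,
B. subtilis LMG 23370,+,+,+,+,+,+,+,-,-,-,+,-,,,,,,,,,,,
B. subtilis LMG 24418,+,+,+,+,+,+,+,-,-,-,+,-,-,,,,,,,,,,
B. ambifaria LMG 11351,+,+,+,-,+,+,+,+,+,+,+,+,+,-,,,,,,,,,
B. ambifaria MCI 7,+,-,+,-,+,+,+,+,+,+,+,+,+,+,+,,,,,,,,
K. pastoris PP59,+,+,+,-,+,+,+,+,+,+,+,+,+,+,+,nc,,,,,,,
P. tropica MDIIIAzo225,+,+,+,-,+,+,+,+,+,nc,+,+,nc,+,+,+,+,,,,,,
Pseudomonas sp. PN53,+,+,+,+,+,+,-,-,+,+,+,+,+,+,+,+,+,+,,,,,
P. fluorescens DR54,+,+,+,-,+,+,+,+,+,+,+,+,+,+,+,+,+,+,nc,,,,
P. granadensis A23/T3c,+,+,+,-,+,+,+,+,+,+,+,+,+,-,+,+,+,+,+,+,,,
R. aquatilis BB23/T4d,+,+,+,-,+,+,+,+,+,+,+,+,+,+,+,+,+,+,+,+,+,,
R. terrigena FS152,+,+,+,-,+,+,+,+,+,+,+,+,+,+,+,+,+,+,+,+,+,+,
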