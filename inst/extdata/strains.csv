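name,aliases,kingdom,properties,extra_functions,selected,notes
Agrobacterium radiobacter AR39,A. radiobacter AR39|Agrobacterium radiobacter AR 39,bacterium,Biocontrol/PGP,,TRUE,
Azospirillum brasilense ATCC 29710,A. brasilense ATCC 29710|Azospirillum brasilense ATTC 29710|Azotobacter brasilense ATCC 29710,bacterium,N-fixation,,TRUE,genus occasionally misprinted as Azotobacter
Azospirillum brasilense NCCB 78036,A. brasilense NCCB 78036,bacterium,N-fixation,,TRUE,
Azotobacter chroococcum DSM 2286,A. chroococcum DSM 2286,bacterium,N-fixation,,TRUE,
Azotobacter chroococcum LS132,A. chroococcum LS132,bacterium,N-fixation,,TRUE,
Azotobacter chroococcum LS163,A. chroococcum LS163|A. chroococcum LS136|Azotobacter chroococcum LS136,bacterium,N-fixation,,TRUE,strain code printed both as LS163 and LS136; recorded as one strain (ambiguity flagged)
Azotobacter vinelandii DSM 2289,A. vinelandii DSM 2289,bacterium,"Siderophore production, N-fixation",,TRUE,
Bacillus sp. BV84,Bacillus sp BV84|B. sp. BV84,bacterium,Biocontrol/PGP,,TRUE,
Bacillus amyloliquefaciens BA41,B. amyloliquefaciens BA41,bacterium,Biocontrol/PGP,,TRUE,
Bacillus amyloliquefaciens LMG 9814,B. amyloliquefaciens LMG 9814,bacterium,"Alpha-amylase, alpha-glucosidase, iso-amylase production",,TRUE,
Bacillus licheniformis PS141,B. licheniformis PS141|Bacillus licheniformis PS 141,bacterium,Indole acetic acid (IAA) production,,TRUE,
Bacillus pumilus LMG 24415,B. pumilus LMG 24415,bacterium,PGP,,TRUE,
Bacillus subtilis LMG 23370,B. subtilis LMG 23370,bacterium,Biocontrol/PGP,,TRUE,
Bacillus subtilis LMG 24418,B. subtilis LMG 24418,bacterium,PGP,,TRUE,
Burkholderia ambifaria LMG 11351,B. ambifaria LMG 11351|Burkholderia ambifaria PHP7|Burkholderia ambifaria PHP7/LMG 11351|Burkholderia cepacia PHP7,bacterium,PGP,,TRUE,
Burkholderia ambifaria MCI 7,B. ambifaria MCI 7|Burkholderia cepacia MCI 7,bacterium,PGP,,TRUE,
Komagataella pastoris PP59,K. pastoris PP59|Pichia pastoris PP59,yeast,PGP,,TRUE,formerly classified in genus Pichia
Paraburkholderia tropica MDIIIAzo225,P. tropica MDIIIAzo225|Paraburkholderia tropica MDIIAzo225,bacterium,N-fixation,,TRUE,
Pseudomonas sp. PN53,Pseudomonas sp PN53|P. fluorescens PN53|Pseudomonas fluorescens PN53,bacterium,PGP,,TRUE,
Pseudomonas fluorescens DR54,P. fluorescens DR54,bacterium,Biocontrol,P_solubilization,TRUE,P solubilization reported from maize field application; added as provenance-flagged extra function
Pseudomonas granadensis A23/T3c,P. granadensis A23/T3c|Pseudomonas sp. A23/T3c|P. fluorescens A23/T3c|Pseudomonas fluorescens A23/T3c,bacterium,PGP,,TRUE,reassigned from Pseudomonas sp. by 16S rDNA sequencing
Rahnella aquatilis BB23/T4d,R. aquatilis BB23/T4d|Ranhella aquatilis BB23/T4d|Enterobacter sp. BB23/T4d,bacterium,PGP,,TRUE,reassigned from Enterobacter sp. by 16S rDNA sequencing
Raoultella terrigena FS152,R. terrigena FS152,bacterium,"Phytase activity, siderophore production",,TRUE,
Trichoderma harzianum TH01,T. harzianum TH01,fungus,PGP,,TRUE,
Trichoderma harzianum ATCC 48131,T. harzianum ATCC 48131|Trichoderma harzianum CBS 354.33|Trichoderma harzianum CBS 354.33/ATCC 48131,fungus,"Chitinase production, biocontrol",,TRUE,
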