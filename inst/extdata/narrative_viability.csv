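chemical_id,assay,conc,viability
prochloraz,H295R,0.03,100
prochloraz,H295R,0.1,100
prochloraz,H295R,0.3,99
prochloraz,H295R,1,98
forskolin,H295R,0.03,100
forskolin,H295R,0.1,100
forskolin,H295R,0.3,99
forskolin,H295R,1,99
forskolin,H295R,3,98
pfos,H295R,3,100
pfos,H295R,10,98
pfos,H295R,30,95
pfos,H295R,100,90
pfos,H295R,300,38.2
pfos,AR_CALUX,3,100
pfos,AR_CALUX,10,100
pfos,AR_CALUX,30,98
pfos,AR_CALUX,100,95
pfos,AR_CALUX,300,70
pfos,ER_CALUX,3,100
pfos,ER_CALUX,10,100
pfos,ER_CALUX,30,99
pfos,ER_CALUX,100,97
pfos,ER_CALUX,300,92
aminoglutethimide,H295R,0.3,100
aminoglutethimide,H295R,1,100
aminoglutethimide,H295R,3,99
aminoglutethimide,H295R,10,99
aminoglutethimide,H295R,30,98
aminoglutethimide,H295R,100,96
aminoglutethimide,H295R,300,92
trilostane,H295R,0.001,100
trilostane,H295R,0.003,100
trilostane,H295R,0.01,100
trilostane,H295R,0.03,99
trilostane,H295R,0.1,99
trilostane,H295R,0.3,98
trilostane,H295R,1,97
trilostane,H295R,3,96
hcg,H295R,0.0039,100
hcg,H295R,0.039,100
hcg,H295R,0.39,100
hcg,H295R,3.9,99
atrazine,H295R,0.1,100
atrazine,H295R,0.3,100
atrazine,H295R,1,100
atrazine,H295R,3,99
atrazine,H295R,10,98
atrazine,H295R,30,96
atrazine,H295R,100,90
atrazine,H295R,300,75
atrazine,AR_CALUX,0.1,100
atrazine,AR_CALUX,1,100
atrazine,AR_CALUX,10,99
atrazine,AR_CALUX,100,97
atrazine,AR_CALUX,300,93
letrozole,H295R,3e-06,100
letrozole,H295R,3e-05,100
letrozole,H295R,1e-04,100
letrozole,H295R,0.001,100
letrozole,H295R,0.01,100
letrozole,H295R,0.3,99
letrozole,H295R,3,98
letrozole,H295R,30,97
letrozole,H295R,100,95
molinate,H295R,1,100
molinate,H295R,3,100
molinate,H295R,10,99
molinate,H295R,30,98
molinate,H295R,100,97
molinate,H295R,200,95
molinate,H295R,300,92
bpa,H295R,0.1,100
bpa,H295R,0.3,100
bpa,H295R,1,100
bpa,H295R,3,99
bpa,H295R,10,97
bpa,H295R,30,94
benomyl,H295R,0.3,100
benomyl,H295R,1,98
benomyl,H295R,3,95
benomyl,H295R,10,75
benomyl,H295R,30,50
benomyl,ER_CALUX,0.3,100
benomyl,ER_CALUX,1,100
benomyl,ER_CALUX,3,99
benomyl,ER_CALUX,10,97
benomyl,ER_CALUX,30,95
benomyl,AR_CALUX,0.3,100
benomyl,AR_CALUX,1,100
benomyl,AR_CALUX,3,99
benomyl,AR_CALUX,10,96
benomyl,AR_CALUX,30,94
butylparaben,H295R,1,100
butylparaben,H295R,3,98
butylparaben,H295R,10,95
butylparaben,H295R,30,90
butylparaben,H295R,100,40
butylparaben,ER_CALUX,1,100
butylparaben,ER_CALUX,3,100
butylparaben,ER_CALUX,10,98
butylparaben,ER_CALUX,30,95
butylparaben,ER_CALUX,100,60
butylparaben,AR_CALUX,1,100
butylparaben,AR_CALUX,3,100
butylparaben,AR_CALUX,10,98
butylparaben,AR_CALUX,30,94
butylparaben,AR_CALUX,100,55
cadmium,H295R,1,90
cadmium,H295R,3,75
cadmium,H295R,10,50
cadmium,H295R,30,25
cadmium,H295R,100,10
cadmium,ER_CALUX,1,100
cadmium,ER_CALUX,3,95
cadmium,ER_CALUX,10,90
cadmium,ER_CALUX,30,85
cadmium,ER_CALUX,100,82
cadmium,AR_CALUX,1,100
cadmium,AR_CALUX,3,96
cadmium,AR_CALUX,10,91
cadmium,AR_CALUX,30,86
cadmium,AR_CALUX,100,83
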