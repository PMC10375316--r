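chemical,family,study_effect,study_loec_um,study_direct,study_direct_loec_calux_um,oecd_effect,oecd_labs,lit_receptor,invitro_ref_override,invivo_effect,include_oecd,include_invivo,note
prochloraz,androgens,down,0.03,FALSE,NA,down,NA,positive,NA,down,TRUE,TRUE,study LOEC is the lowest tested concentration
forskolin,androgens,down,3,FALSE,NA,up,NA,unknown,NA,unknown,TRUE,FALSE,no in vivo data; opposite direction vs validation study
pfos,androgens,up,100,FALSE,NA,unknown,NA,unknown,NA,unknown,FALSE,FALSE,not part of the validation chemical set
aminoglutethimide,androgens,down,100,FALSE,NA,down,NA,unknown,NA,up,TRUE,TRUE,
trilostane,androgens,down,0.003,FALSE,NA,up,NA,unknown,NA,down,TRUE,TRUE,validation-study direction attributed to antibody cross-reactivity
hcg,androgens,nd,NA,FALSE,NA,nd,NA,unknown,NA,nd,TRUE,TRUE,inactive downstream of gonadotropin receptors
atrazine,androgens,nd,NA,TRUE,100,up,1,positive,NA,nd,TRUE,TRUE,equivocal validation call: significant in 1 laboratory only
letrozole,androgens,nd,NA,TRUE,33,down,NA,unknown,FALSE,up,TRUE,TRUE,override: AR antagonism previously unrecorded so counted against the study (false positive) in the combined in vitro comparison
molinate,androgens,nd,NA,TRUE,67,nd,NA,positive,NA,nd,TRUE,TRUE,apparent decrease attributed to direct AR antagonism
bpa,androgens,nd,NA,TRUE,0.3,down,NA,positive,NA,nd,TRUE,TRUE,direct-only: AR antagonist
benomyl,androgens,nd,NA,TRUE,10,nd,NA,positive,NA,nd,TRUE,TRUE,steroidogenic decrease masked by H295R cytotoxicity; sham anti-androgenicity without cytotoxicity
butylparaben,androgens,nd,NA,TRUE,10,nd,NA,positive,NA,nd,TRUE,TRUE,cytotoxic at top concentration in all cell lines
cadmium,androgens,nd,NA,FALSE,NA,unknown,NA,nd,NA,down,FALSE,FALSE,not part of the validation chemical set; leading activity cytotoxicity
prochloraz,estrogens,down,0.03,FALSE,NA,down,NA,unknown,NA,down,TRUE,TRUE,study LOEC is the lowest tested concentration
forskolin,estrogens,up,0.3,FALSE,NA,up,NA,unknown,NA,unknown,TRUE,FALSE,isolated low-concentration hit discarded when setting the LOEC
pfos,estrogens,up,100,FALSE,NA,unknown,NA,unknown,NA,unknown,FALSE,FALSE,not part of the validation chemical set
aminoglutethimide,estrogens,down,3,FALSE,NA,down,NA,unknown,NA,down,TRUE,TRUE,
trilostane,estrogens,down_then_up,0.1,FALSE,NA,up,NA,unknown,NA,down,TRUE,TRUE,biphasic profile matches either single direction
hcg,estrogens,nd,NA,FALSE,NA,nd,NA,unknown,NA,nd,TRUE,TRUE,
atrazine,estrogens,up,1,FALSE,NA,up,NA,nd,NA,up,TRUE,TRUE,
letrozole,estrogens,down,3e-5,FALSE,NA,down,NA,unknown,NA,down,TRUE,TRUE,aromatase inhibition detected far below the validation-study LOEC
molinate,estrogens,up,200,FALSE,NA,up,NA,nd,NA,nd,TRUE,TRUE,
bpa,estrogens,nd,NA,TRUE,0.16,up,NA,positive,NA,nd,TRUE,TRUE,direct-only: ER agonist
benomyl,estrogens,nd,NA,FALSE,NA,nd,NA,nd,NA,nd,TRUE,TRUE,steroidogenic decrease masked by H295R cytotoxicity
butylparaben,estrogens,nd,NA,TRUE,4.2,up,2,positive,NA,nd,TRUE,TRUE,equivocal validation call positive: increase in 2 laboratories
cadmium,estrogens,nd,NA,FALSE,NA,unknown,NA,unknown,NA,down,FALSE,FALSE,not part of the validation chemical set; leading activity cytotoxicity
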