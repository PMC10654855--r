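term,concept_id,preferred_name
kanker,CPT0001,maligne neoplasma
tumor,CPT0001,maligne neoplasma
longcarcinoom,CPT0002,longcarcinoom
gemetastaseerd,CPT0003,metastase
palliatieve,CPT0004,palliatieve zorg
palliatieve zorg,CPT0004,palliatieve zorg
opname,CPT0005,ziekenhuisopname
benauwd,CPT0006,dyspnoe
benauwdheid,CPT0006,dyspnoe
kortademig,CPT0006,dyspnoe
prednison,CPT0007,prednison
prednisolon,CPT0007,prednison
zuurstof,CPT0008,zuurstoftherapie
vermagering,CPT0009,gewichtsverlies
gewichtsverlies,CPT0009,gewichtsverlies
hoest,CPT0010,hoest
koorts,CPT0011,koorts
hypertensie,CPT0012,hypertensie
hoge bloeddruk,CPT0012,hypertensie
pneumonie,CPT0013,pneumonie
longontsteking,CPT0013,pneumonie
rugpijn,CPT0014,rugpijn
hoofdpijn,CPT0015,hoofdpijn
diabetes,CPT0016,diabetes mellitus
diabetes mellitus,CPT0016,diabetes mellitus
diabetes mellitus type 2,CPT0017,diabetes mellitus type 2
eczeem,CPT0018,eczeem
duizeligheid,CPT0019,duizeligheid
moeheid,CPT0020,vermoeidheid
vermoeidheid,CPT0020,vermoeidheid
obstipatie,CPT0021,obstipatie
astma,CPT0022,astma
copd,CPT0023,copd
hartfalen,CPT0024,hartfalen
pijn op de borst,CPT0025,thoracale pijn
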