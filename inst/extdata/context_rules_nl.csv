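trigger,category,direction,terminator
geen,negated,forward,FALSE
geen aanwijzing voor,negated,forward,FALSE
geen aanwijzingen voor,negated,forward,FALSE
geen tekenen van,negated,forward,FALSE
geen sprake van,negated,forward,FALSE
niet,negated,forward,FALSE
zonder,negated,forward,FALSE
negatief voor,negated,forward,FALSE
ontkent,negated,forward,FALSE
uitgesloten,negated,backward,FALSE
niet aangetoond,negated,backward,FALSE
afwezig,negated,backward,FALSE
nooit,negated,forward,FALSE
indien,hypothetical,forward,FALSE
als,hypothetical,forward,FALSE
mogelijk,hypothetical,forward,FALSE
mogelijke,hypothetical,forward,FALSE
eventueel,hypothetical,forward,FALSE
eventuele,hypothetical,forward,FALSE
risico op,hypothetical,forward,FALSE
kans op,hypothetical,forward,FALSE
verdenking op,hypothetical,forward,FALSE
ter uitsluiting van,hypothetical,forward,FALSE
misschien,hypothetical,forward,FALSE
twijfel over,hypothetical,forward,FALSE
voorgeschiedenis van,historical,forward,FALSE
in de voorgeschiedenis,historical,backward,FALSE
in het verleden,historical,bidirectional,FALSE
eerder,historical,forward,FALSE
voorheen,historical,forward,FALSE
status na,historical,forward,FALSE
doorgemaakte,historical,forward,FALSE
moeder,experiencer_other,forward,FALSE
vader,experiencer_other,forward,FALSE
familie,experiencer_other,forward,FALSE
familieanamnese,experiencer_other,forward,FALSE
zus,experiencer_other,forward,FALSE
broer,experiencer_other,forward,FALSE
partner,experiencer_other,forward,FALSE
echtgenoot,experiencer_other,forward,FALSE
maar,,,TRUE
wel,,,TRUE
echter,,,TRUE
behalve,,,TRUE
hoewel,,,TRUE
toch,,,TRUE
met uitzondering van,,,TRUE
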