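structure,stage,flatfoot_k
superomedial_spring,IV,39
inferomedial_spring,II,94
talocalcaneal_interosseus,I,236
plantar_fascia,I,175
plantar_metatarsocuneiform,0,90
plantar_naviculocuneiform,0,180
long_and_short_plantar,0,240
deep_deltoid,0,200
anterior_superficial_deltoid,I,70
posterior_superficial_deltoid,0,117
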