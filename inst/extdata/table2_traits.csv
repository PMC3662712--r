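common_name,n_landcover_types,ln_mass
Wild turkey,9,9.31
Greater sage grouse,1,8.01
Greater prairie chicken,2,6.91
Gambel's quail,3,5.30
Red-headed woodpecker,10,4.32
Red-bellied woodpecker,8,4.32
Fish crow,6,5.71
Carolina chickadee,1,2.49
Carolina wren,5,2.99
Bewick's wren,7,2.43
Bachman's sparrow,2,3.12
Tricolored blackbird,2,4.09
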