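name,trait_class,chr,lines,description
vig2.1,vigor,2,SP_2-4;SP_2-5,Fast vegetative growth
vig3.1,vigor,3,SP_3-1,Severe plant-growth reduction; failed to set fruit in two locations
purp5.1,anthocyanin,5,SP_5-2;SP_5-3,Purple primary and axillary shoots (anthocyanin accumulation)
tri10.1,trichome_density,10,SP_10-3,Dense long trichomes on stems and leaves
ear2.1,earliness,2,SP_2-5,First ripe fruit 8 days earlier than the control
ear11.1,earliness,11,SP_11-4,First ripe fruit 8-13 days later than the control
gs10.1,green_shoulder,10,SP_10-1;SP_10-2,Dark green shoulder on breaker fruit
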