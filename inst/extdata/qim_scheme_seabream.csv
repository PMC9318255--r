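modality,attribute,demerit,description
Appearance,color,0,White
Appearance,color,1,Greyish
Appearance,color,2,Yellowish
Appearance,discoloration,0,Uniform color with no discolorations
Appearance,discoloration,1,Slight discolorations
Appearance,discoloration,2,Intense discolorations
Appearance,brightness,0,"Bright, lean, shiny, lucid"
Appearance,brightness,1,"Slightly bright, slightly porous"
Appearance,brightness,2,"Pale, porous, dull matt"
Odor,odor,0,Fresh seaweed
Odor,odor,1,Neutral
Odor,odor,2,Fishy
Odor,odor,3,"Stale, off-odors"
Texture,firmness,0,Firm
Texture,firmness,1,Slightly firm
Texture,firmness,2,Soft
Texture,elasticity,0,Elastic
Texture,elasticity,1,Slightly elastic
Texture,elasticity,2,Non-elastic
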