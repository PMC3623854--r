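outcome,segmentation,segment,deprivation_rank,beta1,beta2,printed_ratio
not_good_health,imd_tertiles,Upper third (most deprived),1,0.531,0.221,2.202
not_good_health,imd_tertiles,Medium third (middle deprived),2,0.555,0.513,1.081
not_good_health,imd_tertiles,Lower third (least deprived),3,0.732,0.748,0.978
not_good_health,categorical,New Starters,6,0.736,0.237,3.105
not_good_health,categorical,Urban Challenge,1,0.452,0.200,2.260
not_good_health,categorical,Multicultural Centres,3,0.604,0.265,2.279
not_good_health,categorical,Qualified Metropolitan,8,0.542,0.246,2.203
not_good_health,categorical,Weathered Communities,4,0.441,0.252,1.750
not_good_health,categorical,Urban Producers,5,0.627,0.446,1.405
not_good_health,categorical,Disadvantaged Households,2,0.701,0.523,1.340
not_good_health,categorical,Senior Neighbourhoods,9,0.541,0.418,1.294
not_good_health,categorical,Suburban Stability,7,0.534,0.464,1.150
not_good_health,categorical,Country Orchards,11,0.600,0.577,1.039
not_good_health,categorical,Rooted Households,10,0.555,0.558,1.008
not_good_health,categorical,Blossoming Families,12,0.601,0.633,0.949
not_good_health,categorical,Mature oaks,13,0.638,0.688,0.927
llti,imd_tertiles,Upper third (most deprived),1,0.409,0.112,3.651
llti,imd_tertiles,Medium third (middle deprived),2,0.336,0.298,1.127
llti,imd_tertiles,Lower third (least deprived),3,0.577,0.602,0.958
llti,categorical,Urban Challenge,1,0.409,0.055,7.436
llti,categorical,Qualified Metropolitan,8,0.400,0.056,7.142
llti,categorical,New Starters,6,0.659,0.172,3.831
llti,categorical,Multicultural Centres,3,0.537,0.179,3.000
llti,categorical,Weathered Communities,4,0.366,0.158,2.316
llti,categorical,Urban Producers,5,0.643,0.397,1.619
llti,categorical,Disadvantaged Households,2,0.706,0.500,1.412
llti,categorical,Senior Neighbourhoods,9,0.386,0.302,1.278
llti,categorical,Suburban Stability,7,0.426,0.354,1.203
llti,categorical,Rooted Households,10,0.436,0.404,1.079
llti,categorical,Country Orchards,11,0.567,0.546,1.038
llti,categorical,Blossoming Families,12,0.550,0.559,0.983
llti,categorical,Mature oaks,13,0.567,0.606,0.935
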