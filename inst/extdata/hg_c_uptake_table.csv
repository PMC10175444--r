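biome,gem_growing,nep_growing,ratio_growing_printed,gem_annual,nep_annual,ratio_annual_printed
evergreen_broadleaf,53.9,800,0.067,53.9,800,0.067
deciduous,35.3,390,0.091,34.9,416,0.084
coniferous,12.6,224,0.056,13.4,210,0.064
grassland,37.67,1778.6,0.021,25.1,946,0.027
tundra,3.56,108.5,0.033,6.5,-89,-0.073
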