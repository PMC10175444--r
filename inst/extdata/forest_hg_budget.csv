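site,forest_type,gem_annual,gem_growing,canopy_gem,floor_gem,litterfall,wet,throughfall,open_field,hg2_dry,phg_dry,background_gem_ngm3,wet_approx
harvard,deciduous,-25.1,-21.9,-15.4,-9.7,-12.3,-5.0,-7.0,5.0,-1.9,-1.1,1.10,TRUE
howland,coniferous,-13.4,-12.6,-14.3,0.93,-11.2,-5.1,-8.8,5.1,-1.9,-1.1,1.03,FALSE
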