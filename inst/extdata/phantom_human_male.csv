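# ICRP-89-style adult male reference organ masses with organ dose limits.
organ,mass_kg,dose_limit_Gy
kidneys,0.310,23
pancreas,0.140,NA
liver,1.800,30
stomach_wall,0.150,45
lungs,1.200,65
urinary_bladder_wall,0.050,20
spleen,0.150,26
heart_wall,0.330,45
red_marrow,1.170,2
blood,5.300,NA
tumor,0.010,NA
carcass,62.500,NA
body,73.000,NA
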