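# ICRP-89-style adult female reference organ masses with organ dose limits.
organ,mass_kg,dose_limit_Gy
kidneys,0.275,23
pancreas,0.120,NA
liver,1.400,30
stomach_wall,0.140,45
lungs,0.950,65
urinary_bladder_wall,0.040,20
spleen,0.130,26
heart_wall,0.250,45
red_marrow,0.900,2
blood,4.100,NA
tumor,0.010,NA
carcass,49.685,NA
body,58.000,NA
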