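# Typical 25-g adult mouse organ masses (kg) used as the murine phantom.
organ,mass_kg,dose_limit_Gy
kidneys,0.0004,23
pancreas,0.0002,NA
liver,0.0013,30
stomach_wall,0.0003,45
lungs,0.00015,65
urinary_bladder_wall,0.00003,20
spleen,0.0001,26
heart_wall,0.00015,45
red_marrow,0.0003,2
blood,0.0015,NA
tumor,0.0003,NA
carcass,0.020,NA
body,0.025,NA
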