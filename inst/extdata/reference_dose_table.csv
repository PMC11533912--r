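# Published human-projected absorbed doses (Gy, RBE 5) per organ at an administered
# activity of 0.111 GBq, female reference, with organ dose limits (Gy). Consumed as
# inputs: the underlying raw biodistribution is not public, so these printed values
# define the dose coefficients (Gy/GBq = dose_Gy_at_ref / 0.111).
organ,dose_Gy_at_ref,ref_activity_GBq,dose_limit_Gy
kidneys,0.308,0.111,23
pancreas,0.287,0.111,NA
liver,0.109,0.111,30
stomach_wall,0.044,0.111,45
lungs,0.022,0.111,65
urinary_bladder_wall,0.021,0.111,20
spleen,0.018,0.111,26
heart_wall,0.007,0.111,45
red_marrow,0.001,0.111,2
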