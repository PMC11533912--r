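# Pb-212 decay-chain constants, v1 (ICRP-107/NNDC-derived mean energies).
# One row per decay mode; energies are mean MeV emitted per decay occurring VIA THAT MODE.
# half_life_s applies to the parent nuclide; branching fractions per parent sum to 1.
nuclide,half_life_s,stable,daughter,branching,e_alpha_MeV,e_electron_MeV,e_photon_MeV
Pb-212,38304,FALSE,Bi-212,1.0,0,0.1747,0.1448
Bi-212,3633,FALSE,Po-212,0.6406,0,0.7680,0.1614
Bi-212,3633,FALSE,Tl-208,0.3594,6.0490,0,0
Po-212,2.99e-07,FALSE,Pb-208,1.0,8.7850,0,0
Tl-208,183.18,FALSE,Pb-208,1.0,0,0.5993,3.3750
Pb-208,NA,TRUE,NA,NA,NA,NA,NA
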