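# Molar extinction coefficients of human hemoglobin (cm^-1 / M), approximate
# values from the standard tabulated compilation of oxy/deoxyhemoglobin
# absorption spectra. Absolute scale cancels in sO2 estimation; only the
# ratio between wavelengths matters.
wavelength_nm,eps_hbo2,eps_hb
520,24202,25773
530,39956,39036
532,44480,40584
540,53236,46592
545,49156,49846
550,43016,52940
555,36000,53412
558,32620,52276
560,29892,50792
570,44496,45072
580,50104,37020
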