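# Molar extinction coefficients of human hemoglobin, cm^-1 (mol/L)^-1,
# at the two operating wavelengths. Values from the widely used Gratzer/Prahl
# compilation of hemoglobin absorption spectra.
wavelength_nm	oxy	deoxy
760	586	1548.52
850	1058	691.32
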