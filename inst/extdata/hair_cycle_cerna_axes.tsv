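lncrna	mirna	mrna
Neat1	miR-22-3p	Cdkn1a
Tug1	miR-22-3p	Cdkn1a
Neat1	miR-27a-3p	Plk2
Neat1	miR-27b-3p	Gspt1
Neat1	miR-30a-5p	Notch1
Neat1	miR-30e-5p	Notch1
Neat1	miR-146a-5p	Notch1
Neat1	miR-126a-3p	Slc7a5
Neat1	miR-148a-3p	Gadd45a
Neat1	miR-148a-3p	Mafb
Neat1	miR-148a-3p	Mitf
Tug1	miR-148a-3p	Gadd45a
Tug1	miR-148a-3p	Mafb
Tug1	miR-148a-3p	Mitf
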