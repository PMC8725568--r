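variable	level	count
ER	negative	16900
ER	positive	70030
ER	unknown	19641
PR	negative	24283
PR	positive	51603
PR	unknown	30685
HER2	negative	47693
HER2	positive	9529
HER2	unknown	49349
grade	1	15583
grade	2	37568
grade	3	24382
grade	unknown	29038
subtype	luminalA	27510
subtype	luminalB_HER2neg	6804
subtype	luminalB_HER2pos	6511
subtype	HER2pos_nonluminal	2797
subtype	triple_negative	7178
subtype	unknown	55771
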