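# log2-odds pathway activity scores reported for CD4+ T cells isolated from
# tumor-infiltrating lymphocyte (TIL) samples of 10 primary breast cancer
# patients (Affymetrix-based assay), with immunohistochemistry subtype.
# Transcribed published values; used as the worked clinical example.
sample_id	subtype	FOXO	NFkB	JAK_STAT1_2	JAK_STAT3	TGFB	Notch
TIL_pt3	luminal	10.9	30.3	-1.2	0.9	-2.4	9.3
TIL_pt1	luminal	5.6	21.5	-6.3	-3.9	-7.5	6.3
TIL_pt5	luminal	7.2	31.3	-4.0	5.4	-4.8	7.0
TIL_pt2	luminal	6.9	26.8	0.5	1.2	-6.8	2.5
TIL_pt4	her2_positive	0.9	23.5	0.9	0.3	-8.5	1.5
TIL_pt10	triple_negative	14.5	24.8	-2.2	1.3	-7.4	9.3
TIL_pt7	triple_negative	5.4	22.8	-1.3	0.4	-9.0	5.6
TIL_pt6	triple_negative	9.6	19.0	-9.8	-3.3	-10.4	4.0
TIL_pt8	triple_negative	3.2	13.6	-4.5	-3.2	-8.3	5.2
TIL_pt9	triple_negative	-1.9	18.1	-3.4	-4.2	-14.2	-1.3
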