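# log2-odds pathway activity scores reported for blood-derived CD4+ T cells
# of the same 10 primary breast cancer patients (Affymetrix-based assay).
# Transcribed published values; used as the worked clinical example.
sample_id	FOXO	NFkB	JAK_STAT1_2	JAK_STAT3	TGFB	Notch
blood_pt1	8.5	17.4	-7.4	-2.4	-5.0	1.6
blood_pt2	-1.6	-1.5	-7.7	-7.3	-14.5	-5.7
blood_pt3	5.9	6.3	-8.7	-5.5	-14.7	-8.7
blood_pt4	-3.8	-5.1	-5.6	-6.2	-19.6	-6.1
blood_pt5	2.4	8.4	-8.7	-4.3	-11.7	-4.2
blood_pt6	1.7	5.9	-7.2	-6.3	-13.2	-8.4
blood_pt7	6.9	3.2	-8.3	-5.8	-14.3	-7.3
blood_pt8	1.3	5.2	-9.3	-6.7	-14.9	-6.8
blood_pt9	-2.5	-1.3	-4.2	-8.1	-18.4	-8.0
blood_pt10	-2.2	-3.6	-6.2	-7.3	-18.8	-8.4
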