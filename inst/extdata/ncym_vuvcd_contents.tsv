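# Published VUVCD/SELCON3 secondary-structure contents and segment counts for
# the SUMO-tagged NCYM construct (238 residues: 129-residue SUMO tag +
# 109-residue NCYM) and the isolated SUMO tag, each in hydrogenated (H_) and
# perdeuterated (D_) form. Fractions are percent of residues: h_r/h_d =
# ordered/distorted alpha-helix, s_r/s_d = ordered/distorted beta-strand.
sample	n_res	h_r	h_d	s_r	s_d	n_helix	n_strand
H_Tag_NCYM	238	6.7	10.4	15.9	11.3	6	13
D_Tag_NCYM	238	6.5	9.8	15.9	11.1	6	13
H_Tag	129	5.4	8.8	16.6	12.6	3	8
D_Tag	129	4.9	9.0	16.3	12.4	3	8
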