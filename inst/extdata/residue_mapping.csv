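# Curated per-helix residue correspondences (approximate), anchored on
# published equivalent residues (e.g. D79<->D98, Y156<->Y176 for the
# serotonin-transporter pair; D79<->D46, Y156<->Y124 for the fly pair).
# Expanded to residue level by residue_mapping(); replace with an
# alignment-derived table for production comparisons.
pair,helix,ref_chain,ref_start,ref_end,target_chain,target_start
hdat_hsert,TM1b,A,78,92,A,97
hdat_hsert,TM3,A,152,175,A,172
hdat_hsert,TM6a,A,306,319,A,321
hdat_hsert,TM8,A,406,433,A,422
hdat_ddat,TM1b,A,78,92,A,45
hdat_ddat,TM3,A,152,175,A,120
hdat_ddat,TM6a,A,306,319,A,305
hdat_ddat,TM8,A,406,433,A,405
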