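# Curated transmembrane helix ranges (approximate), full-length numbering.
# Derived from topology annotations and published anchor residues; these are
# reference inputs for the helix-comparison analyses and can be replaced by
# a table derived from your own model's annotation.
structure,helix,chain,start,end
hDAT,TM1a,A,65,77
hDAT,TM1b,A,78,92
hDAT,TM3,A,152,175
hDAT,TM6a,A,306,319
hDAT,TM6b,A,320,333
hDAT,TM8,A,406,433
hSERT,TM1a,A,84,96
hSERT,TM1b,A,97,111
hSERT,TM3,A,172,195
hSERT,TM6a,A,321,334
hSERT,TM6b,A,335,348
hSERT,TM8,A,422,449
dDAT,TM1a,A,32,44
dDAT,TM1b,A,45,59
dDAT,TM3,A,120,143
dDAT,TM6a,A,305,318
dDAT,TM6b,A,319,332
dDAT,TM8,A,405,432
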