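# RNA-seq summary of the four Tuber borchii SP1 cultures: read totals,
# expressed-gene counts and KOG-annotated gene counts. The reference_genome
# row carries the gene catalog size in the genes column and the
# genome-wide KOG-annotated count in genes_kog.
sample	total_reads	genes	genes_kog
WPG	116376579	10870	4645
WPGY	125457058	10941	4642
MPY	47969567	10442	4582
PDB	157335190	10599	4621
reference_genome	NA	12346	5686
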