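qpcr_primers_table.tsv: qPCR primer metadata for the validated goat
hypothalamus genes, shipped for documentation only (no function reads
it).  In the published source the forward and reverse primer of each
pair are printed run together without a separator, so the
primer_sequences_5to3 column keeps them concatenated (forward then
reverse, both 5'-3') rather than guessing a split point; product sizes
are in bp.
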