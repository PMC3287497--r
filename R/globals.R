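# data.table non-standard-evaluation column names
utils::globalVariables(c(
  ".", "context", "total_reads", "mc_reads", "methylated", "gene_idx",
  "gstrand", "ndup", "chrom", "pos", "win", "meth", "gene_id", "mirna_id",
  "site_position", "source_db", "n_meth", "n_unmeth", "probe_id", "value",
  "start", "end", "strand", "utr3_start", "utr3_end", "species", "text",
  "transcript_id", "grp", "mc", "tot", "q_value", "statistic", "src_suffix"
))
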