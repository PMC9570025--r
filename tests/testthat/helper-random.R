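# Random peptide sequences for property-style tests.
random_peptides <- function(n, min_len = 5, max_len = 60, seed = 101) {
  set.seed(seed)
  aa <- strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]]
  vapply(seq_len(n), function(i)
    paste(sample(aa, sample(min_len:max_len, 1), TRUE), collapse = ""),
    character(1))
}
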