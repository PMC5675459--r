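# Shared fixtures built in code.

# random singles plus exactly Bliss-consistent pairs (g_ij = g_i * g_j)
random_bliss_inputs <- function(M, lo = 0.05, hi = 1) {
  s <- stats::setNames(stats::runif(M, lo, hi), sprintf("D%02d", seq_len(M)))
  idx <- utils::combn(M, 2L)
  p <- stats::setNames(apply(idx, 2L, function(ij) prod(s[ij])),
                       apply(utils::combn(names(s), 2L), 2L,
                             paste, collapse = "+"))
  list(singles = s, pairs = p, drugs = names(s))
}

# minimal valid screen: two singles and their pair
minimal_records <- function() {
  data.frame(cell_line = "A",
             drugs = c("X", "Y", "X+Y"),
             viability = c(0.8, 0.7, 0.5),
             ste = c(0.01, 0.01, 0.02),
             stringsAsFactors = FALSE)
}

write_screen_file <- function(df, sep = "\t") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
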