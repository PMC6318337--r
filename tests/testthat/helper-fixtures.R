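# Shared in-code fixtures: every sequence is generated, nothing read from disk.

fixture_library <- function(seed = 100L, ltr = 400L, internal = 4200L) {
  structure(list(
    famA = simulate_te_family("famA", ltr_length = ltr, internal_length = internal,
                              superfamily = "Gypsy", seed = seed),
    famB = simulate_te_family("famB", ltr_length = ltr, internal_length = internal,
                              superfamily = "Copia", seed = seed + 1L)),
    class = "te_library")
}

fixture_dna <- function(n, seed = 1L, gc = 0.44) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

fixture_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Nanopore-like 8% total error (substitutions + indels) on one sequence.
mutate_with_indels_for_test <- function(s, rate = 0.08) {
  v <- strsplit(s, "")[[1]]
  alt <- c("A", "C", "G", "T")
  ns <- rbinom(1, length(v), 0.6 * rate)
  if (ns) { at <- sample.int(length(v), ns); v[at] <- alt[sample.int(4, ns, TRUE)] }
  nd <- rbinom(1, length(v), 0.2 * rate)
  if (nd) v <- v[-sample.int(length(v), nd)]
  ni <- rbinom(1, length(v), 0.2 * rate)
  if (ni) {
    at <- sort(sample.int(length(v), ni), decreasing = TRUE)
    ins <- alt[sample.int(4, ni, TRUE)]
    for (j in seq_len(ni)) v <- append(v, ins[j], after = at[j])
  }
  paste(v, collapse = "")
}
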