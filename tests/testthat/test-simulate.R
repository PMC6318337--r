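# The ground-truth generator: determinism, planted repeat content, carrier
# bookkeeping, and read-generation arithmetic.

test_that("reference simulation is seed-deterministic with controlled repeats", {
  r1 <- simulate_reference(length = 2e5, repeat_fraction = 0.4, seed = 101)
  r2 <- simulate_reference(length = 2e5, repeat_fraction = 0.4, seed = 101)
  expect_identical(r1$genome, r2$genome)

  covered <- logical(2e5)
  for (i in seq_len(nrow(r1$repeats)))
    covered[(r1$repeats$start[i] + 1):r1$repeats$end[i]] <- TRUE
  expect_lt(abs(mean(covered) - 0.4), 0.02)

  r0 <- simulate_reference(length = 1e5, repeat_fraction = 0, seed = 102)
  expect_equal(nrow(r0$repeats), 0L)
  expect_error(simulate_reference(length = 1e5, repeat_fraction = 1), "< 1")
  expect_error(simulate_reference(length = 1e4), ">= 1e5")
})

test_that("panel carriers follow the drawn frequencies exactly", {
  ref <- simulate_reference(length = 2e5, repeat_fraction = 0, seed = 103)
  lib <- fixture_library()

  all1 <- simulate_panel(ref, lib, n_accessions = 5L, n_loci = 10L,
                         frequency_law = "constant", const_freq = 1, seed = 104)
  expect_true(all(all1$carrier_matrix))
  expect_equal(all1$truth$carriers, rowSums(all1$carrier_matrix))

  half <- simulate_panel(ref, lib, n_accessions = 20L, n_loci = 100L,
                         frequency_law = "constant", const_freq = 0.5,
                         seed = 105)
  # binomial oracle: mean carriers 10, SE of the mean sqrt(20*0.25/100)
  expect_lt(abs(mean(half$truth$carriers) - 10), 4 * sqrt(20 * 0.25 / 100))
  expect_equal(half$truth$carriers, rowSums(half$carrier_matrix))

  # inserted genomes grow by element length + TSD per carried insertion
  lens <- nchar(vapply(all1$genomes, `[[`, character(1), 1))
  expect_true(all(lens == 2e5 + 10 * (nchar(lib$famA$consensus) + 5)))
})

test_that("the L-shaped law concentrates loci at one or two carriers", {
  ref <- simulate_reference(length = 5e5, repeat_fraction = 0, seed = 106)
  lib <- fixture_library()
  p <- simulate_panel(ref, lib, n_accessions = 20L, n_loci = 100L,
                      frequency_law = "lshape", seed = 107)
  frac <- mean(p$truth$carriers <= 2)
  # oracle from the law's CDF: E[P(c<=2 | c>=1)] for f log-uniform on [1e-3,1]
  expected <- integrate(function(u) {
    f <- 10^u
    (dbinom(1, 20, f) + dbinom(2, 20, f)) / (1 - dbinom(0, 20, f)) / 3
  }, -3, 0)$value
  expect_gte(frac, 0.6)
  expect_lt(abs(frac - expected), 0.15)
})

test_that("paired-end read generation has the stated count, purity and errors", {
  g <- c(chr1 = fixture_dna(100000, seed = 108))
  rd <- generate_reads(g, coverage = 10, error_rate = 0, seed = 109)
  expect_length(rd$mate1, 5000L)  # 10x * 1e5 / (2*100)
  gd <- Biostrings::DNAString(g[[1]])
  for (i in sample.int(5000, 30)) {
    hits <- Biostrings::countPattern(rd$mate1[[i]], gd) +
      Biostrings::countPattern(fixture_revcomp(rd$mate1[[i]]), gd)
    expect_gte(hits, 1L)
  }
  # same seed, with errors: fragments identical, per-base error near nominal
  re <- generate_reads(g, coverage = 10, error_rate = 0.005, seed = 109)
  mm <- sum(charToRaw(paste0(re$mate1, collapse = "")) !=
              charToRaw(paste0(rd$mate1, collapse = ""))) +
    sum(charToRaw(paste0(re$mate2, collapse = "")) !=
          charToRaw(paste0(rd$mate2, collapse = "")))
  rate <- mm / (2 * 5000 * 100)
  expect_lt(abs(rate - 0.005), 0.0005)

  expect_error(generate_reads(g, coverage = 0), "positive")
  expect_error(generate_reads(g, coverage = 5, insert_mean = 150), "insert_mean")

  # FASTQ output round-trips
  pre <- tempfile()
  fq <- generate_reads(g, coverage = 1, error_rate = 0, seed = 110,
                       out_prefix = pre)
  back <- Biostrings::readDNAStringSet(fq$fq1, format = "fastq")
  expect_length(back, 500L)
})

test_that("long reads reach target coverage and are exact when error-free", {
  g <- c(chr1 = fixture_dna(200000, seed = 111))
  lr <- generate_long_reads(g, coverage = 11, error_rate = 0, seed = 112)
  total <- sum(nchar(lr))
  expect_lt(abs(total - 11 * 200000) / (11 * 200000), 0.05)
  gd <- Biostrings::DNAString(g[[1]])
  for (i in sample(seq_along(lr), 10)) {
    hits <- Biostrings::countPattern(lr[[i]], gd) +
      Biostrings::countPattern(fixture_revcomp(lr[[i]]), gd)
    expect_gte(hits, 1L)
  }
  expect_identical(lr, generate_long_reads(g, coverage = 11, error_rate = 0,
                                           seed = 112))
})

test_that("assembly trio plants categories at orthologous backbone positions", {
  lib <- fixture_library()
  trio <- simulate_assembly_trio(lib$famA, n_per_category = 2L, seed = 113)
  truth <- trio$truth
  expect_equal(nrow(truth), 14L)
  # presence pattern matches the category definition
  pres <- !is.na(truth[, c("start_japonica", "start_indica", "start_aus")])
  expect_true(all(pres[truth$category == "common-all", ]))
  expect_equal(unname(pres[truth$category == "Japonica-specific", 1]),
               rep(TRUE, 2))
  expect_false(any(pres[truth$category == "Japonica-specific", 2:3]))
  # the element sequence really sits at the recorded start
  i <- which(truth$category == "common-all")[1]
  ltr <- substring(lib$famA$consensus, 1, 50)
  at <- substring(trio$genomes$indica[[1]], truth$start_indica[i] + 1,
                  truth$start_indica[i] + 50)
  expect_lt(sum(charToRaw(at) != charToRaw(ltr)), 5)
})
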