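# Junction classification, support counting and the two-pass 5/2 thresholds.

make_support <- function(...) {
  data.table::rbindlist(list(...))
}

srow <- function(acc, fam, win, n) {
  data.table::data.table(accession_id = acc, family_id = fam,
                         window_id = win, count = as.integer(n))
}

test_that("classify_pairs keeps pairs with exactly one TE mate", {
  lib <- fixture_library()
  te_read <- substring(lib$famA$consensus, 1001, 1100)
  te_read_b <- substring(lib$famB$consensus, 2001, 2100)
  genomic <- fixture_dna(100, seed = 61)
  genomic2 <- fixture_dna(100, seed = 62)

  jp <- classify_pairs(c(p1 = te_read, p2 = te_read, p3 = genomic),
                       c(p1 = genomic, p2 = te_read_b, p3 = genomic2), lib)
  expect_equal(jp$pair_id, "p1")
  expect_equal(jp$family_id, "famA")
  expect_equal(jp$anchor_mate, unname(genomic))
  cnt <- attr(jp, "counts")
  expect_equal(unname(cnt["both_te"]), 1)
  expect_equal(unname(cnt["neither"]), 1)

  expect_warning(classify_pairs(c(te_read, te_read), genomic, lib), "orphan")
})

test_that("collect_support counts only uniquely anchored junctions per window", {
  base <- fixture_dna(60000, seed = 63)
  g <- paste0(substring(base, 1, 40000), substring(base, 20001, 25000),
              substring(base, 45001, 60000))
  idx <- seed_index(c(chr1 = g))
  w <- make_windows(c(chr1 = nchar(g)))

  anchors <- substring(g, c(5001, 5201, 5401, 5601, 5801),
                       c(5100, 5300, 5500, 5700, 5900))
  jx <- data.frame(pair_id = paste0("p", 1:5), family_id = "famA",
                   te_mate = "x", anchor_mate = anchors)
  sup <- collect_support(jx, idx, w, accession = "accA")
  expect_equal(nrow(sup), 1L)
  expect_equal(sup$count, 5L)
  expect_equal(sup$window_id, "chr1:0-10000")

  # ambiguous anchor (inside the duplicated block) contributes nothing
  jx2 <- rbind(jx, data.frame(pair_id = "p6", family_id = "famA", te_mate = "x",
                              anchor_mate = substring(g, 21001, 21100)))
  sup2 <- collect_support(jx2, idx, w, accession = "accA")
  expect_equal(sup2$count, 5L)

  # left-most base rule at the window boundary
  jx3 <- data.frame(pair_id = c("a", "b"), family_id = "famA", te_mate = "x",
                    anchor_mate = c(substring(g, 9901, 10000),
                                    substring(g, 10001, 10100)))
  sup3 <- collect_support(jx3, idx, w, accession = "accA")
  expect_setequal(sup3$window_id, c("chr1:0-10000", "chr1:10000-20000"))
})

test_that("first pass opens windows at exactly the 5-read threshold", {
  sup <- make_support(srow("A", "f", "w1", 5), srow("B", "f", "w1", 1),
                      srow("A", "f", "w2", 4), srow("B", "f", "w2", 4))
  op <- first_pass(sup)
  expect_equal(op$window_id, "w1")
  expect_equal(nrow(first_pass(srow("A", "f", "w", 4))), 0L)
  expect_equal(nrow(first_pass(srow("A", "f", "w", 0)[0, ])), 0L)
})

test_that("second pass rescues at 2 reads but only in opened windows", {
  sup <- make_support(srow("A", "f", "w1", 5), srow("B", "f", "w1", 2),
                      srow("C", "f", "w1", 1), srow("B", "f", "w2", 3))
  op <- first_pass(sup)
  calls <- second_pass(sup, op)
  expect_setequal(calls$accession_id, c("A", "B"))
  expect_equal(calls$pass[calls$accession_id == "A"], 1L)
  expect_equal(calls$pass[calls$accession_id == "B"], 2L)
  # count 1 in an opened window is not called; count 3 outside opened is not
  expect_false("C" %in% calls$accession_id)
  expect_false("w2" %in% calls$window_id)
})

test_that("thresholds are monotone and the two-pass closure holds", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 60
    sup <- data.table::data.table(
      accession_id = sample(sprintf("acc%02d", 1:8), n, replace = TRUE),
      family_id = sample(c("f1", "f2"), n, replace = TRUE),
      window_id = sample(sprintf("chr1:%d-%d", 0:5 * 10000, 1:6 * 10000),
                         n, replace = TRUE),
      count = sample.int(8, n, replace = TRUE))
    sup <- sup[, list(count = sum(count)),
               by = c("accession_id", "family_id", "window_id")]
    op5 <- first_pass(sup, 5L)
    op4 <- first_pass(sup, 4L)
    key5 <- paste(op5$family_id, op5$window_id)
    key4 <- paste(op4$family_id, op4$window_id)
    expect_true(all(key5 %in% key4))  # lowering the threshold never closes

    calls <- second_pass(sup, op5)
    # every pass-1-eligible cell survives as a call (5 >= 2)
    p1 <- sup[sup$count >= 5L, ]
    expect_true(all(paste(p1$accession_id, p1$family_id, p1$window_id) %in%
                      paste(calls$accession_id, calls$family_id, calls$window_id)))
    # closure: in opened events, every accession with count >= 2 is called
    mat <- build_matrix(calls, unique(sup$accession_id))
    opened_sup <- merge(sup, data.table::as.data.table(op5),
                        by = c("family_id", "window_id"))
    ge2 <- opened_sup[opened_sup$count >= 2L, ]
    idx <- cbind(match(paste(ge2$family_id, ge2$window_id, sep = ":"),
                       rownames(mat)),
                 match(ge2$accession_id, colnames(mat)))
    expect_true(all(mat[idx] == 1L))
  }
})

test_that("build_matrix produces an ordered binary matrix", {
  calls <- data.frame(accession_id = c("A", "A"), family_id = "f",
                      window_id = c("chr1:10000-20000", "chr1:0-10000"),
                      support = c(5L, 6L), pass = 1L)
  m <- build_matrix(calls, c("B", "A"))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(colnames(m), c("A", "B"))
  expect_equal(rownames(m), c("f:chr1:0-10000", "f:chr1:10000-20000"))
  expect_equal(unname(m[, "A"]), c(1L, 1L))
  expect_equal(unname(m[, "B"]), c(0L, 0L))
  expect_equal(sum(m), nrow(unique(calls[c("accession_id", "family_id",
                                           "window_id")])))
  expect_equal(nrow(build_matrix(calls[0, ], c("A"))), 0L)
  expect_error(build_matrix(calls, "B"), "absent from the panel")
})

test_that("detect_tips is deterministic and returns no rows without TE reads", {
  ref <- simulate_reference(length = 150000, repeat_fraction = 0.2, seed = 71)
  lib <- fixture_library()
  panel <- simulate_panel(ref, lib, n_accessions = 2L, n_loci = 4L,
                          frequency_law = "constant", const_freq = 1,
                          seed = 72)
  reads <- lapply(panel$genomes, generate_reads, coverage = 12, seed = 73)
  r1 <- detect_tips(reads, lib, panel$reference)
  r2 <- detect_tips(reads, lib, panel$reference)
  expect_identical(r1$matrix, r2$matrix)
  expect_gt(nrow(r1$matrix), 0L)

  # reads from the bare reference contain no TE junctions
  bare <- list(acc1 = generate_reads(panel$reference, coverage = 5, seed = 74))
  r0 <- detect_tips(bare, lib, panel$reference)
  expect_equal(nrow(r0$matrix), 0L)
})

test_that("FASTQ manifest input matches in-memory input", {
  ref <- simulate_reference(length = 120000, repeat_fraction = 0, seed = 81)
  lib <- fixture_library()
  panel <- simulate_panel(ref, lib, n_accessions = 1L, n_loci = 3L,
                          frequency_law = "constant", const_freq = 1, seed = 82)
  mem <- generate_reads(panel$genomes[[1]], coverage = 12, seed = 83)
  pre <- tempfile()
  fq <- generate_reads(panel$genomes[[1]], coverage = 12, seed = 83,
                       out_prefix = pre)
  r_mem <- detect_tips(list(acc01 = mem), lib, panel$reference)
  r_fq <- detect_tips(list(acc01 = fq), lib, panel$reference)
  expect_identical(r_mem$matrix, r_fq$matrix)
})
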