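# Full-element discovery, LTR-LTR dating, orthology classification and
# category validation.

test_that("molecular-clock dating matches the closed form and is monotone", {
  expect_equal(date_insertion(0.994), (1 - 0.994) / (2 * 1.3e-8))
  expect_equal(date_insertion(1.0), 0)
  expect_error(date_insertion(0.9, rate = 0), "positive")
  expect_error(date_insertion(1.2), "identity")
  # strictly decreasing in identity
  ids <- seq(0.9, 1, by = 0.005)
  expect_true(all(diff(date_insertion(ids)) < 0))
  # Jukes-Cantor correction increases ages for diverged pairs
  expect_gt(date_insertion(0.95, correction = "JC69"), date_insertion(0.95))
})

test_that("ltr_identity measures divergence of the two element halves", {
  ltr <- fixture_dna(1000, seed = 90)
  internal <- fixture_dna(2000, seed = 91)
  elem <- paste0(ltr, internal, ltr)
  expect_equal(ltr_identity(elem), 1.0)

  ltr2 <- ltr
  for (p in c(150, 300, 450, 600, 750, 900)) {
    substr(ltr2, p, p) <- setdiff(c("A", "C", "G", "T"), substr(ltr2, p, p))[1]
  }
  elem2 <- paste0(ltr, internal, ltr2)
  expect_equal(ltr_identity(elem2), 0.994, tolerance = 1e-3)
})

test_that("simulated LTR divergence is recovered on average", {
  lib <- fixture_library(ltr = 1000L, internal = 3000L)
  set.seed(92)
  t_true <- 5e5
  ages <- vapply(1:40, function(i) {
    elem <- tipscan:::element_instance(lib$famA, age = t_true)
    date_insertion(ltr_identity(elem))
  }, numeric(1))
  # per-site divergence 2rt = 0.013 over 1 kb: binomial SE of the mean age
  se <- t_true * sqrt(0.013 * 0.987 / 1000 / 40) / 0.013
  expect_lt(abs(mean(ages) - t_true), 4 * se)
})

test_that("paralog search finds planted copies and merges nearby hits", {
  lib <- fixture_library()
  fam <- lib$famA
  bg <- fixture_dna(100000, seed = 93)
  inst <- fam$consensus
  g <- paste0(substring(bg, 1, 20000), inst,
              substring(bg, 20001, 50000), inst,
              substring(bg, 50001, 80000), inst,
              substring(bg, 80001, 100000))
  idx <- seed_index(c(chr1 = g))
  loci <- find_paralogs(fam, idx)
  expect_equal(nrow(loci), 3L)

  expect_equal(nrow(find_paralogs(fam, seed_index(c(chr1 = bg)))), 0L)

  # two copies 500 bp apart are merged and flagged
  g2 <- paste0(substring(bg, 1, 20000), inst, substring(bg, 20001, 20500),
               inst, substring(bg, 50001, 80000))
  loci2 <- find_paralogs(fam, seed_index(c(chr1 = g2)))
  expect_equal(nrow(loci2), 1L)
  expect_true(loci2$merged)

  noRT <- te_family("noRT", fixture_dna(2000, seed = 94), ltr_length = 300)
  expect_error(find_paralogs(noRT, idx), "rt_domain")
})

test_that("full elements are recovered only when both LTRs are present", {
  lib <- fixture_library()
  fam <- lib$famA
  bg <- fixture_dna(60000, seed = 95)
  g <- c(chr1 = paste0(substring(bg, 1, 30000), fam$consensus,
                       substring(bg, 30001, 60000)))
  idx <- seed_index(g)
  loci <- find_paralogs(fam, idx)
  el <- recover_full_element(loci[1, ], fam, g)
  expect_false(is.null(el))
  expect_lt(abs(el$start - 30000), 10)
  expect_lt(abs(el$end - (30000 + nchar(fam$consensus))), 10)
  expect_equal(ltr_identity(el, g), 1.0)

  # a solo LTR has no RT hit at all; a copy with one LTR truncated to 30%
  # fails the both-LTRs check
  ltr <- substring(fam$consensus, 1, fam$ltr_length)
  trunc <- paste0(substring(fam$consensus, 1, nchar(fam$consensus) - fam$ltr_length),
                  substring(ltr, 1, round(0.3 * fam$ltr_length)))
  g2 <- c(chr1 = paste0(substring(bg, 1, 30000), trunc,
                        substring(bg, 30001, 60000)))
  loci2 <- find_paralogs(fam, seed_index(g2))
  expect_equal(nrow(loci2), 1L)
  expect_null(recover_full_element(loci2[1, ], fam, g2))
})

test_that("classify_insertion is the deterministic 7-way mapping", {
  expect_equal(classify_insertion("present", "absent", "absent"), "Japonica-specific")
  expect_equal(classify_insertion("absent", "present", "absent"), "Indica-specific")
  expect_equal(classify_insertion("absent", "absent", "present"), "Aus-specific")
  expect_equal(classify_insertion("present", "present", "present"), "common-all")
  expect_equal(classify_insertion("present", "present", "absent"), "common-IndJap")
  expect_equal(classify_insertion("absent", "present", "present"), "common-IndAus")
  expect_equal(classify_insertion("present", "absent", "present"), "common-JapAus")
  expect_error(classify_insertion("absent", "absent", "absent"), "absent from all")
  expect_error(classify_insertion("present", "maybe", "absent"), "present")
  # exactly seven reachable categories
  combos <- expand.grid(j = c("present", "absent"), i = c("present", "absent"),
                        a = c("present", "absent"), stringsAsFactors = FALSE)
  cats <- apply(combos[-8, ], 1, function(x) classify_insertion(x[1], x[2], x[3]))
  expect_length(unique(cats), 7L)
})

test_that("category validation applies the 60%/80% group thresholds", {
  grp <- c(Japonica = 0, Indica = 0.6, `Aus/Boro` = 0)
  expect_true(validate_category("Indica-specific", grp)$validated)
  grp["Indica"] <- 0.59
  expect_false(validate_category("Indica-specific", grp)$validated)

  all80 <- c(Japonica = 0.8, Indica = 0.8, `Aus/Boro` = 0.8)
  expect_true(validate_category("common-all", all80)$validated)
  all80["Aus/Boro"] <- 0.79
  expect_false(validate_category("common-all", all80)$validated)
  expect_true(validate_category("common-IndJap",
                                c(Japonica = 0.85, Indica = 0.9,
                                  `Aus/Boro` = 0))$validated)
  res <- validate_category("common-all", NA_real_)
  expect_false(res$validated)
  expect_equal(res$reason, "no panel evidence")
})

test_that("ortholog search resolves present, absent and unresolved cases", {
  lib <- fixture_library()
  fam <- lib$famA
  trio <- simulate_assembly_trio(fam, n_per_category = 1L, seed = 96)
  truth <- trio$truth
  src <- trio$genomes$japonica
  iidx <- seed_index_with_seqs(trio$genomes$indica)

  jp_loci <- truth[!is.na(truth$start_japonica), ]
  ex_common <- jp_loci[jp_loci$category == "common-all", ][1, ]
  ex_spec <- jp_loci[jp_loci$category == "Japonica-specific", ][1, ]
  el_common <- list(family_id = fam$family_id, chrom = "chr1",
                    start = ex_common$start_japonica,
                    end = ex_common$start_japonica + nchar(fam$consensus))
  el_spec <- list(family_id = fam$family_id, chrom = "chr1",
                  start = ex_spec$start_japonica,
                  end = ex_spec$start_japonica + nchar(fam$consensus))
  expect_equal(find_ortholog(el_common, src, iidx, fam)$status, "present")
  expect_equal(find_ortholog(el_spec, src, iidx, fam)$status, "absent")

  # a flank inside a duplication is unresolved
  dup <- substring(src[[1]], ex_spec$start_japonica - 299, ex_spec$start_japonica)
  tgt2 <- seed_index_with_seqs(
    c(chr1 = paste0(trio$genomes$indica[[1]], dup, fixture_dna(5000, seed = 97),
                    dup)))
  expect_equal(find_ortholog(el_spec, src, tgt2, fam)$status, "unresolved")
  # contig edge
  el_edge <- list(family_id = fam$family_id, chrom = "chr1", start = 100,
                  end = 5100)
  expect_equal(find_ortholog(el_edge, src, iidx, fam)$status, "unresolved")
})

test_that("element frequencies join the matrix through source-assembly windows", {
  lib <- fixture_library()
  fam <- lib$famA
  trio <- simulate_assembly_trio(fam, n_per_category = 1L, seed = 98)
  pm <- trio_panel_matrix(trio, source = "japonica")
  jp <- trio$truth[!is.na(trio$truth$start_japonica), ]
  el <- list(family_id = fam$family_id, chrom = "chr1",
             start = jp$start_japonica[1])
  freq <- element_group_frequency(el, pm$matrix, pm$windows, pm$meta)
  expect_true(all(c("Japonica", "Indica", "Aus/Boro") %in% names(freq)))
  # an element with no matching row reports NA ("no panel evidence" upstream)
  el2 <- list(family_id = "ghost", chrom = "chr1", start = jp$start_japonica[1])
  expect_true(all(is.na(element_group_frequency(el2, pm$matrix, pm$windows,
                                                pm$meta))))
})

test_that("category age summaries report medians and quartiles", {
  dated <- data.frame(category = c("common-all", "common-all", "common-all",
                                   "Indica-specific"),
                      ltr_identity = c(0.99, 0.994, 0.996, 0.999),
                      age_years = date_insertion(c(0.99, 0.994, 0.996, 0.999)),
                      validated = TRUE)
  s <- category_age_distributions(dated)
  expect_equal(s$identity_median[s$category == "common-all"], 0.994)
  expect_equal(s$n[s$category == "Indica-specific"], 1L)
  expect_equal(s$identity_median[s$category == "Indica-specific"], 0.999)
})
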