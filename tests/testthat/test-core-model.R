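test_that("make_windows tiles chromosomes without gaps or overlaps", {
  w <- make_windows(c(chr1 = 25000))
  expect_equal(length(w), 3L)
  expect_equal(w$start0, c(0L, 10000L, 20000L))
  expect_equal(w$end0, c(10000L, 20000L, 25000L))
  expect_equal(w$window_id[2], "chr1:10000-20000")

  expect_equal(length(make_windows(c(chr1 = 10000))), 1L)

  w2 <- make_windows(c(chrA = 10000, chrB = 5000))
  expect_equal(length(w2), 2L)
  expect_setequal(as.character(GenomeInfoDb::seqnames(w2)), c("chrA", "chrB"))

  expect_error(make_windows(stats::setNames(numeric(0), character(0))),
               "no sequences")
})

test_that("window tiling partitions every chromosome for random lengths", {
  set.seed(42)
  for (len in sample.int(1e6, 25)) {
    w <- make_windows(c(chr = len))
    expect_equal(length(w), ceiling(len / 10000))
    expect_equal(w$start0[1], 0L)
    expect_equal(w$end0[length(w)], len)
    if (length(w) > 1) expect_equal(w$start0[-1], w$end0[-length(w)])
  }
})

test_that("window_of obeys half-open boundaries and matches a linear scan", {
  w <- make_windows(c(chr1 = 25000))
  expect_equal(window_of("chr1", 12345, w)$window_id, "chr1:10000-20000")
  expect_equal(window_of("chr1", 0, w)$window_id, "chr1:0-10000")
  expect_false(window_of("chr1", 9999, w)$window_id ==
                 window_of("chr1", 10000, w)$window_id)
  expect_error(window_of("chr1", 25000, w), "out of")
  expect_error(window_of("chr1", -1, w), "out of")

  set.seed(7)
  lens <- c(chrX = 53211, chrY = 104729)
  w2 <- make_windows(lens)
  chrom <- sample(names(lens), 500, replace = TRUE)
  pos <- floor(runif(500) * lens[chrom])
  got <- window_of(chrom, pos, w2)
  # brute-force linear scan over all windows
  for (i in sample.int(500, 100)) {
    hit <- which(as.character(GenomicRanges::seqnames(w2)) == chrom[i] &
                   w2$start0 <= pos[i] & pos[i] < w2$end0)
    expect_equal(got$window_id[i], w2$window_id[hit])
  }
})

test_that("read_te_library parses FASTA with optional sidecar features", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">famA", "acgtACGTacgtacgtacgtacgtacgtacgt",
               ">famB", "GGGGCCCCAAAATTTTGGGGCCCCAAAATTTT",
               ">famC", "ACGT"), fa)
  lib <- read_te_library(fa)
  expect_length(lib, 3L)
  expect_equal(lib$famA$consensus, toupper("acgtACGTacgtacgtacgtacgtacgtacgt"))
  expect_true(all(vapply(lib, function(f) is.na(f$ltr_length), logical(1))))

  side <- data.frame(family_id = "famA", superfamily = "Gypsy",
                     ltr_length = 8L, rt_start = 10L, rt_end = 20L)
  lib2 <- read_te_library(fa, side)
  expect_equal(lib2$famA$ltr_length, 8L)
  expect_equal(lib2$famA$superfamily, "Gypsy")
  expect_true(is.na(lib2$famB$ltr_length))

  bad <- data.frame(family_id = "nope", ltr_length = 5L)
  expect_error(read_te_library(fa, bad), "without FASTA record")

  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">dup", "ACGTACGT", ">dup", "ACGTACGT"), fa2)
  expect_error(read_te_library(fa2), "duplicate family_id")
})

test_that("te_family enforces its invariants", {
  expect_error(te_family("x", ""), "non-empty")
  expect_error(te_family("x", "ACGU"), "A,C,G,T,N")
  expect_error(te_family("x", strrep("A", 100), ltr_length = 51),
               "half the consensus")
  expect_error(te_family("x", strrep("A", 100), rt_start = 10, rt_end = 150),
               "within the consensus")
  expect_error(te_family("x", strrep("A", 100), rt_start = 10), "together")
})

test_that("BED5 writing round-trips and validates coordinates", {
  rec <- data.frame(chrom = "chr1", start = 10000L, end = 20000L,
                    name = "Hopi", score = 5)
  path <- tempfile(fileext = ".bed")
  write_bed(rec, path)
  expect_equal(readLines(path), "chr1\t10000\t20000\tHopi\t5")
  expect_equal(read_bed(path), rec)

  empty <- rec[0, ]
  write_bed(empty, path)
  expect_equal(file.size(path), 0)
  expect_equal(nrow(read_bed(path)), 0L)

  expect_error(write_bed(data.frame(chrom = "c", start = 5L, end = 5L,
                                    name = "x", score = 1), path),
               "start < end")
})

test_that("gene annotation is converted from 1-based GFF to half-open ranges", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
               "chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tID=g1.e1"), gff)
  genes <- read_genes(gff)
  expect_equal(length(genes), 1L)
  expect_equal(GenomicRanges::start(genes), 1001L)  # GRanges stays 1-based
  expect_equal(GenomicRanges::end(genes), 2000L)
  expect_equal(genes$gene_id, "g1")
})

test_that("accession metadata reader enforces unique ids", {
  meta <- read_accession_meta(data.frame(accession_id = c("a", "b"),
                                         group = c("Indica", "Japonica")))
  expect_true(all(is.na(meta$zone)))
  expect_error(read_accession_meta(data.frame(accession_id = c("a", "a"),
                                              group = "Indica")),
               "unique")
})
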