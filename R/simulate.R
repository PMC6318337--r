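# Ground-truth simulator: synthetic references with planted repeats, TE family
# consensi, accession panels with insertions at controlled frequencies/ages,
# and short/long read generation. Every generator is deterministic for a
# fixed seed.

random_dna <- function(n, gc = 0.44) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute bases at `rate` across a character vector of sequences; every
# substitution changes the base.
inject_substitutions <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  widths <- nchar(reads)
  total <- sum(widths)
  big <- charToRaw(paste0(reads, collapse = ""))
  n_err <- stats::rbinom(1, total, rate)
  if (n_err == 0) return(reads)
  at <- sample.int(total, n_err)
  bases <- charToRaw("ACGT")
  repl <- bases[sample.int(4, n_err, replace = TRUE)]
  same <- repl == big[at]
  while (any(same)) {
    repl[same] <- bases[sample.int(4, sum(same), replace = TRUE)]
    same <- repl == big[at]
  }
  big[at] <- repl
  out <- substring(rawToChar(big), cumsum(widths) - widths + 1, cumsum(widths))
  names(out) <- names(reads)
  out
}

# Substitutions + indels on one sequence (long-read error model).
mutate_with_indels <- function(s, sub_rate, ins_rate, del_rate) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  ns <- stats::rbinom(1, n, sub_rate)
  if (ns > 0) {
    at <- sample.int(n, ns)
    alt <- c("A", "C", "G", "T")
    repl <- alt[sample.int(4, ns, replace = TRUE)]
    same <- repl == v[at]
    while (any(same)) {
      repl[same] <- alt[sample.int(4, sum(same), replace = TRUE)]
      same <- repl == v[at]
    }
    v[at] <- repl
  }
  nd <- stats::rbinom(1, length(v), del_rate)
  if (nd > 0) v <- v[-sample.int(length(v), nd)]
  ni <- stats::rbinom(1, length(v), ins_rate)
  if (ni > 0) {
    at <- sort(sample.int(length(v), ni), decreasing = TRUE)
    ins <- c("A", "C", "G", "T")[sample.int(4, ni, replace = TRUE)]
    for (j in seq_len(ni)) v <- append(v, ins[j], after = at[j])
  }
  paste(v, collapse = "")
}

#' Simulate a reference genome with planted repeats
#'
#' An i.i.d. background plus planted duplicated blocks (a source block copied
#' over another location) totalling `repeat_fraction` of the genome, to
#' exercise mappability. Emits the repeat annotation alongside.
#'
#' @param length Genome length in bp (>= 1e5).
#' @param gc GC content.
#' @param repeat_fraction Target fraction of the genome covered by duplicated
#'   blocks (source + copy), in `[0, 1)`.
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @param block_range Min/max duplicated block length in bp.
#' @return List of class `sim_reference`: `genome` (named character),
#'   `repeats` (data frame `chrom`, `start`, `end`, `name`, `score` -- BED5
#'   layout, 0-based half-open), `params`.
#' @export
simulate_reference <- function(length = 2e6, gc = 0.44, repeat_fraction = 0.4,
                               seed = 1L, chrom = "chr1",
                               block_range = c(5000, 25000)) {
  if (length < 1e5) stop("length must be >= 1e5")
  if (repeat_fraction >= 1) stop("repeat_fraction must be < 1")
  set.seed(seed)
  g <- random_dna(length, gc)
  covered <- logical(length)
  ann <- list()
  guard <- 0L
  while (mean(covered) < repeat_fraction && guard < 10000L) {
    guard <- guard + 1L
    bl <- sample(block_range[1]:block_range[2], 1)
    # clamp the final block so realised coverage lands near the target
    deficit <- ceiling((repeat_fraction - mean(covered)) * length / 2)
    bl <- max(500L, min(bl, deficit + 250L))
    src <- sample.int(length - bl, 1)           # 1-based start
    dst <- sample.int(length - bl, 1)
    if (abs(dst - src) < bl) next               # keep source and copy disjoint
    block <- substring(g, src, src + bl - 1)
    g <- paste0(substring(g, 1, dst - 1), block, substring(g, dst + bl, length))
    covered[src:(src + bl - 1)] <- TRUE
    covered[dst:(dst + bl - 1)] <- TRUE
    ann[[base::length(ann) + 1L]] <- data.frame(
      chrom = chrom, start = c(src, dst) - 1L, end = c(src, dst) + bl - 1L,
      name = sprintf("rep%03d", guard), score = bl)
  }
  repeats <- if (base::length(ann)) do.call(rbind, ann) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = numeric(0))
  structure(list(genome = stats::setNames(g, chrom), repeats = repeats,
                 params = list(length = length, gc = gc,
                               repeat_fraction = repeat_fraction, seed = seed)),
            class = "sim_reference")
}

#' Simulate an LTR-retrotransposon family consensus
#'
#' Consensus of the form LTR--internal--LTR with the RT-domain interval set to
#' a central stretch of the internal region.
#'
#' @param family_id Family name.
#' @param ltr_length,internal_length Lengths in bp.
#' @param superfamily `"Gypsy"` or `"Copia"` (or others).
#' @param gc GC content.
#' @param seed RNG seed.
#' @return A [te_family()].
#' @export
simulate_te_family <- function(family_id, ltr_length = 400L,
                               internal_length = 4200L, superfamily = "Gypsy",
                               gc = 0.44, seed = 1L) {
  set.seed(seed)
  ltr <- random_dna(ltr_length, gc)
  internal <- random_dna(internal_length, gc)
  cons <- paste0(ltr, internal, ltr)
  rt_len <- min(800L, max(200L, internal_length %/% 3L))
  rt_start <- ltr_length + (internal_length - rt_len) %/% 2L
  te_family(family_id, cons, superfamily = superfamily, ltr_length = ltr_length,
            rt_start = rt_start, rt_end = rt_start + rt_len)
}

# Build one element instance whose two LTRs have diverged for `age` years at
# `rate` substitutions/site/year (each LTR copy mutated independently at
# probability rate*age per site, total divergence 2*rate*age).
element_instance <- function(family, age = 0, rate = 1.3e-8) {
  L <- family$ltr_length
  cons <- family$consensus
  ltr <- substring(cons, 1, L)
  internal <- substring(cons, L + 1, nchar(cons) - L)
  p <- rate * age
  ltr5 <- if (p > 0) inject_substitutions(ltr, p) else ltr
  ltr3 <- if (p > 0) inject_substitutions(ltr, p) else ltr
  paste0(ltr5, internal, ltr3)
}

# Splice an element into `g` before 0-based position pos, duplicating the
# `tsd` bases immediately left of the insertion point (target-site
# duplication).
splice_insertion <- function(g, pos, element, tsd = 5L) {
  paste0(substring(g, 1, pos), element,
         substring(g, pos - tsd + 1, pos), substring(g, pos + 1, nchar(g)))
}

# Draw per-locus population frequencies. The L-shaped law is log10-uniform on
# [1e-3, 1]: a third of loci sit below frequency 0.01, emulating spectra
# dominated by insertions seen in one or two accessions.
draw_frequencies <- function(n_loci, frequency_law = c("lshape", "constant"),
                             const_freq = 0.5) {
  frequency_law <- match.arg(frequency_law)
  switch(frequency_law,
         lshape = 10^stats::runif(n_loci, -3, 0),
         constant = rep(const_freq, n_loci))
}

# Carrier count from Binomial(n, f) conditioned on >= 1 carrier.
draw_carriers <- function(n_acc, freq) {
  pr <- stats::dbinom(seq_len(n_acc), n_acc, freq)
  if (sum(pr) <= 0) return(1L)
  sample.int(n_acc, 1, prob = pr)
}

#' Simulate a panel of accession genomes with TE insertions
#'
#' Places `n_loci` insertion loci on the reference (uniformly, pairwise
#' separated by at least `min_gap`), assigns each a population frequency from
#' `frequency_law`, draws carrier accessions per locus (conditioned on at
#' least one carrier), and splices a full element (LTR-internal-LTR with a
#' `tsd`-bp target-site duplication) into every carrier genome.
#'
#' @param reference A `sim_reference` or a named character genome.
#' @param library A `te_library` of LTR families (loci are assigned to
#'   families round-robin).
#' @param n_accessions,n_loci Panel dimensions.
#' @param frequency_law `"lshape"` (default) or `"constant"`.
#' @param const_freq Frequency used when `frequency_law = "constant"`.
#' @param ages Insertion age(s) in years (recycled over loci); controls
#'   LTR-LTR divergence of the spliced elements.
#' @param rate Molecular-clock rate for the divergence simulation.
#' @param tsd Target-site duplication length.
#' @param min_gap Minimum distance between loci (and from chromosome ends).
#' @param positions Optional explicit 0-based breakpoints (length `n_loci`);
#'   when `NULL`, loci are placed uniformly.
#' @param seed RNG seed.
#' @param max_tries Placement retries before failing.
#' @return List of class `sim_panel`: `genomes` (named list of named character
#'   genomes), `truth` (data frame `locus_id`, `family_id`, `chrom`, `pos`
#'   (0-based reference breakpoint), `frequency`, `carriers`, `age`),
#'   `carrier_matrix` (loci x accessions logical), `reference`, `params`.
#' @export
simulate_panel <- function(reference, library, n_accessions = 12L, n_loci = 60L,
                           frequency_law = "lshape", const_freq = 0.5,
                           ages = 0, rate = 1.3e-8, tsd = 5L, min_gap = 1000L,
                           positions = NULL, seed = 1L, max_tries = 10000L) {
  set.seed(seed)
  ref <- if (inherits(reference, "sim_reference")) reference$genome else reference
  chrom <- names(ref)[1]
  g <- ref[[1]]
  len <- nchar(g)
  if (!is.null(positions)) {
    stopifnot(length(positions) == n_loci)
    pos <- sort(as.integer(positions))
  } else {
    pos <- integer(0); tries <- 0L
    while (length(pos) < n_loci) {
      tries <- tries + 1L
      if (tries > max_tries) stop("could not place loci without overlap")
      cand <- sample(seq(min_gap, len - min_gap), 1)
      if (all(abs(cand - pos) >= min_gap)) pos <- c(pos, cand)
    }
    pos <- sort(pos)
  }
  fams <- rep(names(library), length.out = n_loci)
  freqs <- draw_frequencies(n_loci, frequency_law, const_freq)
  ages <- rep(ages, length.out = n_loci)
  accs <- sprintf("acc%02d", seq_len(n_accessions))
  carrier <- matrix(FALSE, n_loci, n_accessions, dimnames = list(NULL, accs))
  elements <- character(n_loci)
  for (i in seq_len(n_loci)) {
    k <- draw_carriers(n_accessions, freqs[i])
    carrier[i, sample.int(n_accessions, k)] <- TRUE
    elements[i] <- element_instance(library[[fams[i]]], age = ages[i], rate = rate)
  }
  genomes <- lapply(accs, function(a) {
    ga <- g
    idx <- which(carrier[, a])
    for (i in rev(idx))  # apply right-to-left so positions stay valid
      ga <- splice_insertion(ga, pos[i], elements[i], tsd = tsd)
    stats::setNames(ga, chrom)
  })
  names(genomes) <- accs
  truth <- data.frame(locus_id = sprintf("locus%03d", seq_len(n_loci)),
                      family_id = fams, chrom = chrom, pos = pos,
                      frequency = freqs, carriers = rowSums(carrier),
                      age = ages, stringsAsFactors = FALSE)
  structure(list(genomes = genomes, truth = truth, carrier_matrix = carrier,
                 reference = stats::setNames(g, chrom),
                 params = list(n_accessions = n_accessions, n_loci = n_loci,
                               frequency_law = frequency_law, seed = seed,
                               tsd = tsd, rate = rate)),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %d accessions, %d loci, %d families\n",
              length(x$genomes), nrow(x$truth), length(unique(x$truth$family_id))))
  invisible(x)
}

#' Generate paired-end reads from a genome
#'
#' `round(coverage * genome_length / (2 * read_len))` pairs; fragments sampled
#' uniformly with Normal insert sizes, mates on opposite strands (FR), uniform
#' substitution errors, constant Phred-30 qualities when written as FASTQ.
#'
#' @param genome Named character genome (single sequence) or `sim_reference`.
#' @param coverage Fold coverage (> 0).
#' @param read_len Read length.
#' @param insert_mean,insert_sd Insert-size distribution (mean must be at
#'   least `2 * read_len`).
#' @param error_rate Per-base substitution rate.
#' @param seed RNG seed.
#' @param out_prefix If non-NULL, write `<prefix>_1.fastq` / `<prefix>_2.fastq`
#'   and return the paths; otherwise return the reads in memory.
#' @return List `mate1`, `mate2` (named character vectors, pair ids as names)
#'   or, with `out_prefix`, `fq1`/`fq2` paths.
#' @export
generate_reads <- function(genome, coverage, read_len = 100L, insert_mean = 350,
                           insert_sd = 50, error_rate = 0.005, seed = 1L,
                           out_prefix = NULL) {
  if (coverage <= 0) stop("coverage must be positive")
  if (insert_mean < 2 * read_len) stop("insert_mean must be >= 2 * read_len")
  set.seed(seed)
  if (inherits(genome, "sim_reference")) genome <- genome$genome
  g <- genome[[1]]
  len <- nchar(g)
  n <- round(coverage * len / (2 * read_len))
  isz <- pmax(2 * read_len, round(stats::rnorm(n, insert_mean, insert_sd)))
  isz <- pmin(isz, len)
  start <- floor(stats::runif(n) * (len - isz)) + 1  # 1-based fragment start
  left <- substring(g, start, start + read_len - 1)
  right <- revcomp_chr(substring(g, start + isz - read_len, start + isz - 1))
  # fragment sequenced from either strand with equal probability
  flip <- stats::runif(n) < 0.5
  m1 <- ifelse(flip, right, left)
  m2 <- ifelse(flip, left, right)
  m1 <- inject_substitutions(m1, error_rate)
  m2 <- inject_substitutions(m2, error_rate)
  ids <- sprintf("frag%07d", seq_len(n))
  names(m1) <- ids; names(m2) <- ids
  if (is.null(out_prefix)) return(list(mate1 = m1, mate2 = m2))
  fq <- function(reads, path) {
    qual <- strrep("?", read_len)  # Phred 30
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), path)
    path
  }
  list(fq1 = fq(m1, paste0(out_prefix, "_1.fastq")),
       fq2 = fq(m2, paste0(out_prefix, "_2.fastq")))
}

#' Generate long reads from a genome
#'
#' Read lengths follow a log-normal law (default median 8 kb); errors are
#' substitutions and short indels at `error_rate` total (60% substitutions,
#' 20% insertions, 20% deletions). Reads are drawn until total bases reach
#' `coverage * genome_length`.
#'
#' @param genome Named character genome (single sequence) or `sim_reference`.
#' @param coverage Fold coverage.
#' @param length_meanlog,length_sdlog Log-normal length parameters.
#' @param error_rate Total per-base error rate.
#' @param seed RNG seed.
#' @param out If non-NULL, write FASTA there and return the path.
#' @return Named character vector of reads (names carry the true origin as
#'   `readN|chrom|start|strand`), or the FASTA path.
#' @export
generate_long_reads <- function(genome, coverage, length_meanlog = log(8000),
                                length_sdlog = 0.4, error_rate = 0.08,
                                seed = 1L, out = NULL) {
  if (coverage <= 0) stop("coverage must be positive")
  set.seed(seed)
  if (inherits(genome, "sim_reference")) genome <- genome$genome
  g <- genome[[1]]
  chrom <- names(genome)[1]
  len <- nchar(g)
  target <- coverage * len
  lens <- integer(0)
  while (sum(lens) < target)
    lens <- c(lens, pmin(len, pmax(500L, round(stats::rlnorm(200, length_meanlog,
                                                             length_sdlog)))))
  lens <- lens[seq_len(which(cumsum(lens) >= target)[1])]
  n <- length(lens)
  start <- floor(stats::runif(n) * (len - lens)) + 1
  reads <- substring(g, start, start + lens - 1)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  reads[strand == "-"] <- revcomp_chr(reads[strand == "-"])
  if (error_rate > 0) {
    reads <- vapply(reads, mutate_with_indels, character(1),
                    sub_rate = 0.6 * error_rate, ins_rate = 0.2 * error_rate,
                    del_rate = 0.2 * error_rate, USE.NAMES = FALSE)
  }
  names(reads) <- sprintf("read%05d|%s|%d|%s", seq_len(n), chrom, start - 1L, strand)
  if (is.null(out)) return(reads)
  writeLines(paste0(">", names(reads), "\n", reads), out)
  out
}

#' Score detected TIP events against simulator truth
#'
#' A detected (family, window) event matches a truth locus when the window
#' overlaps `[pos - slack, pos + slack]` of a same-family truth breakpoint:
#' junction evidence legitimately spans two adjacent windows when a breakpoint
#' lies near a window boundary, and at the method's 10-kb resolution both
#' windows are true detections of that locus. Recall counts matched truth
#' loci; precision counts matched detected events. With a mappability track,
#' both are restricted to windows at or above `min_mappability`.
#'
#' @param result A `tip_result` or a `tip_matrix`.
#' @param truth Truth loci (`family_id`, `chrom`, `pos`), e.g.
#'   `sim_panel$truth`.
#' @param windows Windows used for detection (taken from a `tip_result`).
#' @param mappability Optional [window_mappability()] track.
#' @param min_mappability Mappability cut-off for both recall and precision.
#' @param slack Breakpoint tolerance in bp.
#' @return List: `recall`, `precision`, `n_truth`, `n_events`, `truth`
#'   (with `detected` flag), `events` (with `matched` flag).
#' @export
score_detection <- function(result, truth, windows = NULL, mappability = NULL,
                            min_mappability = 0, slack = 500L) {
  mat <- if (inherits(result, "tip_result")) result$matrix else result
  if (is.null(windows) && inherits(result, "tip_result")) windows <- result$windows
  ev <- if (nrow(mat)) cbind(parse_event_id(rownames(mat)),
                             parse_window_id(parse_event_id(rownames(mat))$window_id))
        else data.frame(family_id = character(0), window_id = character(0),
                        chrom = character(0), start = integer(0), end = integer(0))
  truth <- as.data.frame(truth)
  tr_widx <- window_index_of(truth$chrom, truth$pos, windows)
  truth$window_id <- windows$window_id[tr_widx]
  if (!is.null(mappability)) {
    truth$mappability <- unname(mappability[truth$window_id])
    ev$mappability <- if (nrow(ev)) unname(mappability[ev$window_id]) else numeric(0)
  } else {
    truth$mappability <- 1; ev$mappability <- rep(1, nrow(ev))
  }
  match_one <- function(fam, chrom, s, e) {
    any(truth$family_id == fam & truth$chrom == chrom &
          truth$pos >= s - slack & truth$pos < e + slack)
  }
  ev$matched <- if (nrow(ev))
    vapply(seq_len(nrow(ev)), function(i)
      match_one(ev$family_id[i], ev$chrom[i], ev$start[i], ev$end[i]),
      logical(1)) else logical(0)
  truth$detected <- vapply(seq_len(nrow(truth)), function(i) {
    any(ev$family_id == truth$family_id[i] & ev$chrom == truth$chrom[i] &
          truth$pos[i] >= ev$start - slack & truth$pos[i] < ev$end + slack)
  }, logical(1))
  tkeep <- truth$mappability >= min_mappability
  ekeep <- ev$mappability >= min_mappability
  list(recall = if (any(tkeep)) mean(truth$detected[tkeep]) else NA_real_,
       precision = if (any(ekeep)) mean(ev$matched[ekeep]) else NA_real_,
       n_truth = sum(tkeep), n_events = sum(ekeep),
       truth = truth, events = ev)
}

#' Simulate three related assemblies with category-controlled insertions
#'
#' A shared backbone is copied into a Japonica-like, an Indica-like and an
#' Aus/Boro-like assembly; each insertion locus is assigned one of the seven
#' presence categories and the corresponding element (with LTRs diverged for
#' the category's age) is spliced into exactly the implicated assemblies at
#' the orthologous position.
#'
#' @param family A [te_family()].
#' @param n_per_category Elements per category.
#' @param ages Named ages (years) per category; defaults make shared
#'   insertions older than specific ones.
#' @param backbone_length Backbone length in bp.
#' @param spacing Minimum distance between loci (keep > `downstream` of
#'   [find_ortholog()] to avoid cross-talk).
#' @param rate Molecular-clock rate.
#' @param seed RNG seed.
#' @return List of class `sim_trio`: `genomes` (named list `japonica`,
#'   `indica`, `aus`), `truth` (locus table with per-genome realized starts),
#'   `family`, `params`.
#' @export
simulate_assembly_trio <- function(family, n_per_category = 3L,
                                   ages = c("Japonica-specific" = 230000,
                                            "Indica-specific" = 230000,
                                            "Aus-specific" = 380000,
                                            "common-all" = 1000000,
                                            "common-IndJap" = 800000,
                                            "common-IndAus" = 540000,
                                            "common-JapAus" = 800000),
                                   backbone_length = NULL, spacing = 20000L,
                                   rate = 1.3e-8, seed = 1L) {
  set.seed(seed)
  cats <- names(ages)
  n_loci <- length(cats) * n_per_category
  if (is.null(backbone_length)) backbone_length <- (n_loci + 2L) * spacing
  backbone <- random_dna(backbone_length)
  pos <- spacing * seq_len(n_loci) + sample.int(2000L, n_loci, replace = TRUE)
  cat_of <- rep(cats, each = n_per_category)[sample.int(n_loci)]
  flags <- list("Japonica-specific" = c(TRUE, FALSE, FALSE),
                "Indica-specific" = c(FALSE, TRUE, FALSE),
                "Aus-specific" = c(FALSE, FALSE, TRUE),
                "common-all" = c(TRUE, TRUE, TRUE),
                "common-IndJap" = c(TRUE, TRUE, FALSE),
                "common-IndAus" = c(FALSE, TRUE, TRUE),
                "common-JapAus" = c(TRUE, FALSE, TRUE))
  gnames <- c("japonica", "indica", "aus")
  elements <- vapply(seq_len(n_loci), function(i)
    element_instance(family, age = ages[[cat_of[i]]], rate = rate), character(1))
  elen <- nchar(elements)
  genomes <- list(); starts <- matrix(NA_real_, n_loci, 3,
                                      dimnames = list(NULL, gnames))
  for (k in seq_along(gnames)) {
    gk <- backbone
    present <- vapply(cat_of, function(cc) flags[[cc]][k], logical(1))
    offset <- 0
    for (i in seq_len(n_loci)) {   # ascending; track cumulative offset
      if (!present[i]) next
      gk <- splice_insertion(gk, pos[i] + offset, elements[i], tsd = 5L)
      starts[i, k] <- pos[i] + offset
      offset <- offset + elen[i] + 5L
    }
    genomes[[gnames[k]]] <- stats::setNames(gk, "chr1")
  }
  truth <- data.frame(locus_id = sprintf("locus%02d", seq_len(n_loci)),
                      category = cat_of, age = unname(ages[cat_of]),
                      pos_backbone = pos,
                      start_japonica = starts[, "japonica"],
                      start_indica = starts[, "indica"],
                      start_aus = starts[, "aus"], stringsAsFactors = FALSE)
  structure(list(genomes = genomes, truth = truth, family = family,
                 params = list(seed = seed, rate = rate, spacing = spacing)),
            class = "sim_trio")
}

#' Panel matrix and metadata consistent with a simulated assembly trio
#'
#' Synthesises a TIP presence/absence matrix (windowed on the chosen source
#' assembly) and accession metadata whose per-group carrier frequencies make
#' every planted category pass its validation thresholds: specific insertions
#' at `specific_freq` in their own group, common insertions at `common_freq`
#' in each implicated group.
#'
#' @param trio A `sim_trio`.
#' @param source Assembly the matrix windows refer to (elements absent from
#'   this assembly get no row).
#' @param n_per_group Accessions per varietal group.
#' @param specific_freq,common_freq Planted carrier frequencies.
#' @param window_size Window size.
#' @return List: `matrix` (`tip_matrix`), `meta`, `windows`.
#' @export
trio_panel_matrix <- function(trio, source = "japonica", n_per_group = 10L,
                              specific_freq = 0.7, common_freq = 0.9,
                              window_size = 10000L) {
  start_col <- paste0("start_", source)
  truth <- trio$truth[!is.na(trio$truth[[start_col]]), , drop = FALSE]
  windows <- make_windows(trio$genomes[[source]], size = window_size)
  groups <- c("Japonica", "Indica", "Aus/Boro")
  meta <- data.frame(
    accession_id = sprintf("%s%02d", rep(c("jap", "ind", "aus"), each = n_per_group),
                           rep(seq_len(n_per_group), 3)),
    group = rep(groups, each = n_per_group), stringsAsFactors = FALSE)
  freq_for <- function(category) {
    f <- stats::setNames(rep(0, 3), groups)
    imp <- switch(category,
                  "Japonica-specific" = "Japonica", "Indica-specific" = "Indica",
                  "Aus-specific" = "Aus/Boro", "common-all" = groups,
                  "common-IndJap" = c("Indica", "Japonica"),
                  "common-IndAus" = c("Indica", "Aus/Boro"),
                  "common-JapAus" = c("Japonica", "Aus/Boro"))
    f[imp] <- if (length(imp) == 1L) specific_freq else common_freq
    f
  }
  calls <- list()
  for (i in seq_len(nrow(truth))) {
    widx <- window_index_of("chr1", truth[[start_col]][i], windows)
    f <- freq_for(truth$category[i])
    for (grp in groups) {
      k <- round(f[[grp]] * n_per_group)
      if (k == 0) next
      acc <- meta$accession_id[meta$group == grp][seq_len(k)]
      calls[[length(calls) + 1L]] <- data.frame(
        accession_id = acc, family_id = trio$family$family_id,
        window_id = windows$window_id[widx], stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  mat <- build_matrix(calls, meta$accession_id)
  list(matrix = mat, meta = meta, windows = windows)
}
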