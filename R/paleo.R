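#' Find paralogous loci of a TE family in an assembly
#'
#' Aligns the family's RT-domain probe (or a configured alternative probe
#' interval, for LARD-like families without coding capacity) against the
#' genome; significant placements within one consensus length of each other
#' are merged into a single candidate locus.
#'
#' @param family A [te_family()] with `rt_start`/`rt_end` set.
#' @param genome_index [seed_index()] over the assembly (or a genome).
#' @param min_cov,min_identity Probe significance gate (fraction of probe
#'   length covered, identity).
#' @return Data frame of candidate loci: `chrom`, `start`, `end` (probe hit
#'   bounds, 0-based half-open), `n_hits`, `merged` (TRUE when several probe
#'   hits were collapsed).
#' @export
find_paralogs <- function(family, genome_index, min_cov = 0.5, min_identity = 0.8) {
  if (is.na(family$rt_start))
    stop("family ", family$family_id,
         " has no rt_domain (or configured probe interval)")
  idx <- if (inherits(genome_index, "seed_index")) genome_index else
    seed_index(genome_index)
  probe <- substring(family$consensus, family$rt_start + 1L, family$rt_end)
  aln <- align_to_index(idx, probe, min_score = 30L, max_hits = 512L,
                        max_cand = 512L, max_occ = 2048L)
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      n_hits = integer(0), merged = logical(0))
  if (nrow(aln) == 0L) return(empty)
  qual <- aln[(aln$qend - aln$qstart) >= min_cov * nchar(probe) &
                aln$identity >= min_identity, , drop = FALSE]
  if (nrow(qual) == 0L) return(empty)
  span <- nchar(family$consensus)
  qual <- qual[order(qual$target, qual$tstart), , drop = FALSE]
  loci <- list(); cur <- qual[1, ]
  cur_n <- 1L
  flush <- function(cur, n) data.frame(chrom = cur$target, start = cur$tstart,
                                       end = cur$tend, n_hits = n, merged = n > 1L)
  if (nrow(qual) > 1) for (i in 2:nrow(qual)) {
    h <- qual[i, ]
    if (h$target == cur$target && h$tstart - cur$tend <= span) {
      cur$tend <- max(cur$tend, h$tend); cur_n <- cur_n + 1L
    } else {
      loci[[length(loci) + 1L]] <- flush(cur, cur_n); cur <- h; cur_n <- 1L
    }
  }
  loci[[length(loci) + 1L]] <- flush(cur, cur_n)
  do.call(rbind, loci)
}

#' Recover a full element around a paralog locus
#'
#' Extends the probe hit by `extend` times the consensus length on both sides
#' and searches the extension for both LTRs (consensus LTR vs the region).
#' Returns `NULL` unless an upstream and a downstream LTR are found; the
#' element is trimmed to the outer LTR bounds.
#'
#' @param locus One row of [find_paralogs()].
#' @param family The [te_family()] (must have `ltr_length`).
#' @param genome Genome (named character / `DNAStringSet`).
#' @param extend Extension factor (times consensus length, each side).
#' @param min_cov,min_identity LTR hit gate (fraction of LTR length, identity).
#' @return A `full_element` list (`chrom`, `start`, `end`, `ltr5`, `ltr3`
#'   half-open intervals in genome coordinates, `family_id`) or `NULL`.
#' @export
recover_full_element <- function(locus, family, genome, extend = 1.5,
                                 min_cov = 0.8, min_identity = 0.8) {
  if (is.na(family$ltr_length)) stop("family has no LTR length")
  g <- genome_as_character(genome)
  span <- nchar(family$consensus)
  chrom <- locus$chrom[1]
  lo <- max(0, locus$start[1] - extend * span)
  hi <- min(nchar(g[[chrom]]), locus$end[1] + extend * span)
  region <- substring(g[[chrom]], lo + 1, hi)
  ltr <- substring(family$consensus, 1L, family$ltr_length)
  aln <- local_align(ltr, stats::setNames(region, "region"), min_score = 30L,
                     max_hits = 8L)
  qual <- aln[(aln$qend - aln$qstart) >= min_cov * family$ltr_length &
                aln$identity >= min_identity & aln$strand == "+", , drop = FALSE]
  if (nrow(qual) < 2L) return(NULL)
  qual <- qual[order(qual$tstart), , drop = FALSE]
  first <- qual[1, ]; last <- qual[nrow(qual), ]
  # the two LTRs must be separated by a plausible internal region
  if (last$tstart - first$tend < 0.2 * (span - 2 * family$ltr_length)) return(NULL)
  structure(list(family_id = family$family_id, chrom = chrom,
                 start = lo + first$tstart, end = lo + last$tend,
                 ltr5 = c(lo + first$tstart, lo + first$tend),
                 ltr3 = c(lo + last$tstart, lo + last$tend)),
            class = "full_element")
}

#' @export
print.full_element <- function(x, ...) {
  cat(sprintf("<full_element> %s %s:[%.0f,%.0f) LTR5 [%.0f,%.0f) LTR3 [%.0f,%.0f)\n",
              x$family_id, x$chrom, x$start, x$end, x$ltr5[1], x$ltr5[2],
              x$ltr3[1], x$ltr3[2]))
  invisible(x)
}

#' LTR-LTR identity of a full element
#'
#' Splits the trimmed element into two equal halves and aligns one half
#' against the other: only the LTRs produce an alignment, and the identity of
#' the largest local alignment (HSP) between them estimates their divergence.
#'
#' @param element A `full_element` (with `genome`) or a raw element sequence.
#' @param genome Genome, required when `element` is a `full_element`.
#' @return Identity fraction in `[0, 1]`.
#' @export
ltr_identity <- function(element, genome = NULL) {
  seq <- if (inherits(element, "full_element")) {
    g <- genome_as_character(genome)
    substring(g[[element$chrom]], element$start + 1, element$end)
  } else .ts_uc(element)
  half <- nchar(seq) %/% 2L
  h1 <- substring(seq, 1L, half)
  h2 <- substring(seq, half + 1L, nchar(seq))
  aln <- local_align(h1, stats::setNames(h2, "half2"), min_score = 20L,
                     max_hits = 4L, both_strands = FALSE)
  if (nrow(aln) == 0L)
    stop("no alignment between element halves; LTRs not recoverable")
  aln <- aln[which.max(aln$aln_len), ]
  aln$matches / aln$aln_len
}

#' Date an insertion from LTR-LTR identity under a molecular clock
#'
#' The two LTRs of an element are identical at insertion time; their raw
#' divergence `1 - identity` accumulates at twice the substitution rate, so
#' `age = (1 - identity) / (2 * rate)`. No multiple-hit correction is applied
#' by default (divergence is taken as the raw mismatch fraction); a
#' Jukes-Cantor correction is available behind `correction = "JC69"`.
#'
#' @param identity LTR-LTR identity fraction(s) in `[0, 1]`.
#' @param rate Substitution rate per site per year (default 1.3e-8).
#' @param correction `"none"` (default) or `"JC69"`.
#' @return Age(s) in years.
#' @export
date_insertion <- function(identity, rate = 1.3e-8, correction = c("none", "JC69")) {
  correction <- match.arg(correction)
  if (rate <= 0) stop("rate must be positive")
  if (any(identity < 0 | identity > 1)) stop("identity must be in [0, 1]")
  d <- 1 - identity
  if (correction == "JC69") d <- -3 / 4 * log(1 - 4 / 3 * d)
  d / (2 * rate)
}

#' Classify an insertion by presence across three assemblies
#'
#' Deterministic 7-way mapping from presence/absence in a Japonica-like,
#' an Indica-like and an Aus/Boro-like assembly. All three flags must be
#' resolved (`"present"`/`"absent"`); elements with an unresolved ortholog
#' call are excluded upstream.
#'
#' @param japonica,indica,aus `"present"` or `"absent"`.
#' @return One of `"Japonica-specific"`, `"Indica-specific"`, `"Aus-specific"`,
#'   `"common-all"`, `"common-IndJap"`, `"common-IndAus"`, `"common-JapAus"`.
#' @export
classify_insertion <- function(japonica, indica, aus) {
  flags <- c(japonica = japonica, indica = indica, aus = aus)
  if (!all(flags %in% c("present", "absent")))
    stop("all flags must be 'present' or 'absent'")
  p <- flags == "present"
  key <- paste(ifelse(p, "P", "A"), collapse = "")
  switch(key,
         "PAA" = "Japonica-specific",
         "APA" = "Indica-specific",
         "AAP" = "Aus-specific",
         "PPP" = "common-all",
         "PPA" = "common-IndJap",
         "APP" = "common-IndAus",
         "PAP" = "common-JapAus",
         "AAA" = stop("element absent from all three assemblies"))
}

#' Test an element for presence at the orthologous locus of another assembly
#'
#' Extracts 300 bp immediately upstream of the element in its source assembly
#' and aligns it to the target assembly. The flank must produce exactly one
#' placement covering at least `min_flank_cov` of its length (else
#' `unresolved`). The `downstream` bp following the flank placement in the
#' target are then searched for the family consensus: a significant match
#' means `present`, otherwise `absent`.
#'
#' @param element A `full_element` (coordinates in the source assembly).
#' @param source_genome Source assembly (named character / `DNAStringSet`).
#' @param target_index [seed_index()] over the target assembly (or a genome).
#' @param family The [te_family()].
#' @param flank,downstream Flank and downstream search lengths in bp.
#' @param min_flank_cov Minimum fraction of the flank that must align.
#' @param min_te_len,min_te_identity Consensus hit gate in the downstream
#'   stretch.
#' @return List: `status` in `{"present","absent","unresolved"}`, `reason`.
#' @export
find_ortholog <- function(element, source_genome, target_index, family,
                          flank = 300L, downstream = 15000L,
                          min_flank_cov = 0.9, min_te_len = 200L,
                          min_te_identity = 0.8) {
  g <- genome_as_character(source_genome)
  if (element$start < flank)
    return(list(status = "unresolved", reason = "element at contig edge"))
  idx <- if (inherits(target_index, "seed_index")) target_index else
    seed_index(target_index)
  up <- substring(g[[element$chrom]], element$start - flank + 1, element$start)
  anc <- anchor_reads(up, idx, min_len = as.integer(min_flank_cov * flank),
                      min_identity = 0.9)
  if (anc$uniqueness[1] != "unique") {
    reason <- if (anc$uniqueness[1] == "none") "flank has no qualifying hit"
              else "flank hits multiple loci"
    return(list(status = "unresolved", reason = reason))
  }
  tlen <- idx$seqlen[[anc$chrom[1]]]
  if (anc$strand[1] == "+") {
    lo <- anc$pos_end[1]; hi <- min(tlen, lo + downstream)
  } else {
    hi <- anc$pos[1]; lo <- max(0, hi - downstream)
  }
  if (hi <= lo) return(list(status = "absent", reason = "no downstream sequence"))
  tname <- anc$chrom[1]
  region <- substring(genome_index_seq(idx, tname), lo + 1, hi)
  hit <- local_align(family$consensus, stats::setNames(region, "region"),
                     min_score = 50L, max_hits = 4L)
  ok <- nrow(hit) > 0 && any((hit$qend - hit$qstart) >= min_te_len &
                               hit$identity >= min_te_identity)
  list(status = if (ok) "present" else "absent",
       reason = if (ok) "consensus match downstream of orthologous flank"
                else "orthologous flank without adjacent element")
}

# The seed index does not expose its sequences to R; keep a parallel character
# store on the R side when ortholog search needs target slices.
genome_index_seq <- function(idx, name) {
  seqs <- attr(idx, "seqs")
  if (is.null(seqs)) stop("index lacks sequence store; build with seed_index_with_seqs()")
  seqs[[name]]
}

#' Build a seed index that also retains its sequences
#'
#' [find_ortholog()] needs to slice target-assembly sequence around flank
#' placements; this wrapper keeps the (uppercased) sequences alongside the
#' index.
#'
#' @inheritParams seed_index
#' @export
seed_index_with_seqs <- function(targets, k = 21L) {
  seqs <- genome_as_character(targets)
  idx <- seed_index(seqs, k = k)
  attr(idx, "seqs") <- seqs
  idx
}

#' Discover, date and classify full elements across three assemblies
#'
#' Pipeline convenience: runs [find_paralogs()] + [recover_full_element()] on
#' each element's source assembly, measures [ltr_identity()], dates the
#' insertion, resolves orthology against the two other assemblies with
#' [find_ortholog()] and classifies the insertion.
#'
#' @param family A [te_family()].
#' @param genomes Named list of three assemblies with names `japonica`,
#'   `indica`, `aus` (named character vectors / `DNAStringSet`).
#' @param source Which assembly to discover elements in.
#' @param rate Molecular-clock rate.
#' @return Data frame of dated, classified elements: `family_id`, `chrom`,
#'   `start`, `end`, `ltr_identity`, `age_years`, `japonica`, `indica`, `aus`,
#'   `category` (`NA` when any ortholog call is unresolved).
#' @export
date_elements <- function(family, genomes, source = "japonica", rate = 1.3e-8) {
  stopifnot(all(c("japonica", "indica", "aus") %in% names(genomes)))
  src <- genome_as_character(genomes[[source]])
  sidx <- seed_index(src)
  others <- setdiff(c("japonica", "indica", "aus"), source)
  oidx <- lapply(genomes[others], seed_index_with_seqs)
  loci <- find_paralogs(family, sidx)
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    el <- recover_full_element(loci[i, ], family, src)
    if (is.null(el)) next
    ident <- tryCatch(ltr_identity(el, src), error = function(e) NA_real_)
    if (is.na(ident)) next
    flags <- stats::setNames(rep(NA_character_, 3), c("japonica", "indica", "aus"))
    flags[source] <- "present"
    for (o in others) {
      res <- find_ortholog(el, src, oidx[[o]], family)
      flags[o] <- if (res$status == "unresolved") NA_character_ else res$status
    }
    category <- if (anyNA(flags)) NA_character_ else
      classify_insertion(flags[["japonica"]], flags[["indica"]], flags[["aus"]])
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = family$family_id, chrom = el$chrom, start = el$start,
      end = el$end, ltr_identity = ident,
      age_years = date_insertion(ident, rate = rate),
      japonica = flags[["japonica"]], indica = flags[["indica"]],
      aus = flags[["aus"]], category = category, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(family_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      ltr_identity = numeric(0), age_years = numeric(0),
                      japonica = character(0), indica = character(0),
                      aus = character(0), category = character(0)))
  do.call(rbind, rows)
}

#' Validate a category against panel carrier frequencies
#'
#' A group-specific category is retained only when the insertion is carried by
#' at least `specific_threshold` (default 60%) of the accessions of that
#' group; a common category requires at least `common_threshold` (default
#' 80%) in each implicated group.
#'
#' @param category A seven-way category from [classify_insertion()].
#' @param group_freq Named numeric vector of carrier frequencies per varietal
#'   group (names `Japonica`, `Indica`, `Aus/Boro`), e.g. from
#'   [element_group_frequency()].
#' @param specific_threshold,common_threshold Retention thresholds.
#' @return List: `validated` (logical), `reason`.
#' @export
validate_category <- function(category, group_freq, specific_threshold = 0.6,
                              common_threshold = 0.8) {
  need <- switch(category,
                 "Japonica-specific" = c(Japonica = specific_threshold),
                 "Indica-specific" = c(Indica = specific_threshold),
                 "Aus-specific" = c(`Aus/Boro` = specific_threshold),
                 "common-all" = c(Japonica = common_threshold,
                                  Indica = common_threshold,
                                  `Aus/Boro` = common_threshold),
                 "common-IndJap" = c(Indica = common_threshold,
                                     Japonica = common_threshold),
                 "common-IndAus" = c(Indica = common_threshold,
                                     `Aus/Boro` = common_threshold),
                 "common-JapAus" = c(Japonica = common_threshold,
                                     `Aus/Boro` = common_threshold),
                 stop("unknown category: ", category))
  if (anyNA(group_freq))
    return(list(validated = FALSE, reason = "no panel evidence"))
  missing_groups <- setdiff(names(need), names(group_freq))
  if (length(missing_groups))
    return(list(validated = FALSE, reason = "no panel evidence"))
  ok <- all(group_freq[names(need)] >= need)
  list(validated = ok,
       reason = if (ok) "carrier frequency meets group thresholds"
                else "carrier frequency below group thresholds")
}

#' Carrier frequency of an element per varietal group
#'
#' Matches an element to a TIP matrix row by family and the window containing
#' the element start (in the element's source-assembly coordinates; the
#' matrix must be windowed on that assembly), then computes the carrier
#' frequency within each varietal group of the panel.
#'
#' @param element A `full_element` (or a list with `family_id`, `chrom`,
#'   `start`).
#' @param matrix A `tip_matrix`.
#' @param windows Windows of the source assembly.
#' @param meta Accession metadata (see [read_accession_meta()]).
#' @return Named numeric vector of per-group frequencies, or `NA` when no
#'   matrix row matches the element.
#' @export
element_group_frequency <- function(element, matrix, windows, meta) {
  widx <- tryCatch(window_index_of(element$chrom, element$start, windows),
                   error = function(e) NA_integer_)
  if (is.na(widx)) return(NA_real_)
  rid <- paste(element$family_id, windows$window_id[widx], sep = ":")
  if (!rid %in% rownames(matrix)) return(NA_real_)
  row <- matrix[rid, meta$accession_id]
  tapply(row, meta$group, mean)
}

#' Identity and age summaries per category
#'
#' Medians and quartiles of LTR identity and age for validated elements of
#' each category.
#'
#' @param dated Output of [date_elements()] with a logical `validated` column
#'   (rows with `validated = FALSE` or `NA` category are dropped).
#' @return Data frame: one row per category with `n`, `identity_median`,
#'   `identity_q1`, `identity_q3`, `age_median`, `age_q1`, `age_q3`.
#' @export
category_age_distributions <- function(dated) {
  keep <- !is.na(dated$category)
  if ("validated" %in% names(dated)) keep <- keep & dated$validated %in% TRUE
  d <- dated[keep, , drop = FALSE]
  if (nrow(d) == 0L)
    return(data.frame(category = character(0), n = integer(0),
                      identity_median = numeric(0), identity_q1 = numeric(0),
                      identity_q3 = numeric(0), age_median = numeric(0),
                      age_q1 = numeric(0), age_q3 = numeric(0)))
  do.call(rbind, lapply(split(d, d$category), function(x) {
    qi <- stats::quantile(x$ltr_identity, c(0.25, 0.5, 0.75), names = FALSE)
    qa <- stats::quantile(x$age_years, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(category = x$category[1], n = nrow(x),
               identity_median = qi[2], identity_q1 = qi[1], identity_q3 = qi[3],
               age_median = qa[2], age_q1 = qa[1], age_q3 = qa[3],
               row.names = NULL)
  }))
}
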