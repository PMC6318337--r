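#' Insertion frequencies and per-family spectra
#'
#' Frequency of each (family, window) event within a chosen accession subset
#' (carriers / subset size). Events with no carrier in the subset are dropped.
#'
#' @param matrix A `tip_matrix`.
#' @param subset Accession ids to restrict to (default: all columns).
#' @param breaks Histogram bin edges on `(0, 1]`.
#' @return A list of class `tip_spectrum`: `events` (data frame with
#'   `family_id`, `window_id`, `carriers`, `frequency`) and `histogram`
#'   (counts per family per bin).
#' @export
tip_frequencies <- function(matrix, subset = colnames(matrix),
                            breaks = c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 1)) {
  if (length(subset) == 0L) stop("empty subset")
  if (!all(subset %in% colnames(matrix)))
    stop("subset contains unknown accessions")
  sub <- matrix[, subset, drop = FALSE]
  carriers <- rowSums(sub)
  keep <- carriers >= 1
  ev <- parse_event_id(rownames(matrix)[keep])
  events <- data.frame(ev, carriers = as.integer(carriers[keep]),
                       frequency = carriers[keep] / length(subset))
  hist <- tapply(events$frequency, events$family_id, function(f)
    table(cut(f, breaks = breaks, include.lowest = FALSE)))
  structure(list(events = events, histogram = hist, n = length(subset),
                 breaks = breaks), class = "tip_spectrum")
}

#' @export
print.tip_spectrum <- function(x, ...) {
  cat(sprintf("<tip_spectrum> %d events over %d accessions; %d families\n",
              nrow(x$events), x$n, length(unique(x$events$family_id))))
  invisible(x)
}

#' Classify a family's transpositional history from its frequency spectrum
#'
#' A declared, configurable heuristic reading the shape of the spectrum:
#' `Recent` if at least `recent_prop` of events sit below `recent_freq`
#' (L-shape, transposition after the panel's lineages separated), `Old` if at
#' least `old_prop` sit above `old_freq` (mostly fixed, ancient activity),
#' `Continuous` otherwise.
#'
#' @param frequencies Event frequencies for one family (or a `tip_spectrum`,
#'   in which case every family is classified).
#' @param recent_freq,recent_prop,old_freq,old_prop Heuristic thresholds.
#' @return Character: `"Recent"`, `"Continuous"` or `"Old"` (named vector for
#'   a spectrum input).
#' @export
classify_activity <- function(frequencies, recent_freq = 0.05, recent_prop = 0.8,
                              old_freq = 0.5, old_prop = 0.5) {
  if (inherits(frequencies, "tip_spectrum")) {
    ev <- frequencies$events
    return(vapply(split(ev$frequency, ev$family_id), classify_activity,
                  character(1), recent_freq, recent_prop, old_freq, old_prop))
  }
  f <- as.numeric(frequencies)
  if (length(f) == 0L) stop("no events for family")
  if (mean(f < recent_freq) >= recent_prop) "Recent"
  else if (mean(f > old_freq) >= old_prop) "Old"
  else "Continuous"
}

#' Distance from TIP windows to the nearest gene
#'
#' Window-to-gene distance at the method's 10-kb resolution: the minimum gap
#' in bp between the TIP window interval and any gene interval, 0 when they
#' overlap, `NA` when the window's chromosome carries no gene.
#'
#' @param window_id Window ids (`"chrom:start-end"`, 0-based half-open), or a
#'   `tip_matrix` (row windows are used, de-duplicated).
#' @param genes `GRanges` of genes (see [read_genes()]).
#' @return Numeric vector of distances in bp.
#' @export
distance_to_gene <- function(window_id, genes) {
  if (inherits(window_id, "tip_matrix"))
    window_id <- unique(parse_event_id(rownames(window_id))$window_id)
  w <- parse_window_id(window_id)
  gr <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1L, w$end))
  # chromosomes absent from the annotation legitimately yield no hit (NA)
  hit <- suppressWarnings(
    GenomicRanges::distanceToNearest(gr, genes, ignore.strand = TRUE))
  out <- rep(NA_real_, length(gr))
  out[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  out
}

#' Per-accession TE copy-number phenotype table
#'
#' For each accession and family, the number of insertions (row sum of the
#' accession's 1-cells for that family), suitable as a quantitative phenotype
#' for external GWAS tools.
#'
#' @param matrix A `tip_matrix`.
#' @return Data frame: one row per accession (`accession_id` first column),
#'   one column per family; column order stable (sorted family ids).
#' @export
copy_number_phenotype <- function(matrix) {
  acc <- colnames(matrix)
  if (nrow(matrix) == 0L) {
    return(data.frame(accession_id = acc))
  }
  fam <- parse_event_id(rownames(matrix))$family_id
  fams <- sort(unique(fam))
  counts <- vapply(fams, function(f)
    colSums(matrix[fam == f, , drop = FALSE]), numeric(length(acc)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(acc),
                                             dimnames = list(acc, fams))
  data.frame(accession_id = acc, counts, check.names = FALSE, row.names = NULL)
}

#' Compare gene distances between two superfamilies
#'
#' Welch two-sample t test of window-to-gene distances between two groups of
#' families (e.g. Gypsy vs Copia).
#'
#' @param distances Numeric vector of distances.
#' @param group Factor/character of the same length with exactly two levels.
#' @return List: `estimate` (group means), `statistic`, `p_value`,
#'   `degenerate` (TRUE when a group has zero variance, in which case the
#'   t test is not computed).
#' @export
group_compare_distance <- function(distances, group) {
  keep <- !is.na(distances) & !is.na(group)
  d <- distances[keep]; g <- factor(as.character(group[keep]))
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) < 2L)) stop("need >= 2 observations per group")
  v <- tapply(d, g, stats::var)
  if (any(v == 0)) {
    return(list(estimate = tapply(d, g, mean), statistic = NA_real_,
                p_value = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(d ~ g)
  list(estimate = tapply(d, g, mean), statistic = unname(tt$statistic),
       p_value = tt$p.value, degenerate = FALSE)
}
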