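#' Slice a window into fixed-length tiles
#'
#' Non-overlapping consecutive 100-bp tiles; a trailing fragment shorter than
#' `tile` bp is dropped (it enters neither numerator nor denominator of the
#' mappability fraction).
#'
#' @param window One row of [make_windows()] (a `GRanges` of length 1), or a
#'   list/data.frame with `chrom`, `start0`, `end0`.
#' @param genome Genome as named character / `DNAStringSet` / FASTA path.
#' @param tile Tile length in bp.
#' @return Character vector of tile sequences (possibly empty), with `start0`
#'   attribute giving each tile's 0-based genomic start.
#' @export
tile_window <- function(window, genome, tile = 100L) {
  g <- genome_as_character(genome)
  if (methods::is(window, "GRanges")) {
    chrom <- as.character(GenomeInfoDb::seqnames(window))[1]
    s0 <- window$start0[1]; e0 <- window$end0[1]
  } else {
    chrom <- window$chrom[1]; s0 <- window$start0[1]; e0 <- window$end0[1]
  }
  n <- (e0 - s0) %/% tile
  if (n == 0L) return(structure(character(0), start0 = integer(0)))
  st <- s0 + (seq_len(n) - 1L) * tile
  tiles <- substring(g[[chrom]], st + 1L, st + tile)
  structure(tiles, start0 = st)
}

#' Is a tile uniquely placeable on the genome?
#'
#' A tile is unique when anchoring it (same gate as TIP anchoring:
#' >= `min_len` bp at >= `min_identity` identity, score margin `margin`)
#' yields exactly one qualifying placement; the tile's own locus counts as
#' that one placement. Tiles with more than 10 Ns are non-unique by fiat.
#'
#' @param tile Tile sequence(s).
#' @param genome_index [seed_index()] over the genome (or a genome).
#' @inheritParams anchor_reads
#' @return Logical vector.
#' @export
tile_is_unique <- function(tile, genome_index, min_len = 80L,
                           min_identity = 0.95, margin = 10L) {
  tile <- .ts_uc(tile)
  n_count <- vapply(strsplit(tile, ""), function(x) sum(x == "N"), integer(1))
  res <- anchor_reads(tile, genome_index, min_len = min_len,
                      min_identity = min_identity, margin = margin)
  res$uniqueness == "unique" & n_count <= 10L
}

#' Per-window mappability track
#'
#' For every reference window, the fraction of its 100-bp tiles that place
#' uniquely on the genome. Because tile uniqueness shares the anchor gate of
#' TIP detection, the track is by construction the detectability bound of
#' junction anchoring.
#'
#' @param genome Genome (named character / `DNAStringSet` / FASTA path).
#' @param windows Windows from [make_windows()]; computed if `NULL`.
#' @param tile Tile length in bp.
#' @inheritParams anchor_reads
#' @param verbose Report the genome-wide mean.
#' @return Named numeric vector of fractions in `[0,1]`, one per window
#'   (`window_id` names); attribute `mean` holds the genome-wide mean.
#' @export
window_mappability <- function(genome, windows = NULL, tile = 100L,
                               min_len = 80L, min_identity = 0.95,
                               margin = 10L, verbose = FALSE) {
  g <- genome_as_character(genome)
  if (is.null(windows)) windows <- make_windows(g)
  gidx <- seed_index(g)
  frac <- rep(NA_real_, length(windows))
  names(frac) <- windows$window_id
  chroms <- as.character(GenomeInfoDb::seqnames(windows))
  for (chrom in unique(chroms)) {
    sel <- which(chroms == chrom)
    # tile the whole chromosome at once, then fold back per window
    starts <- unlist(lapply(sel, function(i) {
      s0 <- windows$start0[i]; e0 <- windows$end0[i]
      n <- (e0 - s0) %/% tile
      if (n == 0L) return(integer(0))
      s0 + (seq_len(n) - 1L) * tile
    }))
    widx <- rep(sel, vapply(sel, function(i)
      (windows$end0[i] - windows$start0[i]) %/% tile, numeric(1)))
    if (length(starts) == 0L) next
    tiles <- substring(g[[chrom]], starts + 1L, starts + tile)
    uniq <- tile_is_unique(tiles, gidx, min_len = min_len,
                           min_identity = min_identity, margin = margin)
    agg_n <- tapply(uniq, widx, length)
    agg_u <- tapply(uniq, widx, sum)
    frac[as.integer(names(agg_n))] <- as.numeric(agg_u) / as.numeric(agg_n)
  }
  attr(frac, "mean") <- mean(frac, na.rm = TRUE)
  if (verbose)
    message(sprintf("genome-wide mean mappability: %.3f", attr(frac, "mean")))
  frac
}

#' Write a mappability track as bedGraph
#'
#' @param track Output of [window_mappability()].
#' @param path Output path.
#' @export
write_mappability_bedgraph <- function(track, path) {
  w <- parse_window_id(names(track))
  utils::write.table(data.frame(w$chrom, w$start, w$end, unname(track)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
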