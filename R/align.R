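#' Build a seed index over target sequences
#'
#' Exact k-mer seeds (default k = 21) over a target set; the index backs every
#' alignment operation (read-vs-consensus matching, unique anchoring, tile
#' mappability, paralog search).
#'
#' @param targets Named character vector, `DNAStringSet`, or FASTA path.
#' @param k Seed length (4-31).
#' @return A `seed_index` object.
#' @export
seed_index <- function(targets, k = 21L) {
  seqs <- genome_as_character(targets)
  ptr <- .cpp_index_build(unname(seqs), names(seqs), as.integer(k))
  structure(list(ptr = ptr, names = names(seqs),
                 seqlen = stats::setNames(nchar(seqs), names(seqs)), k = as.integer(k)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %d target(s), %.0f bp total, k=%d\n",
              length(x$names), sum(x$seqlen), x$k))
  invisible(x)
}

#' Align queries against a seed index
#'
#' Seed-and-extend local alignment: shared k-mers are clustered by diagonal and
#' the best clusters are extended with banded affine-gap Smith-Waterman
#' (match +1, mismatch -2, gap open -4, gap extend -1 by default).
#'
#' @param index A [seed_index()].
#' @param queries Character vector / `DNAStringSet` of query sequences.
#' @param min_score Minimum alignment score to report.
#' @param band Half-width of the extension band (use larger values for
#'   indel-rich long reads).
#' @param max_hits Maximum alignments reported per query.
#' @param max_cand Seed clusters extended per query.
#' @param stride Seed sampling stride along the query.
#' @param max_occ Seeds occurring more often than this in the index are skipped.
#' @param both_strands Also search the reverse complement of each query.
#' @return Data frame of local alignments: `query` (index into `queries`),
#'   `target`, `strand`, `qstart`/`qend` and `tstart`/`tend` (0-based
#'   half-open; query interval always on the forward query), `matches`,
#'   `aln_len`, `identity`, `score`. Sorted by query then score descending.
#' @export
align_to_index <- function(index, queries, min_score = 25L, band = 8L,
                           max_hits = 8L, max_cand = 16L, stride = 1L,
                           max_occ = 64L, both_strands = TRUE) {
  stopifnot(inherits(index, "seed_index"))
  q <- if (methods::is(queries, "XStringSet")) as.character(queries) else as.character(queries)
  if (length(q) == 0L)
    return(empty_alignments())
  if (any(!nzchar(q))) stop("queries must be non-empty")
  df <- .cpp_query(index$ptr, unname(q), as.integer(min_score), as.integer(band),
                   as.integer(max_hits), as.integer(max_cand), as.integer(stride),
                   as.integer(max_occ), 1L, -2L, -4L, -1L, both_strands)
  df$target <- index$names[df$tid]
  df$tid <- NULL
  df$identity <- ifelse(df$aln_len > 0, df$matches / df$aln_len, 0)
  df[order(df$query, -df$score), , drop = FALSE]
}

empty_alignments <- function() {
  data.frame(query = integer(0), strand = character(0), qstart = numeric(0),
             qend = numeric(0), tstart = numeric(0), tend = numeric(0),
             matches = integer(0), aln_len = integer(0), score = integer(0),
             target = character(0), identity = numeric(0))
}

#' Local alignment of one query against one or more targets
#'
#' Convenience wrapper of [align_to_index()] that indexes `target` on the fly.
#' An exact-substring query returns a single full-length identity-1 alignment.
#'
#' @param query A single sequence.
#' @param target Named character vector or `DNAStringSet` of target sequences
#'   (a single unnamed sequence is named `"target"`).
#' @inheritParams align_to_index
#' @return As [align_to_index()], sorted by score descending.
#' @export
local_align <- function(query, target, min_score = 25L, band = 8L, max_hits = 8L,
                        max_cand = 16L, both_strands = TRUE, k = 21L) {
  query <- .ts_uc(query)
  if (!nzchar(query)) stop("query must be non-empty")
  if (is.character(target) && is.null(names(target)) && length(target) == 1L)
    names(target) <- "target"
  idx <- seed_index(target, k = k)
  align_to_index(idx, query, min_score = min_score, band = band,
                 max_hits = max_hits, max_cand = max_cand,
                 both_strands = both_strands)
}

#' Assign reads to TE families
#'
#' Each read is aligned against every family consensus; the family of the
#' best-scoring qualifying alignment is returned (`NA` if none qualifies).
#' Qualification: the alignment covers at least `min_len` bp of the read at
#' identity at least `min_identity`. Ties between families are broken towards
#' the lexicographically smallest family id and flagged `multi_family`.
#'
#' @param reads Character vector / `DNAStringSet`.
#' @param library A `te_library` (see [read_te_library()]) or a prebuilt
#'   [seed_index()] over the consensus sequences.
#' @param min_len,min_identity Qualification gate on the read.
#' @param stride Seed stride (speed/sensitivity trade-off).
#' @return Data frame with one row per read: `family_id` (`NA` = unassigned),
#'   `score`, `qstart`, `qend`, `identity`, `multi_family`.
#' @export
map_reads_to_te <- function(reads, library, min_len = 50L, min_identity = 0.9,
                            stride = 1L) {
  idx <- if (inherits(library, "seed_index")) library else {
    if (length(library) == 0L) stop("empty library")
    seed_index(library_consensus(library))
  }
  n <- length(reads)
  out <- data.frame(family_id = rep(NA_character_, n), score = rep(NA_integer_, n),
                    qstart = rep(NA_real_, n), qend = rep(NA_real_, n),
                    identity = rep(NA_real_, n), multi_family = rep(FALSE, n))
  if (n == 0L) return(out)
  aln <- align_to_index(idx, reads, min_score = as.integer(floor(min_len * 0.5)),
                        stride = stride, max_hits = 4L)
  if (nrow(aln) == 0L) return(out)
  qual <- aln[(aln$qend - aln$qstart) >= min_len & aln$identity >= min_identity, ,
              drop = FALSE]
  if (nrow(qual) == 0L) return(out)
  dt <- data.table::as.data.table(qual)
  # best score per read; among top-score families, lexicographically smallest
  best <- dt[order(query, -score, target),
             .(family_id = target[1L], score = score[1L], qstart = qstart[1L],
               qend = qend[1L], identity = identity[1L],
               multi_family = sum(score == score[1L] & target != target[1L]) > 0L),
             by = query]
  out$family_id[best$query] <- best$family_id
  out$score[best$query] <- best$score
  out$qstart[best$query] <- best$qstart
  out$qend[best$query] <- best$qend
  out$identity[best$query] <- best$identity
  out$multi_family[best$query] <- best$multi_family
  out
}

#' Uniquely anchor reads on a reference genome
#'
#' A placement qualifies when the alignment covers at least `min_len` bp of
#' the read at identity at least `min_identity` (the stringency dialect used
#' in place of a database-size-dependent e-value cut-off). A read is `unique`
#' when the best qualifying placement is the only one, or beats the runner-up
#' by at least `margin` score units; `ambiguous` when several placements
#' qualify within the margin; `none` otherwise.
#'
#' @param reads Character vector / `DNAStringSet`.
#' @param genome_index A [seed_index()] over the reference (or a genome
#'   coercible to one).
#' @param min_len,min_identity Qualification gate.
#' @param margin Best-vs-second score margin for uniqueness.
#' @param band Extension band half-width.
#' @return Data frame with one row per read: `chrom`, `pos` (0-based left-most
#'   aligned base), `strand`, `score`, `identity`, `uniqueness` in
#'   `{"unique","ambiguous","none"}`, `n_qualifying`.
#' @export
anchor_reads <- function(reads, genome_index, min_len = 80L, min_identity = 0.95,
                         margin = 10L, band = 8L) {
  idx <- if (inherits(genome_index, "seed_index")) genome_index else seed_index(genome_index)
  n <- length(reads)
  out <- data.frame(chrom = rep(NA_character_, n), pos = rep(NA_real_, n),
                    pos_end = rep(NA_real_, n),
                    strand = rep(NA_character_, n), score = rep(NA_integer_, n),
                    identity = rep(NA_real_, n),
                    uniqueness = rep("none", n), n_qualifying = rep(0L, n))
  if (n == 0L) return(out)
  aln <- align_to_index(idx, reads, min_score = as.integer(floor(min_len * 0.8)),
                        band = band, max_hits = 4L)
  if (nrow(aln) == 0L) return(out)
  qual <- aln[(aln$qend - aln$qstart) >= min_len & aln$identity >= min_identity, ,
              drop = FALSE]
  if (nrow(qual) == 0L) return(out)
  dt <- data.table::as.data.table(qual)
  best <- dt[order(query, -score),
             .(chrom = target[1L], pos = tstart[1L], pos_end = tend[1L],
               strand = strand[1L],
               score = score[1L], identity = identity[1L], n_qualifying = .N,
               second = if (.N > 1L) score[2L] else NA_integer_),
             by = query]
  uniq <- best$n_qualifying == 1L | (best$score - best$second) >= margin
  out$chrom[best$query] <- best$chrom
  out$pos[best$query] <- best$pos
  out$pos_end[best$query] <- best$pos_end
  out$strand[best$query] <- best$strand
  out$score[best$query] <- best$score
  out$identity[best$query] <- best$identity
  out$n_qualifying[best$query] <- best$n_qualifying
  out$uniqueness[best$query] <- ifelse(uniq, "unique", "ambiguous")
  out
}

#' Assign a single read to a TE family
#'
#' Scalar convenience form of [map_reads_to_te()].
#'
#' @inheritParams map_reads_to_te
#' @param read A single sequence.
#' @return The family id, or `NA_character_` if no alignment qualifies.
#' @export
map_read_to_te <- function(read, library, min_len = 50L, min_identity = 0.9) {
  map_reads_to_te(as.character(read), library, min_len = min_len,
                  min_identity = min_identity)$family_id[1L]
}

#' Anchor a single read
#'
#' Scalar convenience form of [anchor_reads()].
#'
#' @inheritParams anchor_reads
#' @param read A single sequence.
#' @return One-row data frame (`AnchorHit`): `chrom`, `pos`, `uniqueness`, ...
#' @export
anchor_to_genome <- function(read, genome_index, min_len = 80L,
                             min_identity = 0.95, margin = 10L) {
  anchor_reads(as.character(read), genome_index, min_len = min_len,
               min_identity = min_identity, margin = margin)
}
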