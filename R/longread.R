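#' Find long reads spanning a TE junction
#'
#' Aligns each long read against the TE family consensi and keeps reads whose
#' best TE match covers at most `max_te_fraction` (default 0.8) of the read
#' length: reads consisting only of TE sequence carry no junction and are
#' eliminated. Overlapping/nearby hits of the winning family are merged into
#' one TE interval on the read.
#'
#' @param reads Long reads (named character / `DNAStringSet` / FASTA(Q) path).
#' @param library A `te_library` or a [seed_index()] over the consensi.
#' @param max_te_fraction Maximum fraction of the read the TE match may cover.
#' @param min_len,min_identity Significance gate on TE hits (tolerant defaults
#'   for noisy long reads).
#' @param band Extension band half-width (wide, for indel-rich reads).
#' @param merge_gap Hits of the same family closer than this on the read are
#'   merged.
#' @return Data frame of junction reads: `read_id`, `family_id`, `te_start`,
#'   `te_end` (read coordinates, 0-based half-open), `read_len`, `te_fraction`.
#' @export
find_te_reads <- function(reads, library, max_te_fraction = 0.8,
                          min_len = 200L, min_identity = 0.75, band = 40L,
                          merge_gap = 200L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("q$|fastq$", reads, ignore.case = TRUE)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  rd <- if (methods::is(reads, "XStringSet")) as.character(reads) else reads
  ids <- names(rd)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(rd))
  idx <- if (inherits(library, "seed_index")) library else
    seed_index(library_consensus(library))
  out <- data.frame(read_id = character(0), family_id = character(0),
                    te_start = numeric(0), te_end = numeric(0),
                    read_len = integer(0), te_fraction = numeric(0))
  if (length(rd) == 0L) return(out)
  aln <- align_to_index(idx, rd, min_score = as.integer(min_len / 2), band = band,
                        max_hits = 16L, max_cand = 24L, stride = 3L)
  if (nrow(aln) == 0L) return(out)
  qual <- aln[(aln$qend - aln$qstart) >= min_len & aln$identity >= min_identity, ,
              drop = FALSE]
  if (nrow(qual) == 0L) return(out)
  rows <- lapply(split(qual, qual$query), function(h) {
    # winning family = family of the best-scoring hit
    fam <- h$target[which.max(h$score)]
    hf <- h[h$target == fam, , drop = FALSE]
    hf <- hf[order(hf$qstart), , drop = FALSE]
    # merge read intervals within merge_gap
    s <- hf$qstart[1]; e <- hf$qend[1]; iv <- NULL
    if (nrow(hf) > 1) for (i in 2:nrow(hf)) {
      if (hf$qstart[i] - e <= merge_gap) e <- max(e, hf$qend[i])
      else { iv <- rbind(iv, c(s, e)); s <- hf$qstart[i]; e <- hf$qend[i] }
    }
    iv <- rbind(iv, c(s, e))
    # keep the largest merged interval
    best <- which.max(iv[, 2] - iv[, 1])
    qi <- h$query[1]
    data.frame(read_id = ids[qi], family_id = fam, te_start = iv[best, 1],
               te_end = iv[best, 2], read_len = nchar(rd[qi]),
               te_fraction = (iv[best, 2] - iv[best, 1]) / nchar(rd[qi]))
  })
  res <- do.call(rbind, rows)
  res <- res[res$te_fraction <= max_te_fraction, , drop = FALSE]
  rownames(res) <- NULL
  names(rd) <- ids
  attr(res, "reads") <- rd
  res
}

#' Extract flanks around a TE interval on a read
#'
#' Up to two `flank`-bp sequences immediately left and right of the TE
#' interval; flanks shorter than `flank` bp are dropped.
#'
#' @param read Read sequence.
#' @param te_start,te_end TE interval on the read (0-based half-open).
#' @param flank Flank length in bp.
#' @return Data frame with `side` (`"left"`/`"right"`), `seq`, and the flank's
#'   read interval (`start`, `end`).
#' @export
extract_flanks <- function(read, te_start, te_end, flank = 300L) {
  read <- .ts_uc(read)
  len <- nchar(read)
  if (te_start <= 0 && te_end >= len)
    stop("TE interval spans the whole read; should have been filtered out")
  out <- NULL
  if (te_start >= flank) {
    out <- rbind(out, data.frame(side = "left", start = te_start - flank,
                                 end = te_start))
  }
  if (len - te_end >= flank) {
    out <- rbind(out, data.frame(side = "right", start = te_end,
                                 end = te_end + flank))
  }
  if (is.null(out))
    return(data.frame(side = character(0), seq = character(0),
                      start = numeric(0), end = numeric(0)))
  out$seq <- substring(read, out$start + 1L, out$end)
  out[, c("side", "seq", "start", "end")]
}

#' Map junction-read flanks onto the reference
#'
#' Flanks are anchored with a stringent gate (default >= 250 of 300 bp at
#' >= 90% identity, unique placement); each unique flank yields one inferred
#' insertion position: the genome coordinate of the flank base adjacent to
#' the TE. Multiple reads spanning the same insertion are de-duplicated per
#' (family, window).
#'
#' @param junction_reads Output of [find_te_reads()] (attribute `reads` holds
#'   sequences), or a data frame with `read_id`, `family_id`, `te_start`,
#'   `te_end` plus a `reads` named character vector argument.
#' @param genome_index [seed_index()] over the reference (or a genome).
#' @param windows Windows from [make_windows()] used for de-duplication.
#' @param reads Named character vector of read sequences (if not attached).
#' @param flank Flank length.
#' @param min_len,min_identity,margin Anchor gate for flanks.
#' @param band Extension band for noisy flanks.
#' @return Data frame of long-read insertions: `read_id`, `family_id`,
#'   `chrom`, `pos`, `flank_side` in `{"left","right","both"}`, `window_id`.
#'   Attribute `loci`: per-(family, window) de-duplicated loci.
#' @export
map_insertions <- function(junction_reads, genome_index, windows, reads = NULL,
                           flank = 300L, min_len = 250L, min_identity = 0.9,
                           margin = 10L, band = 20L) {
  if (is.null(reads)) reads <- attr(junction_reads, "reads")
  idx <- if (inherits(genome_index, "seed_index")) genome_index else
    seed_index(genome_index)
  empty <- data.frame(read_id = character(0), family_id = character(0),
                      chrom = character(0), pos = numeric(0),
                      flank_side = character(0), window_id = character(0))
  if (nrow(junction_reads) == 0L) { attr(empty, "loci") <- empty[0, ]; return(empty) }
  fl_list <- lapply(seq_len(nrow(junction_reads)), function(i) {
    r <- junction_reads[i, ]
    seq <- if (!is.null(names(reads))) reads[[r$read_id]] else reads[[i]]
    fl <- extract_flanks(seq, r$te_start, r$te_end, flank = flank)
    if (nrow(fl)) cbind(row = i, fl)
  })
  fl <- do.call(rbind, fl_list)
  if (is.null(fl) || nrow(fl) == 0L) { attr(empty, "loci") <- empty[0, ]; return(empty) }
  anc <- anchor_reads(fl$seq, idx, min_len = min_len, min_identity = min_identity,
                      margin = margin, band = band)
  keep <- anc$uniqueness == "unique"
  if (!any(keep)) { attr(empty, "loci") <- empty[0, ]; return(empty) }
  fl <- fl[keep, , drop = FALSE]; anc <- anc[keep, , drop = FALSE]
  # insertion position = flank base adjacent to the TE: for a left flank the
  # junction follows the flank (alignment end on + strand, start on -); for a
  # right flank it precedes it.
  te_after <- (fl$side == "left") == (anc$strand == "+")
  pos <- ifelse(te_after, anc$pos_end, anc$pos)
  widx <- window_index_of(anc$chrom, pmin(pos, GenomeInfoDb::seqlengths(windows)[anc$chrom] - 1),
                          windows)
  ins <- data.frame(read_id = junction_reads$read_id[fl$row],
                    family_id = junction_reads$family_id[fl$row],
                    chrom = anc$chrom, pos = pos, flank_side = fl$side,
                    window_id = windows$window_id[widx])
  # reads with both flanks uniquely placed get flank_side "both" (one record)
  dt <- data.table::as.data.table(ins)
  dt <- dt[, if (.N > 1L) {
    x <- .SD[1L]; x$flank_side <- "both"; x
  } else .SD, by = c("read_id", "family_id")]
  ins <- as.data.frame(dt)
  loci <- unique(ins[, c("family_id", "chrom", "window_id")])
  rownames(ins) <- NULL
  attr(ins, "loci") <- loci
  ins
}

#' Validate short-read TIP calls against long-read insertions
#'
#' A TIP is validated iff a long-read insertion of the same family falls in
#' the same window. Following the field's usage: specificity = validated TIPs
#' / all TIPs; sensitivity = validated long-read loci / all long-read loci.
#' Both sides are de-duplicated per (family, window) before counting, so
#' TP + FP equals the TIP event count and TP + FN the long-read locus count.
#'
#' @param tips TIP events for one accession: data frame with `family_id` and
#'   `window_id` (e.g. from [second_pass()] calls filtered to the accession).
#' @param longread_insertions Output of [map_insertions()] (or its `loci`
#'   attribute).
#' @return List: `tp`, `fp`, `fn`, `sensitivity`, `specificity` (each `NA`
#'   when its denominator is empty), plus the annotated `tips` and `loci`.
#' @export
compare_callsets <- function(tips, longread_insertions) {
  loci <- attr(longread_insertions, "loci")
  if (is.null(loci)) loci <- longread_insertions
  tips <- unique(tips[, c("family_id", "window_id")])
  loci <- unique(loci[, c("family_id", "window_id")])
  key_t <- paste(tips$family_id, tips$window_id)
  key_l <- paste(loci$family_id, loci$window_id)
  tips$validated <- key_t %in% key_l
  loci$recovered <- key_l %in% key_t
  tp <- sum(tips$validated)
  fp <- nrow(tips) - tp
  fn <- sum(!loci$recovered)
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (nrow(loci)) sum(loci$recovered) / nrow(loci) else NA_real_,
       specificity = if (nrow(tips)) tp / nrow(tips) else NA_real_,
       tips = tips, loci = loci)
}
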