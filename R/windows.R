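#' Tile a genome into fixed-size windows
#'
#' Splits every chromosome into consecutive non-overlapping windows of
#' `size` bp (default 10 kb), the resolution at which TIP events are called.
#' The last window of a chromosome may be shorter than `size`.
#'
#' @param genome A named `DNAStringSet`, a named character vector of sequences,
#'   a named numeric vector of chromosome lengths, or a FASTA path.
#' @param size Window size in bp.
#' @return A `GRanges` (0-based half-open stored as `start0`/`end0` metadata;
#'   the `GRanges` itself uses 1-based starts as usual) with a `window_id`
#'   column of the form `"chrom:start-end"` in 0-based half-open coordinates.
#' @export
make_windows <- function(genome, size = 10000L) {
  lens <- genome_seqlengths(genome)
  if (length(lens) == 0L) stop("no sequences")
  size <- as.integer(size)
  chr <- character(0); s0 <- integer(0); e0 <- integer(0)
  for (i in seq_along(lens)) {
    len <- as.integer(lens[[i]])
    n <- ceiling(len / size)
    st <- (seq_len(n) - 1L) * size
    en <- pmin(st + size, len)
    chr <- c(chr, rep(names(lens)[i], n)); s0 <- c(s0, st); e0 <- c(e0, en)
  }
  gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(start = s0 + 1L, end = e0),
                               seqlengths = lens)
  gr$window_id <- window_id(chr, s0, e0)
  gr$start0 <- s0
  gr$end0 <- e0
  gr
}

#' @rdname make_windows
#' @param chrom,start0,end0 Vectors defining windows in 0-based half-open
#'   coordinates.
#' @export
window_id <- function(chrom, start0, end0) {
  sprintf("%s:%d-%d", chrom, as.integer(start0), as.integer(end0))
}

#' Locate the window containing a position
#'
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s).
#' @param windows Windows from [make_windows()].
#' @return The rows of `windows` containing each position (a `GRanges`).
#' @export
window_of <- function(chrom, pos, windows) {
  idx <- window_index_of(chrom, pos, windows)
  windows[idx]
}

# Vectorised window lookup returning integer indices into `windows`.
window_index_of <- function(chrom, pos, windows) {
  pos <- as.numeric(pos)
  lens <- GenomeInfoDb::seqlengths(windows)
  if (any(is.na(match(chrom, names(lens)))))
    stop("unknown chromosome: ", paste(setdiff(chrom, names(lens)), collapse = ", "))
  if (any(pos < 0 | pos >= lens[chrom]))
    stop("position out of chromosome range")
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1, width = 1))
  hit <- GenomicRanges::findOverlaps(q, windows, select = "first")
  if (anyNA(hit)) stop("position not covered by windows")
  hit
}

genome_seqlengths <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    lens <- Biostrings::width(genome); names(lens) <- names(genome)
  } else if (is.character(genome)) {
    lens <- nchar(genome); names(lens) <- names(genome)
  } else if (is.numeric(genome)) {
    lens <- genome
  } else stop("unsupported genome representation")
  if (length(lens) && (is.null(names(lens)) || anyNA(names(lens)) || any(names(lens) == "")))
    stop("genome sequences must be named")
  lens
}

# Coerce a genome to a named character vector of uppercase sequences.
genome_as_character <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- genome
  } else stop("unsupported genome representation")
  if (is.null(names(out))) stop("genome sequences must be named")
  toupper(out)
}
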