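#' Construct a TE family record
#'
#' A family is represented by a single consensus sequence, with optional LTR
#' length (absent for non-LTR elements such as LINEs) and an optional
#' reverse-transcriptase (RT) domain interval on the consensus, used as the
#' paralog probe in full-element discovery.
#'
#' @param family_id Family name.
#' @param consensus Consensus nucleotide sequence (character or `DNAString`).
#' @param superfamily One of `"Gypsy"`, `"Copia"`, `"LINE"`, `"other"`.
#' @param ltr_length LTR length in bp, or `NA` if the element has no LTRs.
#' @param rt_start,rt_end Half-open 0-based RT-domain interval on the
#'   consensus, or `NA`. For LARD-like families lacking an RT domain, point
#'   this at a non-repetitive stretch of the internal sequence instead.
#' @return A `te_family` object (a list).
#' @export
te_family <- function(family_id, consensus, superfamily = "other",
                      ltr_length = NA_integer_, rt_start = NA_integer_,
                      rt_end = NA_integer_) {
  consensus <- .ts_uc(consensus)
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  if (grepl("[^ACGTN]", consensus)) stop("consensus must be over {A,C,G,T,N}")
  superfamily <- match.arg(superfamily, c("Gypsy", "Copia", "LINE", "other"))
  if (!is.na(ltr_length)) {
    ltr_length <- as.integer(ltr_length)
    if (ltr_length <= 0 || ltr_length > nchar(consensus) / 2)
      stop("ltr_length must be positive and at most half the consensus length")
  }
  if (xor(is.na(rt_start), is.na(rt_end))) stop("rt_start and rt_end must be given together")
  if (!is.na(rt_start)) {
    rt_start <- as.integer(rt_start); rt_end <- as.integer(rt_end)
    if (rt_start < 0 || rt_end > nchar(consensus) || rt_start >= rt_end)
      stop("rt_domain must be a half-open interval within the consensus")
  }
  structure(list(family_id = as.character(family_id), superfamily = superfamily,
                 consensus = consensus, ltr_length = ltr_length,
                 rt_start = rt_start, rt_end = rt_end),
            class = "te_family")
}

#' @export
print.te_family <- function(x, ...) {
  cat(sprintf("<te_family> %s (%s), %d bp consensus, LTR %s, RT domain %s\n",
              x$family_id, x$superfamily, nchar(x$consensus),
              if (is.na(x$ltr_length)) "absent" else sprintf("%d bp", x$ltr_length),
              if (is.na(x$rt_start)) "absent" else sprintf("[%d,%d)", x$rt_start, x$rt_end)))
  invisible(x)
}

#' Read a TE family library
#'
#' Reads one consensus per family from FASTA, with an optional tab-separated
#' sidecar table (`family_id`, `superfamily`, `ltr_length`, `rt_start`,
#' `rt_end`) attaching LTR/RT-domain features by family id.
#'
#' @param fasta FASTA path or named `DNAStringSet`/character vector.
#' @param sidecar Optional path to the feature table (or a data frame).
#' @return A named list of [te_family()] objects (class `te_library`).
#' @export
read_te_library <- function(fasta, sidecar = NULL) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    fasta <- Biostrings::readDNAStringSet(fasta)
  }
  seqs <- if (methods::is(fasta, "DNAStringSet")) as.character(fasta) else fasta
  if (is.null(names(seqs))) stop("library sequences must be named")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate family_id in library: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  side <- NULL
  if (!is.null(sidecar)) {
    side <- if (is.data.frame(sidecar)) sidecar else
      utils::read.delim(sidecar, stringsAsFactors = FALSE)
    missing_ids <- setdiff(side$family_id, ids)
    if (length(missing_ids))
      stop("sidecar family_id without FASTA record: ", paste(missing_ids, collapse = ", "))
  }
  lib <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    row <- if (!is.null(side) && id %in% side$family_id) side[side$family_id == id, ] else NULL
    g <- function(field, default) {
      if (!is.null(row) && field %in% names(row) && !is.na(row[[field]][1])) row[[field]][1] else default
    }
    te_family(id, seqs[[i]],
              superfamily = g("superfamily", "other"),
              ltr_length = g("ltr_length", NA_integer_),
              rt_start = g("rt_start", NA_integer_),
              rt_end = g("rt_end", NA_integer_))
  })
  names(lib) <- ids
  structure(lib, class = "te_library")
}

library_consensus <- function(library) {
  stopifnot(length(library) > 0L)
  vapply(library, function(f) f$consensus, character(1))
}

#' Write BED5 records
#'
#' Coordinates are 0-based half-open, written as-is.
#'
#' @param records Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`.
#' @param path Output path.
#' @export
write_bed <- function(records, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score") %in% names(records)))
  if (nrow(records) && any(records$start >= records$end))
    stop("BED records require start < end")
  dt <- records[, c("chrom", "start", "end", "name", "score")]
  utils::write.table(dt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0)))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:5] <- c("chrom", "start", "end", "name", "score")
  df[, 1:5]
}

#' Read an accession metadata table
#'
#' Tab-separated with columns `accession_id`, `group` (e.g. Indica, Japonica,
#' Aus/Boro, other), optional `zone` (1-10) and `coverage`.
#'
#' @param path TSV path or a data frame.
#' @return A data frame, one row per accession.
#' @export
read_accession_meta <- function(path) {
  meta <- if (is.data.frame(path)) path else utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession_id", "group") %in% names(meta)))
    stop("metadata requires accession_id and group columns")
  if (anyDuplicated(meta$accession_id)) stop("accession_id must be unique")
  if (is.null(meta$zone)) meta$zone <- NA_integer_
  if (is.null(meta$coverage)) meta$coverage <- NA_real_
  meta
}

#' Read gene annotation as 0-based half-open records
#'
#' GFF3/GTF input is 1-based inclusive and converted on ingest.
#'
#' @param path GFF3/GTF path, or a `GRanges`.
#' @param feature Feature type to keep (default `"gene"`; set `NULL` to keep all).
#' @return A `GRanges` of genes with a `gene_id` column.
#' @export
read_genes <- function(path, feature = "gene") {
  gr <- if (methods::is(path, "GRanges")) path else rtracklayer::import(path)
  if (!is.null(feature) && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) %in% feature]
  if (!"gene_id" %in% names(S4Vectors::mcols(gr))) {
    id <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else
      sprintf("gene%04d", seq_along(gr))
    gr$gene_id <- id
  }
  gr
}
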