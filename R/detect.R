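#' Classify read pairs into TE junction pairs
#'
#' A pair is kept iff exactly one mate maps to a TE family; the other mate
#' becomes the anchor candidate. Pairs where both or neither mate match a TE
#' carry no junction information and are discarded.
#'
#' @param mate1,mate2 Character vectors / `DNAStringSet` of the two mates,
#'   paired by position; names (if any) are used as pair ids.
#' @param library A `te_library` or a [seed_index()] over family consensi.
#' @param ... Passed to [map_reads_to_te()].
#' @return Data frame of junction pairs: `pair_id`, `family_id`, `te_mate`,
#'   `anchor_mate`, `te_score`, `multi_family`. Attribute `counts` records how
#'   many pairs fell in each class.
#' @export
classify_pairs <- function(mate1, mate2, library, ...) {
  m1 <- if (methods::is(mate1, "XStringSet")) as.character(mate1) else mate1
  m2 <- if (methods::is(mate2, "XStringSet")) as.character(mate2) else mate2
  if (length(m1) != length(m2)) {
    warning(sprintf("orphan mates: %d unpaired reads skipped",
                    abs(length(m1) - length(m2))))
    n <- min(length(m1), length(m2))
    m1 <- m1[seq_len(n)]; m2 <- m2[seq_len(n)]
  }
  pair_id <- names(m1)
  if (is.null(pair_id)) pair_id <- sprintf("pair%d", seq_along(m1))
  hit1 <- map_reads_to_te(m1, library, ...)
  hit2 <- map_reads_to_te(m2, library, ...)
  te1 <- !is.na(hit1$family_id); te2 <- !is.na(hit2$family_id)
  keep <- xor(te1, te2)
  fam <- ifelse(te1, hit1$family_id, hit2$family_id)
  out <- data.frame(pair_id = pair_id[keep], family_id = fam[keep],
                    te_mate = ifelse(te1, m1, m2)[keep],
                    anchor_mate = ifelse(te1, m2, m1)[keep],
                    te_score = ifelse(te1, hit1$score, hit2$score)[keep],
                    multi_family = ifelse(te1, hit1$multi_family, hit2$multi_family)[keep],
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(pairs = length(m1), both_te = sum(te1 & te2),
                           neither = sum(!te1 & !te2), junction = nrow(out))
  out
}

#' Count per-window junction support
#'
#' Each junction pair whose anchor mate places uniquely on the reference
#' increments exactly one (accession, family, window) cell; ambiguous or
#' unplaced anchors contribute nothing. Windows are assigned by the left-most
#' aligned base of the anchor.
#'
#' @param junctions Output of [classify_pairs()] (optionally with an
#'   `accession_id` column; otherwise `accession` is used).
#' @param genome_index [seed_index()] over the reference.
#' @param windows Windows from [make_windows()].
#' @param accession Accession id used when `junctions` lacks one.
#' @param ... Passed to [anchor_reads()].
#' @return A `data.table` support table: `accession_id`, `family_id`,
#'   `window_id`, `count`.
#' @export
collect_support <- function(junctions, genome_index, windows,
                            accession = "accession", ...) {
  empty <- data.table::data.table(accession_id = character(0),
                                  family_id = character(0),
                                  window_id = character(0), count = integer(0))
  if (nrow(junctions) == 0L) return(empty)
  if (is.null(junctions$accession_id)) junctions$accession_id <- accession
  anc <- anchor_reads(junctions$anchor_mate, genome_index, ...)
  keep <- anc$uniqueness == "unique"
  if (!any(keep)) return(empty)
  widx <- window_index_of(anc$chrom[keep], anc$pos[keep], windows)
  dt <- data.table::data.table(accession_id = junctions$accession_id[keep],
                               family_id = junctions$family_id[keep],
                               window_id = windows$window_id[widx])
  dt[, list(count = .N), by = c("accession_id", "family_id", "window_id")]
}

#' First detection pass: open windows at the high threshold
#'
#' A (family, window) event is opened iff some accession supports it with at
#' least `open_threshold` junction pairs (default 5).
#'
#' @param support Support table from [collect_support()] (rows from several
#'   accessions may be concatenated).
#' @param open_threshold Minimum support to open a window.
#' @return Data frame of opened events: `family_id`, `window_id`.
#' @export
first_pass <- function(support, open_threshold = 5L) {
  dt <- data.table::as.data.table(support)
  if (nrow(dt) == 0L)
    return(data.frame(family_id = character(0), window_id = character(0)))
  op <- dt[, list(max_count = max(count)), by = c("family_id", "window_id")]
  as.data.frame(op[op$max_count >= open_threshold, c("family_id", "window_id")])
}

#' Second detection pass: rescue calls in opened windows
#'
#' Re-scans all accessions at the lower threshold (default 2), but only within
#' events opened by [first_pass()]. The `pass` field records which regime each
#' call met (1 if its own support reaches the open threshold, else 2); the
#' rescue threshold applies to every accession including the opener.
#'
#' @param support Support table (all accessions).
#' @param opened Opened events from [first_pass()].
#' @param rescue_threshold Minimum support within an opened window.
#' @param open_threshold Support at which a call is labelled pass 1.
#' @return Data frame of TIP calls: `accession_id`, `family_id`, `window_id`,
#'   `support`, `pass`.
#' @export
second_pass <- function(support, opened, rescue_threshold = 2L, open_threshold = 5L) {
  dt <- data.table::as.data.table(support)
  empty <- data.frame(accession_id = character(0), family_id = character(0),
                      window_id = character(0), support = integer(0), pass = integer(0))
  if (nrow(dt) == 0L || nrow(opened) == 0L) return(empty)
  op <- data.table::as.data.table(opened[, c("family_id", "window_id")])
  calls <- merge(dt, op, by = c("family_id", "window_id"))
  calls <- calls[calls$count >= rescue_threshold, ]
  if (nrow(calls) == 0L) return(empty)
  out <- data.frame(accession_id = calls$accession_id, family_id = calls$family_id,
                    window_id = calls$window_id, support = calls$count,
                    pass = ifelse(calls$count >= open_threshold, 1L, 2L))
  out[order(out$family_id, out$window_id, out$accession_id), , drop = FALSE]
}

#' Build the presence/absence matrix
#'
#' Rows are (family, window) events, columns are accessions, cells are 0/1.
#' Row names are `"family_id:window_id"`; rows are sorted by family then
#' genomic position, columns by accession id.
#'
#' @param calls TIP calls from [second_pass()].
#' @param panel Accession ids (character) or a metadata data frame with an
#'   `accession_id` column.
#' @return Integer matrix of class `tip_matrix`.
#' @export
build_matrix <- function(calls, panel) {
  acc <- if (is.data.frame(panel)) panel$accession_id else as.character(panel)
  acc <- sort(unique(acc))
  if (nrow(calls) && !all(calls$accession_id %in% acc))
    stop("calls reference accessions absent from the panel: ",
         paste(setdiff(calls$accession_id, acc), collapse = ", "))
  if (nrow(calls) == 0L) {
    m <- matrix(0L, nrow = 0, ncol = length(acc),
                dimnames = list(character(0), acc))
    class(m) <- c("tip_matrix", class(m))
    return(m)
  }
  ev <- unique(calls[, c("family_id", "window_id")])
  parts <- parse_window_id(ev$window_id)
  ord <- order(ev$family_id, parts$chrom, parts$start)
  ev <- ev[ord, , drop = FALSE]
  rid <- paste(ev$family_id, ev$window_id, sep = ":")
  m <- matrix(0L, nrow = nrow(ev), ncol = length(acc), dimnames = list(rid, acc))
  m[cbind(match(paste(calls$family_id, calls$window_id, sep = ":"), rid),
          match(calls$accession_id, acc))] <- 1L
  class(m) <- c("tip_matrix", class(m))
  m
}

#' Parse window ids of the form "chrom:start-end"
#'
#' @param window_id Character vector of window ids.
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
parse_window_id <- function(window_id) {
  m <- regmatches(window_id, regexec("^(.*):([0-9]+)-([0-9]+)$", window_id))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed window_id: ", window_id[bad][1])
  data.frame(chrom = vapply(m, `[`, character(1), 2L),
             start = as.integer(vapply(m, `[`, character(1), 3L)),
             end = as.integer(vapply(m, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

# Split "family:chrom:start-end" row names into family and window id.
parse_event_id <- function(event_id) {
  fam <- sub(":.*$", "", event_id)
  win <- sub("^[^:]*:", "", event_id)
  data.frame(family_id = fam, window_id = win, stringsAsFactors = FALSE)
}

#' Detect TIPs across a panel of accessions
#'
#' End-to-end composition of [classify_pairs()], [collect_support()],
#' [first_pass()] and [second_pass()]: maps every read pair of every
#' accession against the TE library, anchors the genomic mates of junction
#' pairs uniquely on the windowed reference, applies the two-pass 5/2 support
#' thresholds across the panel, and returns the presence/absence matrix.
#' Accessions are processed independently; opened events are merged by set
#' union, so results do not depend on processing order.
#'
#' @param panel A named list, one entry per accession, each either
#'   `list(fq1=, fq2=)` FASTQ paths or `list(mate1=, mate2=)` in-memory reads.
#' @param library A `te_library`.
#' @param genome Reference genome (FASTA path, `DNAStringSet`, or named
#'   character).
#' @param open_threshold,rescue_threshold Two-pass support thresholds.
#' @param window_size Reference window size in bp.
#' @param te_min_len,te_min_identity TE-mate qualification gate.
#' @param anchor_min_len,anchor_min_identity,anchor_margin Anchor gate.
#' @param te_stride Seed stride for the TE scan.
#' @param verbose Log per-accession read/junction/anchor counts.
#' @return A list of class `tip_result`: `matrix` (see [build_matrix()]),
#'   `calls`, `support`, `opened`, `windows`, `log` (per-accession counts).
#' @export
detect_tips <- function(panel, library, genome, open_threshold = 5L,
                        rescue_threshold = 2L, window_size = 10000L,
                        te_min_len = 50L, te_min_identity = 0.9,
                        anchor_min_len = 80L, anchor_min_identity = 0.95,
                        anchor_margin = 10L, te_stride = 2L, verbose = FALSE) {
  if (is.null(names(panel)) || any(!nzchar(names(panel))))
    stop("panel entries must be named by accession id")
  genome_chr <- genome_as_character(genome)
  windows <- make_windows(genome_chr, size = window_size)
  gidx <- seed_index(genome_chr)
  tidx <- seed_index(library_consensus(library))
  support_list <- list()
  log <- list()
  for (acc in names(panel)) {
    entry <- panel[[acc]]
    reads <- tryCatch(load_read_pair(entry), error = function(e) {
      warning(sprintf("accession %s dropped: %s", acc, conditionMessage(e)))
      NULL
    })
    if (is.null(reads)) next
    jp <- classify_pairs(reads$mate1, reads$mate2, tidx,
                         min_len = te_min_len, min_identity = te_min_identity,
                         stride = te_stride)
    sup <- collect_support(jp, gidx, windows, accession = acc,
                           min_len = anchor_min_len,
                           min_identity = anchor_min_identity,
                           margin = anchor_margin)
    support_list[[acc]] <- sup
    log[[acc]] <- c(attr(jp, "counts"), anchored = sum(sup$count))
    if (verbose)
      message(sprintf("[%s] pairs=%d junction=%d anchored=%d", acc,
                      attr(jp, "counts")[["pairs"]],
                      attr(jp, "counts")[["junction"]], sum(sup$count)))
  }
  support <- data.table::rbindlist(support_list)
  opened <- first_pass(support, open_threshold)
  calls <- second_pass(support, opened, rescue_threshold, open_threshold)
  mat <- build_matrix(calls, names(panel)[names(panel) %in% names(support_list)])
  structure(list(matrix = mat, calls = calls, support = support, opened = opened,
                 windows = windows, log = log),
            class = "tip_result")
}

load_read_pair <- function(entry) {
  if (!is.null(entry$mate1)) {
    list(mate1 = as.character(entry$mate1), mate2 = as.character(entry$mate2))
  } else if (!is.null(entry$fq1)) {
    list(mate1 = as.character(Biostrings::readDNAStringSet(entry$fq1, format = "fastq")),
         mate2 = as.character(Biostrings::readDNAStringSet(entry$fq2, format = "fastq")))
  } else stop("accession entry needs mate1/mate2 or fq1/fq2")
}

#' @export
print.tip_result <- function(x, ...) {
  cat(sprintf("<tip_result> %d events x %d accessions (%d calls, %d opened)\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$calls), nrow(x$opened)))
  invisible(x)
}

#' Write the TIP matrix and companion files
#'
#' Emits the presence/absence matrix TSV (rows `family:window_id`), the
#' per-call support TSV, and a BED5 of TIP windows (name = family, score =
#' number of carrier accessions).
#'
#' @param result A `tip_result` from [detect_tips()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_tip_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, "tip_matrix.tsv")
  m <- result$matrix
  utils::write.table(data.frame(event = rownames(m), m, check.names = FALSE),
                     mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  spath <- file.path(dir, "tip_calls.tsv")
  utils::write.table(result$calls, spath, sep = "\t", quote = FALSE, row.names = FALSE)
  bpath <- file.path(dir, "tip_windows.bed")
  if (nrow(m)) {
    ev <- parse_event_id(rownames(m))
    w <- parse_window_id(ev$window_id)
    write_bed(data.frame(chrom = w$chrom, start = w$start, end = w$end,
                         name = ev$family_id, score = rowSums(m)), bpath)
  } else {
    file.create(bpath)
  }
  invisible(c(matrix = mpath, calls = spath, bed = bpath))
}

#' Read a TIP matrix written by [write_tip_result()]
#'
#' @param path Matrix TSV path.
#' @return A `tip_matrix`.
#' @export
read_tip_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df[[1]]
  class(m) <- c("tip_matrix", class(m))
  m
}
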