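# Brute-force tile-placement oracle for mappability, independent of the
# package's seeded banded aligner.
#
# Completeness argument (pigeonhole): a qualifying placement covers >= 80 bp
# of the 100-bp tile at >= 95% identity, i.e. at most 5 edits inside the
# covered span; 5 edits cut a >= 80-bp span into at most 6 exact runs, so the
# longest exact run is >= ceiling(75/6) = 13 bp. Every qualifying placement
# therefore shares at least one exact 13-mer with the tile, and enumerating
# all exact 13-mer matches (both strands) enumerates a superset of all
# qualifying placements. Candidates are verified with the full (unbanded)
# local DP of Biostrings::pairwiseAlignment under the same scoring.

oracle_base_codes <- function(g) {
  match(strsplit(g, "")[[1]], c("A", "C", "G", "T")) - 1L
}

oracle_kmer_codes <- function(base, k = 13L) {
  n <- length(base) - k + 1L
  if (n < 1L) return(numeric(0))
  code <- numeric(n)
  for (j in seq_len(k)) code <- code * 4 + base[j:(j + n - 1L)]
  code  # NA where any base was non-ACGT
}

# All (i, j) 0-based genome positions (i on forward tile side) sharing a
# 13-mer, j on the given strand of the genome.
oracle_shared_kmers <- function(fwd_codes, other_codes, self = FALSE) {
  ok_f <- which(!is.na(fwd_codes)); ok_o <- which(!is.na(other_codes))
  a <- data.table::data.table(code = fwd_codes[ok_f], i = ok_f - 1L)
  b <- data.table::data.table(code = other_codes[ok_o], j = ok_o - 1L)
  if (self) {
    # only codes occurring more than once can yield a non-self pair
    dup <- unique(a$code[duplicated(a$code)])
    a <- a[a$code %in% dup, ]; b <- b[b$code %in% dup, ]
  } else {
    common <- intersect(a$code, b$code)
    a <- a[a$code %in% common, ]; b <- b[b$code %in% common, ]
  }
  m <- merge(a, b, by = "code", allow.cartesian = TRUE)
  as.data.frame(m[, c("i", "j")])
}

oracle_qualifying_placements <- function(tile, g, centers, min_len = 80L,
                                         min_ident = 0.95) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  scores <- numeric(0)
  tile_rc <- fixture_revcomp(tile)
  for (cs in centers) {
    # fast path: an exact full-length copy at the expected start needs no DP
    at <- substring(g, cs, cs + nchar(tile) - 1L)
    if (at == tile || at == tile_rc) { scores <- c(scores, nchar(tile)); next }
    lo <- max(1L, cs - 60L); hi <- min(nchar(g), cs + nchar(tile) + 60L)
    region <- substring(g, lo, hi)
    for (qs in c(tile, fixture_revcomp(tile))) {
      aln <- Biostrings::pairwiseAlignment(qs, region, type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 4, gapExtension = 1)
      pat <- Biostrings::pattern(aln)
      covered <- Biostrings::width(pat@range)
      alnlen <- nchar(as.character(pat))
      matches <- Biostrings::nmatch(aln)
      if (covered >= min_len && alnlen > 0 && matches / alnlen >= min_ident) {
        scores <- c(scores, Biostrings::score(aln))
        break  # one placement per center; strands cannot both qualify here
      }
    }
  }
  scores
}

# Exhaustive-by-pigeonhole per-window unique-tile fraction.
oracle_mappability <- function(genome, windows, tile_len = 100L, min_len = 80L,
                               min_ident = 0.95, margin = 10L, k = 13L) {
  g <- toupper(genome[[1]])
  L <- nchar(g)
  base <- oracle_base_codes(g)
  fwd <- oracle_kmer_codes(base, k)
  rcg <- fixture_revcomp(g)
  rc <- oracle_kmer_codes(oracle_base_codes(rcg), k)
  pf <- oracle_shared_kmers(fwd, fwd, self = TRUE)
  pf <- pf[pf$i != pf$j, , drop = FALSE]
  pf$rc <- rep(FALSE, nrow(pf))
  pr <- oracle_shared_kmers(fwd, rc)
  # convert rc-strand k-mer start j (on revcomp genome) to forward interval
  # start: [L - j - k, L - j)
  pr$j <- L - pr$j - k
  # drop palindromic self-overlap
  pr <- pr[abs(pr$j - pr$i) > tile_len, , drop = FALSE]
  pr$rc <- rep(TRUE, nrow(pr))
  cand <- rbind(pf, pr)
  # tile of a position (non-overlapping tiling shared with the implementation)
  frac <- stats::setNames(rep(NA_real_, length(windows)), windows$window_id)
  tile_starts_all <- list(); tile_window <- integer(0)
  for (w in seq_along(windows)) {
    n <- (windows$end0[w] - windows$start0[w]) %/% tile_len
    if (n == 0L) { frac[w] <- NaN; next }
    st <- windows$start0[w] + (seq_len(n) - 1L) * tile_len
    tile_starts_all[[w]] <- st
    tile_window <- c(tile_window, rep(w, n))
  }
  starts <- unlist(tile_starts_all)
  # map each candidate k-mer hit to its tile and expected placement start
  tidx <- findInterval(cand$i, starts)
  inside <- tidx >= 1 & cand$i < starts[pmax(tidx, 1)] + tile_len
  cand <- cand[inside, , drop = FALSE]; tidx <- tidx[inside]
  off <- cand$i - starts[tidx]
  # 0-based expected placement start: for a forward placement the shared
  # k-mer sits at the same tile offset; for a reverse-strand placement the
  # tile offset maps to the far end of the placed interval
  exp_start <- ifelse(cand$rc, cand$j + k - tile_len + off, cand$j - off)
  # a candidate whose verification region would overlap the tile's own locus
  # only rediscovers the self placement; genuine duplicate placements in the
  # simulated genomes are kilobases away, so exclude the self neighbourhood
  away <- abs(exp_start - starts[tidx]) >= 150
  cand <- cand[away, , drop = FALSE]; tidx <- tidx[away]
  exp_start <- exp_start[away]
  uniq <- rep(TRUE, length(starts))
  by_tile <- split(exp_start, tidx)
  for (nm in names(by_tile)) {
    ti <- as.integer(nm)
    es <- sort(by_tile[[nm]])
    # cluster candidate starts within 50 bp; count shared 13-mers per cluster.
    # A qualifying placement keeps >= 75 exact query bases in <= 6 runs, so at
    # least 3 intact 13-mers land in its cluster: smaller clusters are random
    # collisions and can be rejected without the DP verification.
    brk <- cumsum(c(TRUE, diff(es) > 50))
    cl_n <- tabulate(brk)
    cl_start <- es[c(TRUE, diff(es) > 50)]
    centers <- cl_start[cl_n >= 3L] + 1L  # 1-based
    if (length(centers) == 0L) next
    qual <- oracle_qualifying_placements(substring(g, starts[ti] + 1L,
                                                   starts[ti] + tile_len),
                                         g, centers, min_len, min_ident)
    n_qual <- length(qual) + 1L   # + the tile's own locus (exact, score 100)
    best <- 100; second <- if (length(qual)) max(qual) else NA
    uniq[ti] <- n_qual == 1L || (best - second) >= margin
  }
  for (w in seq_along(windows)) {
    if (is.null(tile_starts_all[[w]])) next
    sel <- tile_window == w
    frac[w] <- mean(uniq[sel])
  }
  frac
}

# Brute-force minimum window-to-gene distance (all-pairs scan).
oracle_min_gene_distance <- function(win, genes) {
  vapply(seq_len(nrow(win)), function(i) {
    same <- genes$chrom == win$chrom[i]
    if (!any(same)) return(NA_real_)
    gaps <- vapply(which(same), function(j) {
      if (genes$start[j] < win$end[i] && win$start[i] < genes$end[j]) return(0)
      if (genes$start[j] >= win$end[i]) return(genes$start[j] - win$end[i])
      win$start[i] - genes$end[j]
    }, numeric(1))
    min(gaps)
  }, numeric(1))
}
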