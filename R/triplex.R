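# Simplified RNA:DNA triplex search. The third (RNA) strand reads the purine
# strand of the DNA duplex through Hoogsteen (parallel / pyrimidine motif) or
# reverse-Hoogsteen (antiparallel / purine motif) base triplets. The engine
# is a mismatch-tolerant exhaustive diagonal scan: for every alignment of an
# RNA window against a duplex window, on either duplex strand and in either
# orientation, it reports the containment-maximal windows whose mismatch rate
# and purine/pyrimidine purity satisfy the configured thresholds.

#' Canonical triplex pairing rules
#'
#' The default rule set encodes the canonical triplet code: parallel
#' (pyrimidine motif) `U.A:T` and `C.G:C`; antiparallel (purine motif)
#' `A.A:T`, `G.G:C` and `U.A:T`. Each triplet is written as (third-strand
#' RNA base, purine base of the duplex pair); RNA `U` is represented as `T`
#' internally.
#'
#' @param name Rule-set label.
#' @param parallel,antiparallel Lists of length-2 character vectors
#'   `c(rna_base, duplex_purine_base)`.
#' @return An object of class `triplex_rules` holding one 4x4 logical match
#'   matrix per orientation (rows: RNA base, columns: duplex purine-strand
#'   base).
#' @export
triplex_rules <- function(name = "canonical",
                          parallel = list(c("T", "A"), c("C", "G")),
                          antiparallel = list(c("A", "A"), c("G", "G"),
                                              c("T", "A"))) {
  build <- function(trips, label) {
    if (!length(trips)) stop("empty triplet list for ", label, call. = FALSE)
    m <- matrix(FALSE, 5L, 5L, dimnames = list(c(.BASES, "N"), c(.BASES, "N")))
    for (t in trips) {
      t <- chartr("U", "T", toupper(t))
      if (length(t) != 2L || !all(t %in% .BASES)) {
        stop("triplets must be pairs of bases in ACGT/U", call. = FALSE)
      }
      m[t[1L], t[2L]] <- TRUE
    }
    m
  }
  structure(list(name = name,
                 parallel = build(parallel, "parallel"),
                 antiparallel = build(antiparallel, "antiparallel")),
            class = "triplex_rules")
}

# Containment-maximal qualifying windows on one diagonal.
#
# `match` is the logical compliance vector along the diagonal. A window
# [a, e) (0-based prefix coordinates) qualifies when its first and last
# position match, its length is >= min_len, and mismatches <= rate * length
# (real-valued, no flooring). Returned are the windows not contained in any
# other qualifying window of the same diagonal.
.triplex_windows <- function(match, rate, min_len) {
  L <- length(match)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0))
  if (L < min_len || !any(match)) return(empty)
  M <- c(0L, cumsum(!match))          # M[i + 1] = mismatches in first i chars
  g <- M - rate * (0:L)
  starts <- which(match) - 1L         # window may start where a match sits
  ends <- which(match)                # and must end on a match
  ge <- g[ends + 1L]
  ord <- order(ge, ends)
  ends_sorted <- ends[ord]
  ge_sorted <- ge[ord]
  prefmax <- cummax(ends_sorted)
  cnt <- findInterval(g[starts + 1L] + 1e-9, ge_sorted)
  f <- rep(-1L, length(starts))
  f[cnt > 0L] <- prefmax[cnt[cnt > 0L]]
  keep <- f - starts >= min_len
  a <- starts[keep]
  e <- f[keep]
  if (!length(a)) return(empty)
  # drop windows contained in an earlier-starting window reaching at least as far
  runmax <- cummax(c(-1L, e[-length(e)]))
  keep2 <- e > runmax
  a <- a[keep2]
  e <- e[keep2]
  data.frame(start = a, end = e, mismatches = M[e + 1L] - M[a + 1L])
}

#' Find putative RNA:DNA triplex hits between an lncRNA and promoters
#'
#' Enumerates, for both duplex strands and both orientations, all
#' containment-maximal alignment windows of length at least `min_len` whose
#' triplet compliance satisfies `max_mismatch_rate` and whose target site has
#' purine (or pyrimidine) purity at least `min_purity`. The hit score is
#' `matches - mismatch_penalty * mismatches`.
#'
#' @param rna The lncRNA sequence (character; `U` accepted) or a path-free
#'   string already read with [read_rna_sequence()].
#' @param promoters A [promoter_set].
#' @param rules A [triplex_rules] object.
#' @param min_len Minimum triplex length, at least 10 nt.
#' @param max_mismatch_rate Maximum fraction of non-compliant triplets.
#' @param min_purity Minimum purine-or-pyrimidine fraction of the TTS.
#' @param mismatch_penalty Score penalty per mismatch.
#' @return A data.frame of hits with 0-based half-open `tfo_start`/`tfo_end`
#'   (on the RNA), `gene_id`, `tts_start`/`tts_end` (on the promoter `+`
#'   strand), `orientation`, `strand`, `matches`, `mismatches`, `score`,
#'   ordered by (gene, tts_start, tfo_start, orientation, strand).
#' @export
find_triplex_pairs <- function(rna, promoters, rules = triplex_rules(),
                               min_len = 20L, max_mismatch_rate = 0.1,
                               min_purity = 0.8, mismatch_penalty = 1) {
  if (min_len < 10L) {
    stop("min_len must be >= 10 (sub-biological triplex length)", call. = FALSE)
  }
  stopifnot(inherits(rules, "triplex_rules"), inherits(promoters, "promoter_set"))
  rna <- chartr("U", "T", toupper(rna))
  rna_f <- seq_to_int(rna)
  rna_r <- rev(rna_f)
  n <- length(rna_f)
  if (n < min_len) stop("RNA shorter than min_len", call. = FALSE)

  out <- list()
  for (pi in seq_len(nrow(promoters))) {
    gene <- promoters$gene_id[pi]
    prom <- promoters$sequence[pi]
    prom_f <- seq_to_int(prom)
    prom_rc <- seq_to_int(revcomp(prom))
    m <- length(prom_f)
    if (m < min_len) next
    pur <- c(0L, cumsum(prom_f == 1L | prom_f == 3L))
    nn <- c(0L, cumsum(prom_f == 5L))

    combos <- list(
      list(strand = "+", orientation = "parallel", x = rna_f, y = prom_f,
           mat = rules$parallel, xrev = FALSE, yrc = FALSE),
      list(strand = "+", orientation = "antiparallel", x = rna_r, y = prom_f,
           mat = rules$antiparallel, xrev = TRUE, yrc = FALSE),
      list(strand = "-", orientation = "parallel", x = rna_f, y = prom_rc,
           mat = rules$parallel, xrev = FALSE, yrc = TRUE),
      list(strand = "-", orientation = "antiparallel", x = rna_r, y = prom_rc,
           mat = rules$antiparallel, xrev = TRUE, yrc = TRUE))

    for (cb in combos) {
      x <- cb$x
      y <- cb$y
      for (d in seq.int(min_len - n, m - min_len)) {
        i0 <- max(1L, 1L - d)
        i1 <- min(n, m - d)
        if (i1 - i0 + 1L < min_len) next
        v <- cb$mat[cbind(x[i0:i1], y[(i0 + d):(i1 + d)])]
        w <- .triplex_windows(v, max_mismatch_rate, min_len)
        if (!nrow(w)) next
        xs <- (i0 - 1L) + w$start
        xe <- (i0 - 1L) + w$end
        ys <- xs + d
        ye <- xe + d
        tfo_start <- if (cb$xrev) n - xe else xs
        tfo_end <- if (cb$xrev) n - xs else xe
        tts_start <- if (cb$yrc) m - ye else ys
        tts_end <- if (cb$yrc) m - ys else ye
        len <- xe - xs
        pur_ct <- pur[tts_end + 1L] - pur[tts_start + 1L]
        n_ct <- nn[tts_end + 1L] - nn[tts_start + 1L]
        pyr_ct <- len - pur_ct - n_ct
        purity <- pmax(pur_ct, pyr_ct) / len
        ok <- purity >= min_purity
        if (!any(ok)) next
        out[[length(out) + 1L]] <- data.frame(
          tfo_start = tfo_start[ok], tfo_end = tfo_end[ok],
          gene_id = gene,
          tts_start = tts_start[ok], tts_end = tts_end[ok],
          orientation = cb$orientation, strand = cb$strand,
          matches = (len - w$mismatches)[ok],
          mismatches = w$mismatches[ok],
          score = (len - w$mismatches - mismatch_penalty * w$mismatches)[ok],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tfo_start = integer(0), tfo_end = integer(0),
                      gene_id = character(0), tts_start = integer(0),
                      tts_end = integer(0), orientation = character(0),
                      strand = character(0), matches = integer(0),
                      mismatches = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$gene_id, hits$tts_start, hits$tfo_start,
                     hits$orientation, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Rank triplex-forming oligonucleotide (TFO) regions
#'
#' Merges overlapping TFO windows on the RNA into regions, counts the
#' triplex target sites supporting each region, and ranks regions by
#' (supporting TTS count, total score). The top region is labeled `TFO1`;
#' its supporting hits can be exported for motif analysis.
#'
#' @param hits A hit table from [find_triplex_pairs()].
#' @param merge_overlap Merge overlapping TFO windows into regions
#'   (default `TRUE`); if `FALSE` every distinct window is its own region.
#' @return A data.frame of regions in rank order with `label`, `tfo_start`,
#'   `tfo_end`, `n_tts`, `total_score`, plus a `region` column added to the
#'   hits, returned as attribute `hits`.
#' @export
rank_tfos <- function(hits, merge_overlap = TRUE) {
  if (!nrow(hits)) {
    return(data.frame(label = character(0), tfo_start = integer(0),
                      tfo_end = integer(0), n_tts = integer(0),
                      total_score = numeric(0)))
  }
  iv <- unique(hits[, c("tfo_start", "tfo_end")])
  iv <- iv[order(iv$tfo_start, iv$tfo_end), , drop = FALSE]
  if (merge_overlap) {
    rs <- iv$tfo_start[1L]
    re <- iv$tfo_end[1L]
    regions <- list()
    for (i in seq_len(nrow(iv))[-1L]) {
      if (iv$tfo_start[i] < re) {
        re <- max(re, iv$tfo_end[i])
      } else {
        regions[[length(regions) + 1L]] <- c(rs, re)
        rs <- iv$tfo_start[i]
        re <- iv$tfo_end[i]
      }
    }
    regions[[length(regions) + 1L]] <- c(rs, re)
    reg <- do.call(rbind, regions)
  } else {
    reg <- as.matrix(iv)
  }
  reg_df <- data.frame(tfo_start = reg[, 1L], tfo_end = reg[, 2L])
  idx <- vapply(seq_len(nrow(hits)), function(i) {
    which(reg_df$tfo_start <= hits$tfo_start[i] &
            reg_df$tfo_end >= hits$tfo_end[i])[1L]
  }, integer(1))
  reg_df$n_tts <- as.integer(tabulate(idx, nbins = nrow(reg_df)))
  reg_df$total_score <- vapply(seq_len(nrow(reg_df)), function(r) {
    sum(hits$score[idx == r])
  }, numeric(1))
  o <- order(-reg_df$n_tts, -reg_df$total_score, reg_df$tfo_start)
  reg_df <- reg_df[o, , drop = FALSE]
  reg_df$label <- paste0("TFO", seq_len(nrow(reg_df)))
  reg_df <- reg_df[, c("label", "tfo_start", "tfo_end", "n_tts", "total_score")]
  rownames(reg_df) <- NULL
  hits$region <- reg_df$label[match(idx, o)]
  attr(reg_df, "hits") <- hits
  reg_df
}
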