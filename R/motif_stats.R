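# PWM scanning with exact null p-values, relative motif enrichment between
# promoter sets, ungapped motif-motif similarity with a permutation null,
# and TFBS enrichment on best per-promoter scores.
#
# Scoring lives on an integer grid: per-column log-odds (bits) are rounded
# to multiples of `delta`, window scores are sums of grid values, and the
# null distribution of the window score over background-distributed words is
# obtained by column-wise convolution on the same grid. Window score and
# null therefore never disagree about ties, and exact enumeration over all
# 4^w words reproduces the p-values identically.

# per-column integer score grid; row 5 holds the score of N, defined as the
# background expectation of the column score (keeps scan length invariant)
.motif_score_units <- function(motif, background = NULL, delta = 1e-3,
                               pseudocount = 0.01) {
  bg <- background %||% motif$background
  p <- (motif$probs + pseudocount * bg) / (1 + pseudocount)
  s <- log2(p / bg)
  u <- round(s / delta)
  rbind(u, round(colSums(bg * s) / delta))
}

# exact null distribution of the grid score: survival function over
# background-distributed words
.score_distribution <- function(units, background) {
  u4 <- units[1:4, , drop = FALSE]
  pmf <- 1
  min_total <- 0
  for (j in seq_len(ncol(u4))) {
    u <- u4[, j]
    um <- min(u)
    new <- numeric(length(pmf) + max(u) - um)
    for (b in 1:4) {
      idx <- seq_along(pmf) + (u[b] - um)
      new[idx] <- new[idx] + pmf * background[b]
    }
    pmf <- new
    min_total <- min_total + um
  }
  sf <- rev(cumsum(rev(pmf)))
  list(min_units = min_total, sf = pmin(sf, 1))
}

# P(S >= s) under the null, vectorized over grid scores s
.score_pvalue <- function(dist, s) {
  k <- s - dist$min_units + 1
  p <- numeric(length(s))
  p[k < 1] <- 1
  p[k > length(dist$sf)] <- 0
  inr <- k >= 1 & k <= length(dist$sf)
  p[inr] <- dist$sf[k[inr]]
  p
}

# smallest grid score with p-value <= alpha (Inf if unreachable)
.score_threshold <- function(dist, alpha) {
  k <- which(dist$sf <= alpha)
  if (!length(k)) return(Inf)
  dist$min_units + k[1L] - 1
}

# grid scores of all windows of a coded sequence
.window_units <- function(seq_int, units) {
  w <- ncol(units)
  nwin <- length(seq_int) - w + 1L
  if (nwin < 1L) return(numeric(0))
  total <- numeric(nwin)
  for (j in seq_len(w)) {
    total <- total + units[, j][seq_int[j:(j + nwin - 1L)]]
  }
  total
}

#' Scan promoters with a motif, reporting hits with exact null p-values
#'
#' Each window on either strand is scored by the summed log-odds
#' `log2(p_motif / p_background)` in bits (on a discretized grid, see
#' `delta`); its p-value is the exact probability, over background-
#' distributed words, of a score at least as high, computed by column-wise
#' convolution of the score distribution. Windows with `p <= alpha` are
#' reported. `N` scores as the background expectation of the column score.
#'
#' @param promoters A [promoter_set] (or a single-row subset).
#' @param motif A [motif_model].
#' @param background Length-4 background frequencies (defaults to the
#'   motif's own background).
#' @param alpha Per-window p-value threshold for reporting a hit.
#' @param delta Score grid step in bits.
#' @param pseudocount Additive pseudocount applied to motif probabilities at
#'   scoring time.
#' @return A data.frame of hits: `motif_id`, `gene_id`, `pos` (0-based start
#'   on the `+` strand), `strand`, `logodds` (bits), `pvalue`.
#' @export
scan_motif <- function(promoters, motif, background = NULL, alpha = 1e-4,
                       delta = 1e-3, pseudocount = 0.01) {
  stopifnot(inherits(promoters, "promoter_set"), inherits(motif, "motif_model"))
  bg <- background %||% motif$background
  u_fwd <- .motif_score_units(motif, bg, delta, pseudocount)
  u_rev <- .motif_score_units(motif_rc(motif), bg, delta, pseudocount)
  d_fwd <- .score_distribution(u_fwd, bg)
  d_rev <- .score_distribution(u_rev, bg)
  out <- list()
  for (i in seq_len(nrow(promoters))) {
    if (promoters$length[i] < motif$width) {
      warning(sprintf("promoter '%s' shorter than motif '%s'",
                      promoters$gene_id[i], motif$motif_id))
      next
    }
    si <- seq_to_int(promoters$sequence[i])
    for (sd in list(list("+", u_fwd, d_fwd), list("-", u_rev, d_rev))) {
      sc <- .window_units(si, sd[[2L]])
      pv <- .score_pvalue(sd[[3L]], sc)
      hit <- which(pv <= alpha)
      if (!length(hit)) next
      out[[length(out) + 1L]] <- data.frame(
        motif_id = motif$motif_id, gene_id = promoters$gene_id[i],
        pos = hit - 1L, strand = sd[[1L]],
        logodds = sc[hit] * delta, pvalue = pv[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(motif_id = character(0), gene_id = character(0),
                      pos = integer(0), strand = character(0),
                      logodds = numeric(0), pvalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$gene_id, hits$pos, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# best grid-score (bits) per promoter over both strands; NA if too short
.best_scores <- function(promoters, motif, background, delta, pseudocount) {
  u_fwd <- .motif_score_units(motif, background, delta, pseudocount)
  u_rev <- .motif_score_units(motif_rc(motif), background, delta, pseudocount)
  vapply(seq_len(nrow(promoters)), function(i) {
    if (promoters$length[i] < motif$width) return(NA_real_)
    si <- seq_to_int(promoters$sequence[i])
    max(.window_units(si, u_fwd), .window_units(si, u_rev)) * delta
  }, numeric(1))
}

# ACGT composition of a promoter set (uniform fallback)
promoter_background <- function(promoters) {
  counts <- colSums(vapply(promoters$sequence, function(s) {
    tabulate(seq_to_int(s), nbins = 5L)[1:4]
  }, numeric(4)) |> t())
  if (sum(counts) == 0) return(rep(0.25, 4))
  as.numeric(counts / sum(counts))
}

#' One-sided enrichment test on a presence 2x2 table
#'
#' Fisher's exact test (one-sided, enrichment in the target set) on the
#' motif-presence table, plus a Haldane-corrected presence ratio
#' `((t + 0.5)/(T + 1)) / ((b + 0.5)/(B + 1))`.
#'
#' @param n_target_with,n_target Promoters with >= 1 hit / total, target set.
#' @param n_background_with,n_background Same for the background set.
#' @return A list with `pvalue` and `ratio`.
#' @export
enrichment_test <- function(n_target_with, n_target,
                            n_background_with, n_background) {
  if (n_target_with > n_target || n_background_with > n_background) {
    stop("presence counts exceed set sizes", call. = FALSE)
  }
  tab <- matrix(c(n_target_with, n_target - n_target_with,
                  n_background_with, n_background - n_background_with),
                nrow = 2L)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  ratio <- ((n_target_with + 0.5) / (n_target + 1)) /
    ((n_background_with + 0.5) / (n_background + 1))
  list(pvalue = p, ratio = ratio)
}

#' Relative motif enrichment between target and background promoters
#'
#' A promoter "contains" a motif when it has at least one scan hit at
#' `scan_alpha`; per motif the presence counts are compared between the two
#' sets with a one-sided Fisher's exact test; `significant` flags
#' `p < alpha`.
#'
#' @param targets,background_promoters Two [promoter_set]s.
#' @param motifs List of [motif_model]s.
#' @param scan_alpha Per-window p-value defining a hit.
#' @param alpha Enrichment significance level (default 0.05).
#' @param background_freqs Scan background; defaults to the background
#'   promoter composition.
#' @param delta,pseudocount Scoring parameters, see [scan_motif()].
#' @return A data.frame, one row per motif, with presence counts,
#'   `enrichment_ratio`, `pvalue` and `significant`.
#' @export
relative_enrichment <- function(targets, background_promoters, motifs,
                                scan_alpha = 1e-4, alpha = 0.05,
                                background_freqs = NULL, delta = 1e-3,
                                pseudocount = 0.01) {
  stopifnot(inherits(targets, "promoter_set"),
            inherits(background_promoters, "promoter_set"))
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  bg <- background_freqs %||% promoter_background(background_promoters)

  presence <- function(promoters, motif) {
    u_fwd <- .motif_score_units(motif, bg, delta, pseudocount)
    u_rev <- .motif_score_units(motif_rc(motif), bg, delta, pseudocount)
    thr_f <- .score_threshold(.score_distribution(u_fwd, bg), scan_alpha)
    thr_r <- .score_threshold(.score_distribution(u_rev, bg), scan_alpha)
    vapply(seq_len(nrow(promoters)), function(i) {
      if (promoters$length[i] < motif$width) return(FALSE)
      si <- seq_to_int(promoters$sequence[i])
      any(.window_units(si, u_fwd) >= thr_f) ||
        any(.window_units(si, u_rev) >= thr_r)
    }, logical(1))
  }

  rows <- lapply(motifs, function(m) {
    tw <- sum(presence(targets, m))
    bw <- sum(presence(background_promoters, m))
    et <- enrichment_test(tw, nrow(targets), bw, nrow(background_promoters))
    data.frame(motif_id = m$motif_id,
               n_target_with = tw, n_target = nrow(targets),
               n_background_with = bw, n_background = nrow(background_promoters),
               enrichment_ratio = et$ratio, pvalue = et$pvalue,
               significant = et$pvalue < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# best ungapped alignment of two probability matrices over all offsets with
# at least min_overlap overlapping columns; returns r = -Inf if none
.best_alignment <- function(p1, p2, min_overlap = 4L) {
  w1 <- ncol(p1)
  w2 <- ncol(p2)
  best <- list(r = -Inf, offset = NA_integer_)
  for (off in seq.int(-(w2 - min_overlap), w1 - min_overlap)) {
    i <- seq.int(max(1L, 1L + off), min(w1, w2 + off))
    if (length(i) < min_overlap) next
    a <- as.vector(p1[, i, drop = FALSE])
    b <- as.vector(p2[, i - off, drop = FALSE])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (r > best$r) best <- list(r = r, offset = off)
  }
  best
}

#' Ungapped motif-motif similarity with a column-permutation null
#'
#' Finds the best Pearson correlation of aligned probability columns over
#' all ungapped offsets with at least `min_overlap` overlapping columns, in
#' both orientations (the second motif is also tried reverse-complemented).
#' The p-value is estimated against a null in which the columns of the
#' second motif are randomly permuted.
#'
#' @param m1,m2 Two [motif_model]s.
#' @param n_perm Number of column permutations.
#' @param min_overlap Minimum overlapping columns.
#' @param seed RNG seed for the permutation null.
#' @return A list with `best_offset`, `orientation` (`"forward"` or
#'   `"reverse_complement"`), `r` and `pvalue`.
#' @export
motif_similarity <- function(m1, m2, n_perm = 1000L, min_overlap = 4L,
                             seed = 1L) {
  stopifnot(inherits(m1, "motif_model"), inherits(m2, "motif_model"))
  score_pair <- function(p2) {
    f <- .best_alignment(m1$probs, p2, min_overlap)
    r <- .best_alignment(m1$probs, p2[4:1, rev(seq_len(ncol(p2))), drop = FALSE],
                         min_overlap)
    if (f$r >= r$r) c(f, orientation = "forward")
    else c(r, orientation = "reverse_complement")
  }
  obs <- score_pair(m2$probs)
  if (!is.finite(obs$r)) {
    stop("motifs have no alignable overlap of at least ", min_overlap,
         " columns", call. = FALSE)
  }
  set.seed(seed)
  perm_r <- vapply(seq_len(n_perm), function(k) {
    score_pair(m2$probs[, sample.int(m2$width), drop = FALSE])$r
  }, numeric(1))
  pvalue <- (1 + sum(perm_r >= obs$r - 1e-12)) / (n_perm + 1)
  list(best_offset = obs$offset, orientation = obs$orientation,
       r = obs$r, pvalue = pvalue)
}

#' TFBS enrichment on best per-promoter scores
#'
#' For every motif of a PWM library, the best log-odds hit per promoter is
#' collected in the target and background sets and compared with a one-sided
#' Welch t test (target > background). Rows are flagged significant at raw
#' `p < alpha` (the screening rule used for candidate TFs); a
#' Benjamini-Hochberg column is reported alongside.
#'
#' @param targets,background_promoters Two [promoter_set]s.
#' @param pwm_library List of [motif_model]s.
#' @param motif_to_tf Data.frame with columns `motif_id`, `tf_name`
#'   (several rows per motif allowed), mapping motifs to the transcription
#'   factors able to bind them.
#' @param alpha Significance level on the raw p-value.
#' @param background_freqs Scan background; defaults to the background
#'   promoter composition.
#' @param delta,pseudocount Scoring parameters, see [scan_motif()].
#' @return A data.frame per motif: `tf_names` (`;`-separated),
#'   `mean_best_target`, `mean_best_background`, `z` (Welch statistic),
#'   `pvalue`, `p_bh`, `significant`.
#' @export
tfbs_enrichment <- function(targets, background_promoters, pwm_library,
                            motif_to_tf, alpha = 0.05,
                            background_freqs = NULL, delta = 1e-3,
                            pseudocount = 0.01) {
  stopifnot(inherits(targets, "promoter_set"),
            inherits(background_promoters, "promoter_set"))
  if (inherits(pwm_library, "motif_model")) pwm_library <- list(pwm_library)
  if (!all(c("motif_id", "tf_name") %in% names(motif_to_tf))) {
    stop("motif_to_tf needs columns motif_id, tf_name", call. = FALSE)
  }
  bg <- background_freqs %||% promoter_background(background_promoters)
  rows <- lapply(pwm_library, function(m) {
    x <- .best_scores(targets, m, bg, delta, pseudocount)
    y <- .best_scores(background_promoters, m, bg, delta, pseudocount)
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    wt <- tryCatch(stats::t.test(x, y, alternative = "greater",
                                 var.equal = FALSE),
                   error = function(e) NULL)
    z <- if (is.null(wt)) 0 else unname(wt$statistic)
    p <- if (is.null(wt)) 1 else wt$p.value
    tfs <- motif_to_tf$tf_name[motif_to_tf$motif_id == m$motif_id]
    data.frame(motif_id = m$motif_id,
               tf_names = paste(tfs, collapse = ";"),
               mean_best_target = mean(x),
               mean_best_background = mean(y),
               z = z, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant <- out$pvalue < alpha
  rownames(out) <- NULL
  out
}
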