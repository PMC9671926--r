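# Independent oracles used by module and acceptance tests. These re-derive
# the expected results from first principles (literal rule lists, exhaustive
# enumeration, closed forms) and share no code path with the implementation.

# Exhaustive all-window-pairs triplex oracle for short sequences: enumerates
# every equal-length window pair in every orientation/strand, qualifies each
# window literally, and keeps the containment-maximal ones per diagonal by
# pairwise comparison.
oracle_triplex <- function(rna, prom, gene = "g", min_len = 10L, rate = 0,
                           min_purity = 0, penalty = 1) {
  rna <- chartr("U", "T", toupper(rna))
  prom <- toupper(prom)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rn <- strsplit(rna, "")[[1]]
  pm <- strsplit(prom, "")[[1]]
  prc <- rev(unname(comp[pm]))
  allowed <- list(parallel = c("T|A", "C|G"),
                  antiparallel = c("A|A", "G|G", "T|A"))
  n <- length(rn)
  m <- length(pm)
  pur_frac <- function(s, e) {
    w <- pm[(s + 1):e]
    max(sum(w %in% c("A", "G")), sum(w %in% c("C", "T"))) / (e - s)
  }
  rows <- list()
  for (orient in c("parallel", "antiparallel")) for (strand in c("+", "-")) {
    x <- if (orient == "parallel") rn else rev(rn)
    y <- if (strand == "+") pm else prc
    for (d in seq.int(-(n - 1L), m - 1L)) {
      i0 <- max(1L, 1L - d)
      i1 <- min(n, m - d)
      L <- i1 - i0 + 1L
      if (L < min_len) next
      xi <- x[i0:i1]
      yi <- y[(i0 + d):(i1 + d)]
      v <- paste(xi, yi, sep = "|") %in% allowed[[orient]]
      if (!any(v)) next
      mism <- cumsum(!v)
      S <- matrix(seq_len(L), L, L)
      E <- t(S)
      len <- E - S + 1L
      mm <- matrix(mism[E], L, L) - matrix(c(0L, mism)[S], L, L)
      qual <- len >= min_len & matrix(v[S], L, L) & matrix(v[E], L, L) &
        mm <= rate * len + 1e-9
      qi <- which(qual, arr.ind = TRUE)
      if (!nrow(qi)) next
      keep <- vapply(seq_len(nrow(qi)), function(k) {
        s <- qi[k, 1]
        e <- qi[k, 2]
        !any(qi[, 1] <= s & qi[, 2] >= e & (qi[, 1] != s | qi[, 2] != e))
      }, logical(1))
      qi <- qi[keep, , drop = FALSE]
      for (k in seq_len(nrow(qi))) {
        s <- qi[k, 1]
        e <- qi[k, 2]
        x0 <- (i0 - 1L) + (s - 1L)
        x1 <- (i0 - 1L) + e
        y0 <- x0 + d
        y1 <- x1 + d
        tfo <- if (orient == "parallel") c(x0, x1) else c(n - x1, n - x0)
        tts <- if (strand == "+") c(y0, y1) else c(m - y1, m - y0)
        if (pur_frac(tts[1], tts[2]) < min_purity - 1e-12) next
        nm <- mm[s, e]
        rows[[length(rows) + 1L]] <- data.frame(
          tfo_start = tfo[1], tfo_end = tfo[2], gene_id = gene,
          tts_start = tts[1], tts_end = tts[2], orientation = orient,
          strand = strand, matches = (x1 - x0) - nm, mismatches = nm,
          score = (x1 - x0) - nm - penalty * nm, stringsAsFactors = FALSE)
      }
    }
  }
  cols <- c("tfo_start", "tfo_end", "gene_id", "tts_start", "tts_end",
            "orientation", "strand", "matches", "mismatches")
  if (!length(rows)) {
    out <- data.frame(tfo_start = integer(0), tfo_end = integer(0),
                      gene_id = character(0), tts_start = integer(0),
                      tts_end = integer(0), orientation = character(0),
                      strand = character(0), matches = integer(0),
                      mismatches = integer(0))
    return(out)
  }
  out <- do.call(rbind, rows)[, cols]
  out <- out[order(out$gene_id, out$tts_start, out$tfo_start,
                   out$orientation, out$strand), ]
  rownames(out) <- NULL
  out
}

# comparable view of a triplex hit table
triplex_key <- function(df) {
  df <- df[, c("tfo_start", "tfo_end", "gene_id", "tts_start", "tts_end",
               "orientation", "strand", "matches", "mismatches")]
  df <- df[order(df$gene_id, df$tts_start, df$tfo_start, df$orientation,
                 df$strand), ]
  rownames(df) <- NULL
  df
}

# p-values of all windows by exhaustive enumeration over the 4^w words,
# re-deriving the grid scores from the probability matrix
oracle_scan_pvalues <- function(probs, background, window_units,
                                delta = 1e-3, pseudocount = 0.01) {
  w <- ncol(probs)
  p2 <- (probs + pseudocount * background) / (1 + pseudocount)
  u <- round(log2(p2 / background) / delta)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  wscore <- numeric(nrow(words))
  wprob <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    wscore[i] <- sum(u[cbind(words[i, ], seq_len(w))])
    wprob[i] <- prod(background[words[i, ]])
  }
  vapply(window_units, function(s) sum(wprob[wscore >= s]), numeric(1))
}

# one-sided hypergeometric tail for a presence 2x2 table, by direct summation
oracle_hyper_p <- function(tw, nt, bw, nb) {
  s <- tw + bw
  ks <- tw:min(nt, s)
  sum(choose(nt, ks) * choose(nb, s - ks)) / choose(nt + nb, s)
}

# planted two-set score tables for brute-force consensus comparisons
random_score_instance <- function(seed) {
  set.seed(seed)
  n1 <- sample(3:1000, 1)
  n2 <- sample(3:1000, 1)
  pool <- sprintf("P%04d", seq_len(max(n1, n2) + 50L))
  cat_ids <- sample(pool, n1)
  lnc_ids <- sample(pool, n2)
  while (!length(intersect(cat_ids, lnc_ids))) {
    lnc_ids <- sample(pool, n2)
  }
  list(catrapid = data.frame(protein_id = cat_ids,
                             interaction_score = stats::rnorm(n1),
                             discriminative_power = stats::rnorm(n1),
                             stringsAsFactors = FALSE),
       lncpro = data.frame(protein_id = lnc_ids,
                           score = stats::rnorm(n2, 30, 8),
                           stringsAsFactors = FALSE))
}

# literal restatement of the consensus rule
brute_force_consensus <- function(catrapid, lncpro) {
  common <- intersect(catrapid$protein_id, lncpro$protein_id)
  i <- match(common, catrapid$protein_id)
  j <- match(common, lncpro$protein_id)
  comb <- (catrapid$interaction_score[i] + catrapid$discriminative_power[i]) / 2
  lnc <- lncpro$score[j]
  sort(common[comb > mean(comb) & lnc > mean(lnc)])
}
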