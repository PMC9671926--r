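test_that("motif scanning scores the consensus maximally and the uniform motif at zero", {
  m <- gen_motifs(1, width = 6, peak = 0.9, prefix = "M", seed = 2)[[1]]
  consensus <- paste(c("A", "C", "G", "T")[apply(m$probs, 2, which.max)],
                     collapse = "")
  ps <- promoter_set("g", paste0("TTTTT", consensus, "TTTTT"))
  hits <- scan_motif(ps, m, alpha = 1)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$pos[which.max(fwd$logodds)], 5L)
  expect_equal(max(fwd$logodds), max(hits$logodds))

  uni <- motif_model("uni", matrix(0.25, 4, 4))
  hu <- scan_motif(promoter_set("g", "ACGTACGTACGT"), uni, alpha = 1)
  expect_true(all(hu$logodds == 0))
  expect_true(all(hu$pvalue == 1))
})

test_that("scan p-values equal exhaustive word enumeration", {
  bgs <- list(rep(0.25, 4), c(0.3, 0.2, 0.2, 0.3))
  for (w in 3:5) {
    m <- gen_motifs(1, width = w, peak = 0.8, prefix = "M", seed = w)[[1]]
    for (bg in bgs) {
      pr <- gen_promoters(1, 1, length = 120, gc = 0.5, seed = 10 + w)
      hits <- scan_motif(pr$target, m, background = bg, alpha = 1)
      for (str in c("+", "-")) {
        h <- hits[hits$strand == str, ]
        probs <- if (str == "+") m$probs else
          m$probs[4:1, rev(seq_len(w)), drop = FALSE]
        want <- oracle_scan_pvalues(probs, bg, round(h$logodds / 1e-3))
        expect_lt(max(abs(h$pvalue - want)), 1e-9)
      }
    }
  }
})

test_that("hit counts are monotone non-decreasing in alpha", {
  m <- gen_motifs(1, width = 8, peak = 0.9, prefix = "M", seed = 4)[[1]]
  pr <- gen_promoters(2, 1, length = 800, motifs = list(m), target_rate = 1,
                      seed = 6)
  counts <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2, 1), function(a) {
    nrow(scan_motif(pr$target, m, alpha = a))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("a motif wider than the promoter warns and yields nothing", {
  m <- gen_motifs(1, width = 12, peak = 0.9, prefix = "M", seed = 1)[[1]]
  expect_warning(h <- scan_motif(promoter_set("tiny", "ACGTACGT"), m),
                 "shorter than")
  expect_equal(nrow(h), 0L)
})

test_that("enrichment on identical sets is null; extreme tables match the hypergeometric", {
  et <- enrichment_test(5, 10, 5, 10)
  expect_equal(et$ratio, 1)
  expect_equal(et$pvalue, oracle_hyper_p(5, 10, 5, 10))

  # motif in all 10 targets and no background: the closed form is
  # 1 / choose(20, 10)
  et2 <- enrichment_test(10, 10, 0, 10)
  expect_equal(et2$pvalue, 1 / choose(20, 10))

  m <- gen_motifs(1, width = 8, peak = 0.95, prefix = "M", seed = 3)
  pr <- gen_promoters(6, 6, length = 300, motifs = m, target_rate = 1,
                      background_rate = 1, seed = 4)
  same <- relative_enrichment(pr$target, pr$target, m)
  expect_equal(same$enrichment_ratio, 1)
  expect_false(same$significant)
  expect_gte(same$pvalue, 0.5)
})

test_that("Fisher p equals the direct hypergeometric sum on random tables", {
  set.seed(17)
  for (i in 1:100) {
    nt <- sample(1:60, 1)
    nb <- sample(1:60, 1)
    tw <- sample(0:nt, 1)
    bw <- sample(0:nb, 1)
    et <- enrichment_test(tw, nt, bw, nb)
    expect_equal(et$pvalue, oracle_hyper_p(tw, nt, bw, nb), tolerance = 1e-9)
  }
  expect_error(enrichment_test(5, 4, 0, 10), "exceed")
})

test_that("enrichment verdicts ignore promoter and motif file order", {
  ms <- gen_motifs(2, width = 9, peak = 0.9, prefix = "M", seed = 31)
  pr <- gen_promoters(8, 12, length = 400, motifs = ms,
                      target_rate = c(1, 0.1), background_rate = 0.1,
                      seed = 32)
  r1 <- relative_enrichment(pr$target, pr$background, ms)
  shuffle <- function(ps, idx) {
    out <- ps[idx, ]
    class(out) <- class(ps)
    out
  }
  r2 <- relative_enrichment(shuffle(pr$target, sample(8)),
                            shuffle(pr$background, sample(12)),
                            rev(ms))
  expect_equal(r1[order(r1$motif_id), ]$pvalue,
               r2[order(r2$motif_id), ]$pvalue)
  expect_equal(r1[order(r1$motif_id), ]$significant,
               r2[order(r2$motif_id), ]$significant)
})

test_that("motif similarity is reflexive and detects reverse complements", {
  m <- gen_motifs(1, width = 8, peak = 0.85, prefix = "M", seed = 12)[[1]]
  self <- motif_similarity(m, m, n_perm = 50)
  expect_equal(self$r, 1)
  expect_equal(self$best_offset, 0L)
  expect_equal(self$orientation, "forward")

  rc <- motif_similarity(m, motif_rc(m), n_perm = 50)
  expect_equal(rc$r, 1)
  expect_equal(rc$orientation, "reverse_complement")
})

test_that("the permutation p-value agrees with the exhaustive permutation null", {
  m1 <- gen_motifs(1, width = 4, peak = 0.9, prefix = "A", seed = 41)[[1]]
  m2 <- gen_motifs(1, width = 4, peak = 0.7, prefix = "B", seed = 42)[[1]]
  sim <- motif_similarity(m1, m2, n_perm = 2000, seed = 9)

  # exhaustive null: all 24 column permutations of m2
  allp <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- t(allp[apply(allp, 1, function(p) length(unique(p)) == 4), ])
  align_r <- function(p1, p2) {
    best <- -Inf
    for (p2v in list(p2, p2[4:1, 4:1])) {
      r <- stats::cor(as.vector(p1), as.vector(p2v))
      best <- max(best, r)
    }
    best
  }
  null_r <- apply(perms, 2, function(p) {
    align_r(m1$probs, m2$probs[, p])
  })
  exact_p <- mean(null_r >= sim$r - 1e-12)
  mc_err <- 3 * sqrt(exact_p * (1 - exact_p) / 2000) + 2 / 2000
  expect_lt(abs(sim$pvalue - exact_p), mc_err + 0.02)
})

test_that("TFBS enrichment flags planted sites and stays quiet on identical sets", {
  lib <- gen_motifs(2, width = 10, peak = 0.95, prefix = "TFM", seed = 61)
  map <- data.frame(motif_id = c("TFM-1", "TFM-2"),
                    tf_name = c("STAT1;STAT2", "GATA1"))
  pr <- gen_promoters(10, 15, length = 600, motifs = lib,
                      target_rate = c(1, 0), background_rate = c(0, 0),
                      seed = 62)
  res <- tfbs_enrichment(pr$target, pr$background, lib, map)
  r1 <- res[res$motif_id == "TFM-1", ]
  expect_true(r1$significant)
  expect_gt(r1$z, 0)
  expect_gt(r1$mean_best_target, r1$mean_best_background)
  expect_equal(r1$tf_names, "STAT1;STAT2")
  expect_false(res$significant[res$motif_id == "TFM-2"])

  same <- tfbs_enrichment(pr$target, pr$target, lib, map)
  expect_false(any(same$significant))
})

test_that("the TFBS Welch statistic matches its closed form on a 3-vs-3 table", {
  m <- gen_motifs(1, width = 4, peak = 0.8, prefix = "W", seed = 71)[[1]]
  map <- data.frame(motif_id = "W-1", tf_name = "TF")
  tg <- promoter_set(paste0("t", 1:3), c("AACGTA", "CGCGCG", "TTATAA"))
  bg <- promoter_set(paste0("b", 1:3), c("GTGTGT", "CCAACC", "AGGTCA"))
  res <- tfbs_enrichment(tg, bg, list(m), map, background_freqs = rep(0.25, 4))

  # best score per promoter recomputed through the hit-level scanner
  best <- function(ps) vapply(seq_len(nrow(ps)), function(i) {
    h <- scan_motif(ps[i, , drop = FALSE], m, background = rep(0.25, 4),
                    alpha = 1)
    max(h$logodds)
  }, numeric(1))
  x <- best(tg)
  y <- best(bg)
  vx <- stats::var(x) / 3
  vy <- stats::var(y) / 3
  tw <- (mean(x) - mean(y)) / sqrt(vx + vy)
  dfw <- (vx + vy)^2 / (vx^2 / 2 + vy^2 / 2)
  expect_equal(res$z, tw, tolerance = 1e-12)
  expect_equal(res$pvalue, 1 - stats::pt(tw, dfw), tolerance = 1e-12)
})
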