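test_that("combined catRAPID score is the symmetric mean", {
  expect_equal(combine_catrapid(1, 0), 0.5)
  expect_equal(combine_catrapid(0.8, 0.6), 0.7)
  set.seed(3)
  a <- stats::rnorm(200)
  b <- stats::rnorm(200)
  expect_equal(combine_catrapid(a, b), combine_catrapid(b, a))
})

test_that("consensus selection implements the strict two-mean rule", {
  # identical scores: nothing strictly above the mean
  cat_tab <- data.frame(protein_id = paste0("P", 1:4),
                        interaction_score = rep(0.5, 4),
                        discriminative_power = rep(0.5, 4))
  lnc_tab <- data.frame(protein_id = paste0("P", 1:4), score = rep(30, 4))
  sel <- select_consensus(cat_tab, lnc_tab)
  expect_equal(sum(sel$predictions$selected), 0L)
  # ... unless ties are allowed
  expect_equal(sum(select_consensus(cat_tab, lnc_tab,
                                    strict = FALSE)$predictions$selected), 4L)

  cat3 <- data.frame(protein_id = c("A", "B", "C"),
                     interaction_score = c(0.9, 0.1, 0.2),
                     discriminative_power = c(0.9, 0.1, 0.2))
  lnc3 <- data.frame(protein_id = c("A", "B", "C"), score = c(50, 10, 20))
  s3 <- select_consensus(cat3, lnc3)
  expect_equal(s3$predictions$protein_id[s3$predictions$selected], "A")
  expect_equal(unname(s3$thresholds),
               c(mean(c(0.9, 0.1, 0.2)), mean(c(50, 10, 20))))

  # row order invariance
  perm <- c(3, 1, 2)
  s3b <- select_consensus(cat3[perm, ], lnc3[rev(perm), ])
  expect_setequal(s3b$predictions$protein_id[s3b$predictions$selected], "A")

  # only common proteins are candidates; empty intersection errors
  lnc_disjoint <- data.frame(protein_id = c("X", "Y"), score = c(1, 2))
  expect_error(select_consensus(cat3, lnc_disjoint), "common")
})

test_that("consensus selection equals the brute-force filter on random instances", {
  for (s in 1:25) {
    inst <- random_score_instance(1000 + s)
    sel <- select_consensus(inst$catrapid, inst$lncpro)
    got <- sort(sel$predictions$protein_id[sel$predictions$selected])
    expect_identical(got, brute_force_consensus(inst$catrapid, inst$lncpro))
  }
})

test_that("raising either consensus threshold never grows the selection", {
  inst <- random_score_instance(77)
  sel <- select_consensus(inst$catrapid, inst$lncpro)
  p <- sel$predictions
  base <- p$protein_id[p$selected]
  for (bump in c(0.05, 0.2, 1)) {
    tighter <- p$protein_id[p$catrapid_combined > sel$thresholds[1] + bump &
                              p$lncpro_score > sel$thresholds[2]]
    expect_true(all(tighter %in% base))
    tighter2 <- p$protein_id[p$catrapid_combined > sel$thresholds[1] &
                               p$lncpro_score > sel$thresholds[2] + bump]
    expect_true(all(tighter2 %in% base))
  }
})

test_that("candidate classification reports counts with their denominators", {
  ann <- data.frame(
    protein_id = paste0("P", 1:5),
    family = "f",
    functional_class = c("transcriptional", "transcriptional",
                         "post_transcriptional", "post_transcriptional",
                         "other"),
    is_tf = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  cls <- classify_candidates(paste0("P", 1:5), ann)
  expect_equal(cls$n_classified, 4L)      # "other" excluded
  expect_equal(cls$pct_transcriptional, 50)
  expect_equal(cls$pct_post_transcriptional, 50)
  expect_equal(cls$pct_tf_of_transcriptional, 50)

  expect_warning(zero <- classify_candidates("missing", ann), "denominator 0")
  expect_equal(zero$n_classified, 0L)
  expect_equal(zero$pct_transcriptional, 0)

  # planted 60/40 split is reproduced exactly
  ann2 <- data.frame(protein_id = paste0("Q", 1:10), family = "f",
                     functional_class = rep(c("transcriptional",
                                              "post_transcriptional"),
                                            c(6, 4)),
                     is_tf = rep(c(TRUE, FALSE), c(3, 7)))
  cls2 <- classify_candidates(paste0("Q", 1:10), ann2)
  expect_equal(cls2$pct_transcriptional, 60)
  expect_equal(cls2$pct_post_transcriptional, 40)
  expect_equal(cls2$pct_tf_of_transcriptional, 50)
})

test_that("binding-element calling segments profiles like a direct state machine", {
  expect_equal(nrow(call_binding_elements(rep(0, 600), threshold = 0.5)), 0L)

  prof <- rep(0, 600)
  prof[301:480] <- 1  # 0-based [300, 480)
  el <- call_binding_elements(prof, threshold = 0.5, min_length = 50,
                              merge_gap = 10)
  expect_equal(el$start, 300L)
  expect_equal(el$end, 480L)
  expect_equal(el$label, "PBE-1")

  # two blocks with a sub-merge_gap valley merge into one element
  prof2 <- rep(0, 600)
  prof2[101:160] <- 0.9
  prof2[166:240] <- 0.7  # gap of 5 < merge_gap 10
  el2 <- call_binding_elements(prof2, threshold = 0.5, min_length = 50,
                               merge_gap = 10)
  expect_equal(nrow(el2), 1L)
  expect_equal(c(el2$start, el2$end), c(100L, 240L))

  # independent state-machine oracle on random profiles
  oracle_elements <- function(p, thr, min_len, gap) {
    runs <- list()
    i <- 1
    while (i <= length(p)) {
      if (p[i] >= thr) {
        j <- i
        while (j < length(p) && p[j + 1] >= thr) j <- j + 1
        runs[[length(runs) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    if (!length(runs)) return(NULL)
    merged <- list(runs[[1]])
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      if (r[1] - last[2] - 1 < gap) {
        merged[[length(merged)]] <- c(last[1], r[2])
      } else merged[[length(merged) + 1]] <- r
    }
    keep <- Filter(function(r) r[2] - r[1] + 1 >= min_len, merged)
    if (!length(keep)) return(NULL)
    do.call(rbind, keep)
  }
  set.seed(21)
  for (i in 1:50) {
    p <- stats::rnorm(400, 0.35, 0.3)
    got <- call_binding_elements(p, threshold = 0.5, min_length = 8,
                                 merge_gap = 4)
    want <- oracle_elements(p, 0.5, 8, 4)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, want[, 1] - 1L)
      expect_equal(got$end, want[, 2])
    }
    # elements are sorted and non-overlapping
    if (nrow(got) > 1L) {
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    }
  }
})

test_that("binding elements are labeled by descending mean score", {
  prof <- rep(0, 500)
  prof[101:200] <- 0.6
  prof[301:400] <- 0.9
  el <- call_binding_elements(prof, 0.5, min_length = 50, merge_gap = 10)
  expect_equal(el$label[el$start == 300], "PBE-1")
  expect_equal(el$label[el$start == 100], "PBE-2")
})
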