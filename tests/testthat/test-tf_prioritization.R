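test_that("evidence scoring reproduces the rule table over all eight flag cases", {
  grid <- expand.grid(pred = c(FALSE, TRUE), lit = c(FALSE, TRUE),
                      enc = c(FALSE, TRUE))
  got <- evidence_score(grid$pred, grid$lit, grid$enc)
  want <- ifelse(grid$lit & grid$enc, 10L,
                 ifelse(grid$enc, 8L, ifelse(grid$lit, 6L,
                                             ifelse(grid$pred, 2L, 0L))))
  expect_identical(got, want)
  # the five published constants, spot-checked
  expect_identical(evidence_score(FALSE, TRUE, TRUE), 10L)
  expect_identical(evidence_score(FALSE, FALSE, TRUE), 8L)
  expect_identical(evidence_score(FALSE, TRUE, FALSE), 6L)
  expect_identical(evidence_score(TRUE, FALSE, FALSE), 2L)
  expect_identical(evidence_score(FALSE, FALSE, FALSE), 0L)
  # predicted sites never upgrade ChIP-backed categories
  expect_identical(evidence_score(TRUE, FALSE, TRUE), 8L)
  expect_identical(evidence_score(TRUE, TRUE, FALSE), 6L)
})

test_that("the score matrix is dense, ordered and conflict-checked", {
  empty <- build_score_matrix(
    data.frame(tf = character(0), gene = character(0),
               lit_predicted_tfbs = logical(0), lit_chip = logical(0),
               encode_chip = logical(0)),
    tfs = c("A", "B"), genes = c("g1", "g2"))
  expect_true(all(empty == 0L))
  expect_equal(dim(empty), c(2L, 2L))

  one <- build_score_matrix(
    data.frame(tf = "A", gene = "g1", lit_predicted_tfbs = FALSE,
               lit_chip = FALSE, encode_chip = TRUE),
    tfs = c("A", "B"), genes = c("g1", "g2"))
  expect_equal(one["A", "g1"], 8L)
  expect_equal(sum(one), 8L)

  dup_ok <- data.frame(tf = c("A", "A"), gene = c("g1", "g1"),
                       lit_predicted_tfbs = FALSE, lit_chip = TRUE,
                       encode_chip = TRUE)
  expect_equal(build_score_matrix(dup_ok)["A", "g1"], 10L)

  conflict <- dup_ok
  conflict$encode_chip <- c(TRUE, FALSE)
  expect_error(build_score_matrix(conflict), "conflicting.*'A'.*'g1'")

  # entries always lie in the score alphabet over random record sets
  set.seed(100)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    rec <- data.frame(
      tf = sample(paste0("T", 1:12), n, TRUE),
      gene = sample(paste0("g", 1:6), n, TRUE),
      lit_predicted_tfbs = sample(c(TRUE, FALSE), n, TRUE),
      lit_chip = sample(c(TRUE, FALSE), n, TRUE),
      encode_chip = sample(c(TRUE, FALSE), n, TRUE))
    rec <- rec[!duplicated(rec[, c("tf", "gene")]), ]
    m <- build_score_matrix(rec)
    expect_true(all(m %in% c(0L, 2L, 6L, 8L, 10L)))
  }
})

test_that("clustering recovers planted blocks and respects input-order determinism", {
  m0 <- matrix(5, nrow = 4, ncol = 3,
               dimnames = list(paste0("T", 1:4), paste0("g", 1:3)))
  expect_equal(unname(cluster_tfs(m0, k = 1)), rep(1L, 4))
  expect_error(cluster_tfs(m0, k = 9), "between 1 and")

  set.seed(5)
  block <- matrix(10L, 20, 8) + matrix(sample(0:1, 160, TRUE), 20, 8)
  rest <- matrix(sample(0:1, 240, TRUE), 30, 8)
  m <- rbind(block, rest)
  rownames(m) <- paste0("T", 1:50)
  colnames(m) <- paste0("g", 1:8)
  cl <- cluster_tfs(m, k = 2)
  expect_equal(length(unique(cl[1:20])), 1L)
  expect_equal(length(unique(cl[21:50])), 1L)
  expect_true(cl[1] != cl[21])

  # permutation of rows changes labels at most, not the partition
  perm <- sample(50)
  cl2 <- cluster_tfs(m[perm, ], k = 2)[rownames(m)]
  tab <- table(cl, cl2)
  expect_equal(sum(tab > 0), 2L)
})

test_that("high-coverage cluster selection matches a brute-force count", {
  m <- rbind(matrix(10L, 3, 10), matrix(0L, 3, 10))
  rownames(m) <- paste0("T", 1:6)
  colnames(m) <- paste0("g", 1:10)
  asg <- c(1L, 1L, 1L, 2L, 2L, 2L)
  sel <- select_high_coverage_cluster(m, asg)
  expect_equal(sel$cluster_id, 1L)
  expect_equal(sel$coverage, 1)
  expect_setequal(sel$tfs, paste0("T", 1:3))

  # 80% vs 30% coverage, brute-force comparison
  m2 <- matrix(0L, 6, 10, dimnames = list(paste0("T", 1:6), paste0("g", 1:10)))
  m2[1:3, 1:8] <- 6L
  m2[4:6, 1:3] <- 10L
  sel2 <- select_high_coverage_cluster(m2, asg)
  cov_brute <- vapply(1:2, function(cl) {
    sub <- m2[asg == cl, , drop = FALSE]
    sum(colSums(sub) > 0) / ncol(sub)
  }, numeric(1))
  expect_equal(sel2$cluster_id, which.max(cov_brute))
  expect_equal(sel2$coverage, max(cov_brute))

  # invariant to relabeling
  sel3 <- select_high_coverage_cluster(m2, c(2L, 2L, 2L, 7L, 7L, 7L))
  expect_setequal(sel3$tfs, sel2$tfs)

  # below the majority threshold a warning is emitted
  m3 <- matrix(0L, 4, 10, dimnames = list(paste0("T", 1:4), paste0("g", 1:10)))
  m3[1:2, 1:2] <- 8L
  expect_warning(select_high_coverage_cluster(m3, c(1L, 1L, 2L, 2L)),
                 "covers only")
})

test_that("candidate intersection normalizes names and requires significance", {
  rows <- data.frame(
    motif_id = c("m1", "m2", "m3"),
    tf_names = c("STAT1; stat2", "IRF1", "MYC"),
    significant = c(TRUE, TRUE, FALSE))
  cand <- intersect_candidates(c(" stat1", "MYC", "SP1"), rows)
  expect_equal(cand$final_tfs, "STAT1")           # MYC row not significant
  expect_setequal(cand$enriched_tfbs_tfs, c("STAT1", "STAT2", "IRF1"))

  expect_equal(intersect_candidates(c("A", "B"),
                                    data.frame(tf_names = "C",
                                               significant = TRUE))$final_tfs,
               character(0))
  same <- intersect_candidates(c("A", "B"),
                               data.frame(tf_names = c("A;B"),
                                          significant = TRUE))
  expect_equal(same$final_tfs, c("A", "B"))
})

test_that("prioritization output ignores evidence record order", {
  ev <- gen_evidence_matrix(n_tf = 40, n_gene = 8, n_block = 10,
                            seed = 55)
  m1 <- build_score_matrix(ev$records, tfs = ev$tfs, genes = ev$genes)
  shuf <- ev$records[sample(nrow(ev$records)), ]
  m2 <- build_score_matrix(shuf, tfs = ev$tfs, genes = ev$genes)
  expect_identical(m1, m2)
  a1 <- cluster_tfs(m1, k = 2)
  s1 <- select_high_coverage_cluster(m1, a1)
  s2 <- select_high_coverage_cluster(m2, cluster_tfs(m2, k = 2))
  expect_setequal(s1$tfs, s2$tfs)
})
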