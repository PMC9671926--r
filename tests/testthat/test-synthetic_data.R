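test_that("generators are pure functions of their seed", {
  expect_identical(gen_promoters(3, 3, length = 300, seed = 7),
                   gen_promoters(3, 3, length = 300, seed = 7))
  expect_identical(gen_interaction_scores(n = 100, n_true = 10, seed = 3),
                   gen_interaction_scores(n = 100, n_true = 10, seed = 3))
  expect_identical(gen_evidence_matrix(n_tf = 30, n_gene = 6, n_block = 8,
                                       seed = 4),
                   gen_evidence_matrix(n_tf = 30, n_gene = 6, n_block = 8,
                                       seed = 4))
  expect_identical(gen_qpcr(seed = 5), gen_qpcr(seed = 5))
  expect_identical(gen_rip(seed = 6), gen_rip(seed = 6))
  expect_identical(gen_triplex_case(seed = 8), gen_triplex_case(seed = 8))
  # different seeds give different data
  expect_false(identical(gen_qpcr(seed = 5), gen_qpcr(seed = 6)))
})

test_that("emitted FASTA files are byte-identical across same-seed runs", {
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(gen_promoters(4, 2, length = 250, seed = 9)$target, f1)
  write_fasta(gen_promoters(4, 2, length = 250, seed = 9)$target, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated promoters match the requested GC content", {
  pr <- gen_promoters(100, 1, length = 1000, gc = 0.45, seed = 14)
  gc <- mean(vapply(pr$target$sequence, function(s) {
    x <- strsplit(s, "")[[1]]
    mean(x %in% c("G", "C"))
  }, numeric(1)))
  expect_lt(abs(gc - 0.45), 0.02)
})

test_that("planting rates 1 and 0 are honored exactly, at recorded positions", {
  ms <- gen_motifs(2, width = 8, peak = 0.9, seed = 15)
  pr <- gen_promoters(6, 6, length = 400, motifs = ms,
                      target_rate = 1, background_rate = 0, seed = 16)
  plants <- pr$truth$planted_target
  expect_equal(nrow(plants), 12L)  # every target gets both motifs
  expect_equal(nrow(pr$truth$planted_background), 0L)
  for (i in seq_len(nrow(plants))) {
    s <- pr$target$sequence[pr$target$gene_id == plants$gene_id[i]]
    w <- nchar(plants$instance[i])
    expect_identical(substr(s, plants$start[i] + 1, plants$start[i] + w),
                     plants$instance[i])
  }
})

test_that("null effect sizes give chance-level consensus selection", {
  recalls <- vapply(1:30, function(s) {
    g <- gen_interaction_scores(n = 400, n_true = 40, catrapid_shift = 0,
                                lncpro_shift = 0, seed = 700 + s)
    sel <- select_consensus(g$catrapid, g$lncpro)
    picked <- sel$predictions$protein_id[sel$predictions$selected]
    mean(g$truth$planted_binders %in% picked)
  }, numeric(1))
  # under independence a protein is above both means with p ~ 0.25
  expect_lt(abs(mean(recalls) - 0.25), 0.05)
})

test_that("zero-noise qPCR and RIP generators hit their closed forms", {
  q <- gen_qpcr(knockdown = c(G = 0.5), replicate_sd = 0, donor_sd = 0,
                seed = 21)
  res <- analyze_knockdown(q$ct_table)
  expect_equal(res$summary$mean_pct_change, -50, tolerance = 1e-9)

  r <- gen_rip(folds = c(AB = 8), noise_sd = 0, seed = 22)
  out <- analyze_rip(r$rip_table)
  expect_equal(out$fold_over_igg[out$antibody == "AB"], 8, tolerance = 1e-9)
})

test_that("fractionation generator plants recoverable shares", {
  fr <- gen_fractionation(noise_sd = 0, seed = 23)
  q <- quantify_fractions(stats::setNames(fr$ct_table$ct,
                                          fr$ct_table$fraction))
  pct <- fraction_percentages(q)
  expect_equal(pct$percent_of_total / 100,
               unname(fr$truth$shares[pct$fraction]), tolerance = 1e-9)
})

test_that("evidence generator plants a recoverable block", {
  ev <- gen_evidence_matrix(noise_rate = 0, seed = 24)
  m <- build_score_matrix(ev$records, tfs = ev$tfs, genes = ev$genes)
  cl <- cluster_tfs(m, k = 2)
  in_block <- ev$tfs %in% ev$truth$block_tfs
  expect_equal(length(unique(cl[in_block])), 1L)
  expect_equal(length(unique(cl[!in_block])), 1L)
  expect_true(cl[in_block][1] != cl[!in_block][1])

  # all rates zero: no records at all
  ev0 <- gen_evidence_matrix(n_tf = 10, n_gene = 4, n_block = 3,
                             block_rate = 0, block_lit_rate = 0,
                             noise_rate = 0, seed = 25)
  expect_equal(nrow(ev0$records), 0L)
  m0 <- build_score_matrix(ev0$records, tfs = ev0$tfs, genes = ev0$genes)
  expect_true(all(m0 == 0L))
})

test_that("short planted tracts stay below the detection floor", {
  tc <- gen_triplex_case(tract_len = 12, seed = 26)
  hits <- find_triplex_pairs(tc$rna, tc$promoters, min_len = 20,
                             max_mismatch_rate = 0)
  tt <- tc$truth
  overlapping <- hits[hits$gene_id == tt$gene_id &
                        hits$tts_start < tt$tts_end &
                        hits$tts_end > tt$tts_start, ]
  expect_equal(nrow(overlapping), 0L)
})

test_that("the truth manifest is verifiable and tampering is caught", {
  d <- withr::local_tempdir()
  simulate_run(d, seed = 30, promoter_length = 400)
  expect_true(verify_truth_manifest(d))

  # corrupt one planted instance
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  plants <- man$planted_motifs$planted_target
  ps <- read_fasta(file.path(d, "promoters_target.fa"))
  i <- ps$gene_id == plants$gene_id[1]
  s <- ps$sequence[i]
  pos <- plants$start[1] + 1
  bad <- setdiff(c("A", "C", "G", "T"), substr(s, pos, pos))[1]
  substr(s, pos, pos) <- bad
  ps$sequence[i] <- s
  write_fasta(ps, file.path(d, "promoters_target.fa"))
  expect_error(verify_truth_manifest(d), "manifest check failed")
})
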