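# Orchestration: run configuration, the simulated-run writer with its truth
# manifest, an independent manifest checker, and the end-to-end driver that
# chains expression, consensus, triplex, motif-enrichment, TFBS-enrichment
# and TF-prioritization stages.

.CONFIG_KEYS <- c("inputs", "scan_alpha", "enrich_alpha", "consensus_mode",
                  "consensus_strict", "triplex_min_len",
                  "triplex_max_mismatch_rate", "triplex_min_purity",
                  "pbe_threshold", "pbe_min_length", "pbe_merge_gap",
                  "k_clusters", "coverage_threshold", "input_fraction",
                  "efficiency", "reference_gene", "seed", "out_dir")

.INPUT_KEYS <- c("qpcr", "fractionation", "rip", "catrapid", "lncpro",
                 "annotations", "profile", "lncrna_fasta",
                 "triplex_promoters", "target_promoters",
                 "background_promoters", "nbs_motifs", "tf_motifs",
                 "motif_to_tf", "evidence")

#' Build and validate a run configuration
#'
#' With `run_dir` set, input paths default to the file layout written by
#' [simulate_run()]. Unknown keys and out-of-range thresholds are rejected
#' before any stage runs.
#'
#' @param run_dir Optional directory produced by [simulate_run()].
#' @param inputs Named list of input paths (see [simulate_run()] for the
#'   expected keys).
#' @param out_dir Output directory for stage tables and the summary.
#' @param seed Seed forwarded to any stage needing randomness.
#' @param ... Threshold overrides: `scan_alpha`, `enrich_alpha`,
#'   `consensus_mode`, `consensus_strict`, `triplex_min_len`,
#'   `triplex_max_mismatch_rate`, `triplex_min_purity`, `pbe_threshold`,
#'   `pbe_min_length`, `pbe_merge_gap`, `k_clusters`, `coverage_threshold`,
#'   `input_fraction`, `efficiency`, `reference_gene`.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(run_dir = NULL, inputs = NULL, out_dir = tempfile("run"),
                       seed = 1L, ...) {
  cfg <- list(
    inputs = inputs,
    scan_alpha = 1e-4, enrich_alpha = 0.05,
    consensus_mode = "intersection", consensus_strict = TRUE,
    triplex_min_len = 20L, triplex_max_mismatch_rate = 0.1,
    triplex_min_purity = 0.8,
    pbe_threshold = 0.5, pbe_min_length = 50L, pbe_merge_gap = 10L,
    k_clusters = 4L, coverage_threshold = 0.5,
    input_fraction = 0.1, efficiency = 2, reference_gene = "ACTB",
    seed = as.integer(seed), out_dir = out_dir)
  extra <- list(...)
  unknown <- setdiff(names(extra), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(extra)] <- extra
  if (!is.null(run_dir)) {
    files <- c(qpcr = "qpcr_knockdown.tsv", fractionation = "fractionation.tsv",
               rip = "rip.tsv", catrapid = "catrapid.tsv",
               lncpro = "lncpro.tsv", annotations = "annotations.tsv",
               profile = "profile.tsv", lncrna_fasta = "lncrna.fa",
               triplex_promoters = "triplex_promoters.fa",
               target_promoters = "promoters_target.fa",
               background_promoters = "promoters_background.fa",
               nbs_motifs = "motifs_nbs.meme", tf_motifs = "motifs_tf.meme",
               motif_to_tf = "motif_to_tf.tsv", evidence = "evidence.tsv")
    cfg$inputs <- as.list(stats::setNames(file.path(run_dir, files),
                                          names(files)))
  }
  if (is.null(cfg$inputs)) stop("no inputs configured", call. = FALSE)
  unknown_in <- setdiff(names(cfg$inputs), .INPUT_KEYS)
  if (length(unknown_in)) {
    stop("unknown input key(s): ", paste(unknown_in, collapse = ", "),
         call. = FALSE)
  }
  for (a in c("scan_alpha", "enrich_alpha")) {
    if (cfg[[a]] <= 0 || cfg[[a]] > 1) {
      stop(a, " must lie in (0, 1]", call. = FALSE)
    }
  }
  if (!cfg$consensus_mode %in% c("intersection", "union")) {
    stop("consensus_mode must be 'intersection' or 'union'", call. = FALSE)
  }
  if (cfg$k_clusters < 1L) stop("k_clusters must be >= 1", call. = FALSE)
  if (cfg$coverage_threshold < 0 || cfg$coverage_threshold > 1) {
    stop("coverage_threshold must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with any subset of [run_config()] keys.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c(.CONFIG_KEYS)
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- y[setdiff(names(y), c("inputs", "out_dir", "seed"))]
  do.call(run_config, c(list(inputs = y$inputs,
                             out_dir = y$out_dir %||% tempfile("run"),
                             seed = y$seed %||% 1L), args))
}

# stable hash of the configuration (out_dir excluded so reruns into a
# different directory stay byte-identical)
config_hash <- function(cfg) {
  core <- unclass(cfg)
  core$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(core[order(names(core))]), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a self-contained simulated run directory
#'
#' Generates every input the pipeline consumes, with planted ground truth,
#' into `dir`: promoter FASTA sets with planted motifs, an lncRNA and
#' triplex promoter pair, predictor score tables, annotations, an evidence
#' table whose high-evidence block contains the planted partner TFs, a PWM
#' library in which exactly the partner TFs' motifs are planted in target
#' promoters, qPCR / fractionation / RIP Ct tables, a binding profile, and
#' `manifest.json` recording the planted truth.
#'
#' @param dir Output directory (created).
#' @param seed Master seed; every generator receives a sub-seed derived
#'   from it.
#' @param n_target,n_background,promoter_length Promoter set geometry.
#' @param partner_tfs Planted partner TFs: members of the evidence block
#'   whose motifs are planted in (only) the target promoters.
#' @param decoy_tfs TFs outside the block whose motifs are present in the
#'   library but planted nowhere.
#' @param n_block Evidence block size.
#' @param knockdown Named per-gene knockdown fractions for the qPCR table.
#' @return Invisibly, the truth manifest (also written as JSON).
#' @export
simulate_run <- function(dir, seed,
                         n_target = 15L, n_background = 41L,
                         promoter_length = 5000L,
                         partner_tfs = c("STAT1", "STAT2", "IRF1", "SP1",
                                         "MYC", "MAX", "TBP", "YY1"),
                         decoy_tfs = c("GATA1", "CEBPA", "FOXO3", "NR3C1"),
                         n_block = 34L,
                         knockdown = c(CXCL10 = 0.67, DDX58 = 0.40,
                                       MX1 = 0.42, CXCL11 = 0.66,
                                       EPSTI1 = 0.38, IFIT2 = 0.57,
                                       IFI44 = 0.46)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  # motifs: NBS set for relative enrichment (2 planted, 3 neutral) and the
  # TF PWM library (partner motifs planted in targets only, decoys nowhere)
  nbs <- gen_motifs(5L, width = 10L, peak = 0.95, prefix = "NBS",
                    seed = child_seed(seed, 1L))
  tf_motifs <- gen_motifs(length(partner_tfs) + length(decoy_tfs),
                          width = 10L, peak = 0.95, prefix = "TFM",
                          seed = child_seed(seed, 2L))
  names(tf_motifs) <- vapply(tf_motifs, `[[`, character(1), "motif_id")
  motif_to_tf <- data.frame(
    motif_id = vapply(tf_motifs, `[[`, character(1), "motif_id"),
    tf_name = c(partner_tfs, decoy_tfs),
    stringsAsFactors = FALSE)

  all_motifs <- c(nbs, tf_motifs)
  target_rates <- c(0.9, 0.9, 0.1, 0.1, 0.1,
                    rep(1.0, length(partner_tfs)),
                    rep(0.0, length(decoy_tfs)))
  background_rates <- c(0.1, 0.1, 0.1, 0.1, 0.1,
                        rep(0.0, length(partner_tfs)),
                        rep(0.0, length(decoy_tfs)))
  proms <- gen_promoters(n_target, n_background, promoter_length,
                         motifs = all_motifs, target_rate = target_rates,
                         background_rate = background_rates,
                         seed = child_seed(seed, 3L))
  write_fasta(proms$target, p("promoters_target.fa"))
  write_fasta(proms$background, p("promoters_background.fa"))
  write_meme_motifs(nbs, p("motifs_nbs.meme"))
  write_meme_motifs(tf_motifs, p("motifs_tf.meme"))
  write_tsv_table(motif_to_tf, p("motif_to_tf.tsv"))

  # triplex fixture
  trip <- gen_triplex_case(seed = child_seed(seed, 4L))
  write_fasta(promoter_set("lncRNA", trip$rna), p("lncrna.fa"))
  write_fasta(trip$promoters, p("triplex_promoters.fa"))

  # predictor tables and annotations
  scores <- gen_interaction_scores(seed = child_seed(seed, 5L))
  write_tsv_table(scores$catrapid, p("catrapid.tsv"))
  write_tsv_table(scores$lncpro, p("lncpro.tsv"))
  ann <- gen_annotations(scores$catrapid$protein_id,
                         seed = child_seed(seed, 6L))
  write_tsv_table(ann, p("annotations.tsv"))

  # evidence table: block = partners + generic TFs; decoys stay outside
  n_tf <- 158L
  generic <- sprintf("TF%03d", seq_len(n_tf))
  tf_names <- c(partner_tfs, generic[seq_len(n_block - length(partner_tfs))],
                decoy_tfs,
                generic[seq.int(n_block - length(partner_tfs) + 1L,
                                n_tf - length(partner_tfs) -
                                  length(decoy_tfs))])
  ev <- gen_evidence_matrix(n_tf = n_tf, n_gene = 15L, n_block = n_block,
                            tf_names = tf_names,
                            gene_names = sprintf("G%02d", 1:15),
                            seed = child_seed(seed, 7L))
  write_tsv_table(ev$records, p("evidence.tsv"))

  # qPCR, fractionation, RIP, binding profile
  qp <- gen_qpcr(knockdown = knockdown, seed = child_seed(seed, 8L))
  write_tsv_table(qp$ct_table, p("qpcr_knockdown.tsv"))
  fr <- gen_fractionation(seed = child_seed(seed, 9L))
  write_tsv_table(fr$ct_table, p("fractionation.tsv"))
  rip <- gen_rip(seed = child_seed(seed, 10L))
  write_tsv_table(rip$rip_table, p("rip.tsv"))
  prof <- gen_binding_profile(seed = child_seed(seed, 11L))
  write_tsv_table(prof$profile, p("profile.tsv"))

  manifest <- list(
    seed = seed,
    planted_motifs = list(
      motif_ids = names(all_motifs),
      target_rate = target_rates, background_rate = background_rates,
      planted_target = proms$truth$planted_target,
      planted_background = proms$truth$planted_background),
    planted_binders = scores$truth$planted_binders,
    planted_tf_block = list(tfs = ev$truth$block_tfs,
                            genes = ev$truth$block_genes),
    planted_partner_tfs = sort(partner_tfs),
    planted_effects = as.list(qp$truth$knockdown),
    planted_fractionation = as.list(fr$truth$shares),
    planted_rip_folds = as.list(rip$truth$folds),
    planted_triplex = trip$truth,
    planted_profile_elements = prof$truth$elements)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Verify a truth manifest against the emitted files
#'
#' Independent checker: re-reads the files of a [simulate_run()] directory
#' and verifies that every planted item is really present (motif instances
#' at their recorded positions, planted binders in both score tables, block
#' TFs in the evidence table, the triplex tract at its coordinates).
#'
#' @param dir A [simulate_run()] directory.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
verify_truth_manifest <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  fail <- function(...) stop("manifest check failed: ", sprintf(...),
                             call. = FALSE)
  check_plants <- function(fasta, plants) {
    ps <- read_fasta(fasta)
    if (!NROW(plants)) return(invisible())
    for (i in seq_len(nrow(plants))) {
      s <- ps$sequence[ps$gene_id == plants$gene_id[i]]
      w <- nchar(plants$instance[i])
      got <- substr(s, plants$start[i] + 1L, plants$start[i] + w)
      if (!identical(got, plants$instance[i])) {
        fail("motif %s not found at %s:%d", plants$motif_id[i],
             plants$gene_id[i], plants$start[i])
      }
    }
  }
  check_plants(file.path(dir, "promoters_target.fa"),
               man$planted_motifs$planted_target)
  check_plants(file.path(dir, "promoters_background.fa"),
               man$planted_motifs$planted_background)

  cat_tab <- read_tsv_table(file.path(dir, "catrapid.tsv"))
  lnc_tab <- read_tsv_table(file.path(dir, "lncpro.tsv"))
  if (!all(man$planted_binders %in% cat_tab$protein_id) ||
      !all(man$planted_binders %in% lnc_tab$protein_id)) {
    fail("planted binders missing from predictor tables")
  }

  ev <- read_tsv_table(file.path(dir, "evidence.tsv"))
  if (!all(man$planted_tf_block$tfs %in% ev$tf)) {
    fail("planted TF block missing from evidence table")
  }

  tt <- man$planted_triplex
  proms <- read_fasta(file.path(dir, "triplex_promoters.fa"))
  tract <- substr(proms$sequence[proms$gene_id == tt$gene_id],
                  tt$tts_start + 1L, tt$tts_end)
  if (grepl("[^AG]", tract)) fail("planted tract is not polypurine")
  rna <- read_rna_sequence(file.path(dir, "lncrna.fa"))
  window <- substr(rna, tt$tfo_start + 1L, tt$tfo_end)
  if (!identical(chartr("AG", "TC", tract), window)) {
    fail("planted TFO window does not pair with the tract")
  }
  invisible(TRUE)
}

.stage_inputs <- list(
  expression = c("qpcr", "fractionation", "rip"),
  consensus = c("catrapid", "lncpro", "annotations", "profile"),
  triplex = c("lncrna_fasta", "triplex_promoters"),
  enrich = c("nbs_motifs", "target_promoters", "background_promoters"),
  tfbs_enrich = c("tf_motifs", "motif_to_tf", "target_promoters",
                  "background_promoters"),
  prioritize = c("evidence"))

#' Run the full mechanism-of-action pipeline
#'
#' Executes the stages in dependency order — expression, consensus and
#' triplex independently, then motif enrichment, TFBS enrichment and TF
#' prioritization — writing one provenance-stamped TSV per stage output and
#' a machine-readable `summary.json` (every applied threshold, the
#' per-stage headline numbers and the final candidate TF set) into
#' `config$out_dir`. Given identical configuration and seed the summary is
#' byte-identical across reruns.
#'
#' @param config A [run_config()].
#' @return Invisibly, the summary list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  needed <- unique(unlist(.stage_inputs))
  for (key in needed) {
    path <- config$inputs[[key]]
    if (is.null(path)) {
      stop("missing input '", key, "' required by stage '",
           names(.stage_inputs)[vapply(.stage_inputs, function(x)
             key %in% x, logical(1))][1L], "'", call. = FALSE)
    }
    if (!file.exists(path)) {
      stop("input '", key, "' not found: ", path, call. = FALSE)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  prov <- list(package = paste0("lncmoa ",
                                as.character(utils::packageVersion("lncmoa"))),
               config_hash = hash, seed = config$seed)
  logfile <- file.path(config$out_dir, "run.log")
  note <- function(...) {
    msg <- sprintf(...)
    message("[lncmoa] ", msg)
    cat(msg, "\n", file = logfile, append = TRUE)
  }
  out <- function(df, name) {
    write_tsv_table(df, file.path(config$out_dir, name), provenance = prov)
  }

  ## expression
  note("expression: knockdown, fractionation, RIP")
  qp <- read_tsv_table(config$inputs$qpcr,
                       c(donor = "character", treatment = "character",
                         silencing = "character", gene = "character",
                         ct = "double"))
  kd <- analyze_knockdown(qp, reference_gene = config$reference_gene,
                          e_target = config$efficiency,
                          e_ref = config$efficiency)
  out(kd$summary, "expression_knockdown.tsv")
  fr <- read_tsv_table(config$inputs$fractionation,
                       c(gene = "character", fraction = "character",
                         ct = "double"))
  fr_q <- quantify_fractions(stats::setNames(fr$ct, fr$fraction),
                             config$efficiency)
  fr_pct <- fraction_percentages(fr_q)
  out(fr_pct, "fractionation_percent.tsv")
  rip <- read_tsv_table(config$inputs$rip,
                        c(antibody = "character", gene = "character",
                          ct_ip = "double", ct_input = "double",
                          input_fraction = "double"))
  rip_res <- analyze_rip(rip)
  out(rip_res, "rip_percent_input.tsv")

  ## consensus
  note("consensus: predictor intersection and binding elements")
  catrapid <- read_tsv_table(config$inputs$catrapid,
                             c(protein_id = "character",
                               interaction_score = "double",
                               discriminative_power = "double"))
  lncpro <- read_tsv_table(config$inputs$lncpro,
                           c(protein_id = "character", score = "double"))
  cons <- select_consensus(catrapid, lncpro, mode = config$consensus_mode,
                           strict = config$consensus_strict)
  out(cons$predictions, "consensus_predictions.tsv")
  ann <- read_tsv_table(config$inputs$annotations,
                        c(protein_id = "character",
                          functional_class = "character", is_tf = "logical"))
  cls <- classify_candidates(
    cons$predictions$protein_id[cons$predictions$selected], ann)
  out(cls, "consensus_classes.tsv")
  prof <- read_tsv_table(config$inputs$profile,
                         c(position = "integer", score = "double"))
  pbe <- call_binding_elements(prof, threshold = config$pbe_threshold,
                               min_length = config$pbe_min_length,
                               merge_gap = config$pbe_merge_gap)
  out(pbe, "binding_elements.tsv")

  ## triplex
  note("triplex: TFO/TTS search")
  rna <- read_rna_sequence(config$inputs$lncrna_fasta)
  tproms <- read_fasta(config$inputs$triplex_promoters)
  hits <- find_triplex_pairs(rna, tproms,
                             min_len = config$triplex_min_len,
                             max_mismatch_rate = config$triplex_max_mismatch_rate,
                             min_purity = config$triplex_min_purity)
  out(hits, "triplex_tts.tsv")
  tfos <- rank_tfos(hits)
  out(tfos, "tfo_ranking.tsv")

  ## motif enrichment
  note("enrichment: NBS relative enrichment")
  targets <- read_fasta(config$inputs$target_promoters)
  background <- read_fasta(config$inputs$background_promoters)
  nbs <- read_meme_motifs(config$inputs$nbs_motifs)
  enr <- relative_enrichment(targets, background, nbs,
                             scan_alpha = config$scan_alpha,
                             alpha = config$enrich_alpha)
  out(enr, "nbs_enrichment.tsv")

  ## TFBS enrichment
  note("TFBS enrichment")
  tf_lib <- read_meme_motifs(config$inputs$tf_motifs)
  m2t <- read_tsv_table(config$inputs$motif_to_tf,
                        c(motif_id = "character", tf_name = "character"))
  tfbs <- tfbs_enrichment(targets, background, tf_lib, m2t,
                          alpha = config$enrich_alpha)
  out(tfbs, "tfbs_enrichment.tsv")

  ## prioritization
  note("prioritization: scoring, clustering, intersection")
  ev <- read_tsv_table(config$inputs$evidence,
                       c(tf = "character", gene = "character",
                         lit_predicted_tfbs = "logical",
                         lit_chip = "logical", encode_chip = "logical"))
  scores <- build_score_matrix(ev)
  out(data.frame(tf = rownames(scores), as.data.frame(scores),
                 check.names = FALSE), "score_matrix.tsv")
  assignment <- cluster_tfs(scores, k = config$k_clusters)
  out(data.frame(tf = names(assignment), cluster = as.integer(assignment)),
      "clusters.tsv")
  sel <- select_high_coverage_cluster(scores, assignment,
                                      config$coverage_threshold)
  cand <- intersect_candidates(sel$tfs, tfbs)
  out(data.frame(tf = cand$final_tfs), "candidate_tfs.tsv")

  summary <- list(
    package = prov$package,
    config_hash = hash,
    seed = config$seed,
    thresholds = list(
      scan_alpha = config$scan_alpha, enrich_alpha = config$enrich_alpha,
      consensus_mode = config$consensus_mode,
      consensus_strict = config$consensus_strict,
      consensus_thresholds = as.list(cons$thresholds),
      triplex_min_len = config$triplex_min_len,
      triplex_max_mismatch_rate = config$triplex_max_mismatch_rate,
      triplex_min_purity = config$triplex_min_purity,
      pbe_threshold = config$pbe_threshold,
      pbe_min_length = config$pbe_min_length,
      pbe_merge_gap = config$pbe_merge_gap,
      k_clusters = config$k_clusters,
      coverage_threshold = config$coverage_threshold,
      input_fraction = config$input_fraction,
      efficiency = config$efficiency),
    expression = list(
      genes = kd$summary$gene,
      mean_pct_change = kd$summary$mean_pct_change,
      p_adj = kd$summary$p_adj,
      nuclear_percent = attr(fr_pct, "nuclear_percent"),
      chromatin_percent =
        fr_pct$percent_of_total[fr_pct$fraction == "chromatin"],
      rip_fold_over_igg = stats::setNames(
        as.list(rip_res$fold_over_igg), rip_res$antibody)),
    consensus = list(
      n_common = nrow(cons$predictions),
      n_selected = sum(cons$predictions$selected),
      pct_transcriptional = cls$pct_transcriptional,
      pct_tf_of_transcriptional = cls$pct_tf_of_transcriptional,
      binding_elements = pbe$label),
    triplex = list(
      n_hits = nrow(hits),
      tfo1 = if (nrow(tfos)) as.list(tfos[1L, ]) else NULL),
    enrichment = list(
      significant_nbs = enr$motif_id[enr$significant]),
    tfbs = list(
      significant_motifs = tfbs$motif_id[tfbs$significant]),
    prioritization = list(
      cluster_id = sel$cluster_id,
      n_cluster_tfs = length(sel$tfs),
      coverage = sel$coverage,
      enriched_tfbs_tfs = cand$enriched_tfbs_tfs,
      final_tfs = cand$final_tfs))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  note("done: %d candidate TF(s)", length(cand$final_tfs))
  invisible(summary)
}
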