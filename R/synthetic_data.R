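# Seeded generators producing every input the pipeline consumes, with
# planted ground truth. Each generator is a pure function of its parameters
# and seed: it seeds the global RNG on entry, so the same call reproduces
# identical output byte for byte.

#' Generate random motif models
#'
#' Position probability matrices with one dominant letter per column
#' (probability `peak`, remainder split evenly), a common device for
#' planting detectable but imperfect signals.
#'
#' @param n Number of motifs.
#' @param width Motif width (recycled over motifs).
#' @param peak Probability of the dominant letter per column.
#' @param prefix Motif id prefix (ids are `prefix-1`, `prefix-2`, ...).
#' @param seed RNG seed (required).
#' @return Named list of [motif_model]s.
#' @export
gen_motifs <- function(n = 5L, width = 10L, peak = 0.85, prefix = "NBS",
                       seed) {
  set.seed(seed)
  width <- rep_len(width, n)
  motifs <- list()
  for (i in seq_len(n)) {
    dom <- sample.int(4L, width[i], replace = TRUE)
    probs <- matrix((1 - peak) / 3, nrow = 4L, ncol = width[i])
    probs[cbind(dom, seq_len(width[i]))] <- peak
    id <- paste0(prefix, "-", i)
    motifs[[id]] <- motif_model(id, probs)
  }
  motifs
}

# sample one motif instance (a word) from its probability columns
.sample_instance <- function(motif) {
  paste(.BASES[vapply(seq_len(motif$width), function(j) {
    sample.int(4L, 1L, prob = motif$probs[, j])
  }, integer(1))], collapse = "")
}

#' Generate target and background promoter sets with planted motifs
#'
#' Sequences are i.i.d. with the requested GC content. Each promoter
#' independently receives, per motif, one instance sampled from the motif's
#' probability columns with its set's planting rate, at a uniform random
#' position not overlapping previously planted instances (always on the `+`
#' strand). The returned truth manifest records every planted instance.
#'
#' @param n_target,n_background Set sizes (defaults mirror a 15-target /
#'   41-background study design).
#' @param length Promoter length in nt.
#' @param gc GC content of the random background.
#' @param motifs List of [motif_model]s to plant (may be `NULL`).
#' @param target_rate,background_rate Per-motif planting probability in each
#'   set (recycled over motifs).
#' @param seed RNG seed (required).
#' @return A list with `target` and `background` ([promoter_set]s) and
#'   `truth` (planting records and parameters).
#' @export
gen_promoters <- function(n_target = 15L, n_background = 41L, length = 5000L,
                          gc = 0.45, motifs = NULL, target_rate = 0.9,
                          background_rate = 0.1, seed) {
  set.seed(seed)
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  n_motif <- length(motifs %||% list())
  target_rate <- rep_len(target_rate, max(n_motif, 1L))
  background_rate <- rep_len(background_rate, max(n_motif, 1L))

  make_set <- function(n, prefix, rates) {
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    seqs <- character(n)
    plants <- list()
    for (i in seq_len(n)) {
      s <- sample(.BASES, length, replace = TRUE, prob = base_p)
      occupied <- rep(FALSE, length)
      if (n_motif > 0L) {
        for (k in seq_len(n_motif)) {
          if (stats::runif(1) >= rates[k]) next
          m <- motifs[[k]]
          inst <- .sample_instance(m)
          w <- nchar(inst)
          free <- which(vapply(seq_len(length - w + 1L), function(p) {
            !any(occupied[p:(p + w - 1L)])
          }, logical(1)))
          if (!length(free)) next
          p <- free[sample.int(length(free), 1L)]
          s[p:(p + w - 1L)] <- strsplit(inst, "")[[1L]]
          occupied[p:(p + w - 1L)] <- TRUE
          plants[[length(plants) + 1L]] <- data.frame(
            gene_id = ids[i], motif_id = m$motif_id, start = p - 1L,
            instance = inst, stringsAsFactors = FALSE)
        }
      }
      seqs[i] <- paste(s, collapse = "")
    }
    list(set = promoter_set(ids, seqs),
         plants = if (length(plants)) do.call(rbind, plants) else
           data.frame(gene_id = character(0), motif_id = character(0),
                      start = integer(0), instance = character(0)))
  }

  tg <- make_set(n_target, "TG", target_rate)
  bg <- make_set(n_background, "BG", background_rate)
  list(target = tg$set, background = bg$set,
       truth = list(seed = seed, gc = gc, length = length,
                    target_rate = target_rate,
                    background_rate = background_rate,
                    planted_target = tg$plants,
                    planted_background = bg$plants))
}

#' Generate two predictor score tables with planted binders
#'
#' Null proteins draw their catRAPID-style interaction score and
#' discriminative power from `N(0.3, 0.15)` and their lncPRO-style score
#' from `N(30, 8)`; planted binders are shifted upward in every channel, so
#' the two predictors agree on them (the correlation the consensus rule
#' exploits).
#'
#' @param n Total number of proteins.
#' @param n_true Number of planted binders.
#' @param catrapid_shift Upward shift of both catRAPID channels for planted
#'   binders.
#' @param lncpro_shift Upward shift of the lncPRO score for planted binders.
#' @param catrapid_sd,lncpro_sd Channel noise SDs.
#' @param seed RNG seed (required).
#' @return A list with `catrapid`, `lncpro` (data.frames) and `truth`
#'   (planted protein ids).
#' @export
gen_interaction_scores <- function(n = 1000L, n_true = 50L,
                                   catrapid_shift = 0.45, lncpro_shift = 25,
                                   catrapid_sd = 0.15, lncpro_sd = 8,
                                   seed) {
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n))
  true_ids <- sort(sample(ids, n_true))
  shift <- ids %in% true_ids
  catrapid <- data.frame(
    protein_id = ids,
    interaction_score = stats::rnorm(n, 0.3, catrapid_sd) +
      catrapid_shift * shift,
    discriminative_power = stats::rnorm(n, 0.3, catrapid_sd) +
      catrapid_shift * shift,
    stringsAsFactors = FALSE)
  lncpro <- data.frame(
    protein_id = ids,
    score = stats::rnorm(n, 30, lncpro_sd) + lncpro_shift * shift,
    stringsAsFactors = FALSE)
  list(catrapid = catrapid, lncpro = lncpro,
       truth = list(seed = seed, planted_binders = true_ids))
}

#' Generate functional annotations for proteins
#'
#' Assigns each protein a functional class (`transcriptional` with
#' probability `transcriptional_frac`, otherwise `post_transcriptional`)
#' and, within the transcriptional class, flags a fraction `tf_frac` as
#' transcription factors. Defaults mirror the 63% / 87% split typical of a
#' chromatin-biased candidate list.
#'
#' @param protein_ids Character vector of proteins to annotate.
#' @param transcriptional_frac Fraction annotated as transcriptional.
#' @param tf_frac Fraction of transcriptional proteins flagged as TFs.
#' @param seed RNG seed (required).
#' @return A data.frame with `protein_id`, `family`, `functional_class`,
#'   `is_tf`.
#' @export
gen_annotations <- function(protein_ids, transcriptional_frac = 0.63,
                            tf_frac = 0.87, seed) {
  set.seed(seed)
  n <- length(protein_ids)
  tr <- stats::runif(n) < transcriptional_frac
  is_tf <- tr & (stats::runif(n) < tf_frac)
  data.frame(
    protein_id = protein_ids,
    family = ifelse(is_tf, "C2H2 zinc finger transcription factor (PC00248)",
                    ifelse(tr, "chromatin-binding regulatory protein (PC00077)",
                           "RNA metabolism protein (PC00031)")),
    functional_class = ifelse(tr, "transcriptional", "post_transcriptional"),
    is_tf = is_tf,
    stringsAsFactors = FALSE)
}

#' Generate TF evidence records with a planted high-evidence block
#'
#' A block of TFs receives ENCODE ChIP evidence on a fixed majority subset
#' of the genes (plus literature ChIP at `block_lit_rate`); all remaining
#' evidence is background noise. Background flags are restricted to a small
#' set of heavily-studied genes (`n_bias_genes`), emulating the strong
#' study bias of literature/ENCODE evidence; without that bias any large
#' sparse cluster would trivially touch every gene.
#'
#' @param n_tf,n_gene Matrix dimensions (defaults mirror a 158-TF,
#'   15-gene study).
#' @param n_block Size of the planted block (default 34).
#' @param block_gene_frac Fraction of genes the block covers.
#' @param block_rate Probability a block cell receives ENCODE evidence.
#' @param block_lit_rate Probability a covered block cell also has
#'   literature ChIP evidence.
#' @param noise_rate Per-flag background rate on the biased genes.
#' @param n_bias_genes Number of heavily-studied genes receiving background
#'   evidence.
#' @param tf_names Optional TF names; the first `n_block` are the block.
#' @param gene_names Optional gene names.
#' @param seed RNG seed (required).
#' @return A list with `records` (evidence data.frame), `tfs`, `genes`, and
#'   `truth` (block TF and gene lists).
#' @export
gen_evidence_matrix <- function(n_tf = 158L, n_gene = 15L, n_block = 34L,
                                block_gene_frac = 0.8, block_rate = 1.0,
                                block_lit_rate = 0.5, noise_rate = 0.02,
                                n_bias_genes = 5L, tf_names = NULL,
                                gene_names = NULL, seed) {
  set.seed(seed)
  tfs <- tf_names %||% sprintf("TF%03d", seq_len(n_tf))
  genes <- gene_names %||% sprintf("G%02d", seq_len(n_gene))
  stopifnot(length(tfs) == n_tf, length(genes) == n_gene, n_block <= n_tf)
  block_tfs <- tfs[seq_len(n_block)]
  block_genes <- genes[seq_len(max(1L, ceiling(block_gene_frac * n_gene)))]
  bias_genes <- genes[seq_len(min(n_bias_genes, n_gene))]

  rows <- list()
  add <- function(tf, gene, pred, lit, enc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      tf = tf, gene = gene, lit_predicted_tfbs = pred, lit_chip = lit,
      encode_chip = enc, stringsAsFactors = FALSE)
  }
  for (tf in tfs) {
    in_block <- tf %in% block_tfs
    for (gene in genes) {
      if (in_block && gene %in% block_genes) {
        if (stats::runif(1) < block_rate) {
          add(tf, gene, FALSE, stats::runif(1) < block_lit_rate, TRUE)
        }
      } else if (gene %in% bias_genes) {
        pred <- stats::runif(1) < noise_rate
        lit <- stats::runif(1) < noise_rate
        enc <- stats::runif(1) < noise_rate
        if (pred || lit || enc) add(tf, gene, pred, lit, enc)
      }
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(0), gene = character(0),
               lit_predicted_tfbs = logical(0), lit_chip = logical(0),
               encode_chip = logical(0))
  list(records = records, tfs = tfs, genes = genes,
       truth = list(seed = seed, block_tfs = block_tfs,
                    block_genes = block_genes))
}

#' Generate a silencing RT-qPCR Ct table
#'
#' Emulates a med/LPS x control-siRNA/target-siRNA design over `n_donors`
#' donors with technical replicates. Expression is 1 at baseline,
#' `induction_fold` under LPS, and the knockdown multiplies the LPS-induced
#' expression by `1 - knockdown`. Ct values follow
#' `base_ct - log2(expression)` plus per-replicate Gaussian noise; the
#' reference gene is condition-independent.
#'
#' @param knockdown Named vector of per-gene knockdown fractions.
#' @param induction_fold LPS induction of each target gene.
#' @param n_donors Number of donors.
#' @param n_tech Technical replicates per measurement.
#' @param replicate_sd Per-replicate Ct noise SD.
#' @param donor_sd SD of the per-donor log2 expression offset (cancels in
#'   per-donor percent change).
#' @param reference_gene Reference gene name.
#' @param seed RNG seed (required).
#' @return A list with `ct_table` (long data.frame: `donor`, `treatment`,
#'   `silencing`, `gene`, `replicate`, `ct`) and `truth`.
#' @export
gen_qpcr <- function(knockdown = c(CXCL10 = 0.5), induction_fold = 50,
                     n_donors = 5L, n_tech = 2L, replicate_sd = 0.15,
                     donor_sd = 0.25, reference_gene = "ACTB", seed) {
  set.seed(seed)
  genes <- names(knockdown)
  stopifnot(!is.null(genes), all(knockdown >= 0 & knockdown < 1))
  conds <- expand.grid(treatment = c("med", "LPS"),
                       silencing = c("si_CTR", "si_NRIR"),
                       stringsAsFactors = FALSE)
  rows <- list()
  for (d in seq_len(n_donors)) {
    donor <- sprintf("D%02d", d)
    donor_offset <- stats::rnorm(1, 0, donor_sd)
    for (ci in seq_len(nrow(conds))) {
      tr <- conds$treatment[ci]
      si <- conds$silencing[ci]
      # reference gene
      rows[[length(rows) + 1L]] <- data.frame(
        donor = donor, treatment = tr, silencing = si, gene = reference_gene,
        replicate = seq_len(n_tech),
        ct = 15 + stats::rnorm(n_tech, 0, replicate_sd),
        stringsAsFactors = FALSE)
      for (g in genes) {
        expr <- if (tr == "med") 1 else induction_fold
        if (tr == "LPS" && si == "si_NRIR") expr <- expr * (1 - knockdown[[g]])
        rows[[length(rows) + 1L]] <- data.frame(
          donor = donor, treatment = tr, silencing = si, gene = g,
          replicate = seq_len(n_tech),
          ct = 28 - log2(expr) - donor_offset +
            stats::rnorm(n_tech, 0, replicate_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(ct_table = do.call(rbind, rows),
       truth = list(seed = seed, knockdown = knockdown,
                    induction_fold = induction_fold))
}

#' Generate a subcellular fractionation Ct table
#'
#' Plants per-fraction shares of a transcript (defaults put ~88% in the
#' nucleus with a third chromatin-bound, the hallmark of a chromatin-
#' associated lncRNA) and emits one Ct per fraction.
#'
#' @param shares Named shares over `cytoplasm`, `nucleoplasm`, `chromatin`
#'   (normalized internally).
#' @param gene Gene name.
#' @param noise_sd Ct noise SD.
#' @param seed RNG seed (required).
#' @return A list with `ct_table` (`gene`, `fraction`, `ct`) and `truth`.
#' @export
gen_fractionation <- function(shares = c(cytoplasm = 0.1236,
                                         nucleoplasm = 0.5492,
                                         chromatin = 0.3272),
                              gene = "lncRNA", noise_sd = 0.1, seed) {
  set.seed(seed)
  shares <- shares / sum(shares)
  ct <- 20 - log2(shares) + stats::rnorm(length(shares), 0, noise_sd)
  list(ct_table = data.frame(gene = gene, fraction = names(shares),
                             ct = as.numeric(ct), stringsAsFactors = FALSE),
       truth = list(seed = seed, shares = shares))
}

#' Generate a nuclear RIP Ct table with planted enrichment
#'
#' Each antibody immunoprecipitates the transcript at `folds[ab]` times the
#' IgG baseline percent-of-input.
#'
#' @param folds Named per-antibody fold enrichments over IgG (the IgG entry
#'   itself is implicit).
#' @param igg_percent Baseline IgG percent of input.
#' @param input_fraction Input fraction of the lysate.
#' @param ct_input Input Ct.
#' @param noise_sd IP Ct noise SD.
#' @param gene Gene measured.
#' @param seed RNG seed (required).
#' @return A list with `rip_table` (`antibody`, `gene`, `ct_ip`, `ct_input`,
#'   `input_fraction`) and `truth`.
#' @export
gen_rip <- function(folds = c(STAT1 = 8, STAT2 = 6, p50 = 1),
                    igg_percent = 0.1, input_fraction = 0.1, ct_input = 20,
                    noise_sd = 0.1, gene = "lncRNA", seed) {
  set.seed(seed)
  ab <- c(names(folds), "IgG")
  pct <- c(folds * igg_percent, IgG = igg_percent)
  adjusted <- ct_input - log2(1 / input_fraction)
  ct_ip <- adjusted - log2(pct / 100) + stats::rnorm(length(ab), 0, noise_sd)
  list(rip_table = data.frame(antibody = ab, gene = gene,
                              ct_ip = as.numeric(ct_ip), ct_input = ct_input,
                              input_fraction = input_fraction,
                              stringsAsFactors = FALSE),
       truth = list(seed = seed, folds = folds, igg_percent = igg_percent))
}

#' Generate an RNA/promoter pair with a planted triplex
#'
#' Plants a pure polypurine tract in one promoter and the parallel-motif
#' complementary window (`A -> U`, `G -> C`) in the RNA. The tract is
#' flanked by pyrimidines so the planted alignment cannot extend, making
#' the expected hit coordinates exact.
#'
#' @param rna_len RNA length in nt.
#' @param tract_len Planted tract length.
#' @param n_promoters Number of promoters.
#' @param promoter_length Promoter length in nt.
#' @param gc GC content of the random sequence.
#' @param planted_promoter Index of the promoter receiving the tract.
#' @param seed RNG seed (required).
#' @return A list with `rna` (character), `promoters` ([promoter_set]) and
#'   `truth` (planted coordinates, 0-based half-open).
#' @export
gen_triplex_case <- function(rna_len = 600L, tract_len = 25L,
                             n_promoters = 4L, promoter_length = 1000L,
                             gc = 0.45, planted_promoter = 1L, seed) {
  set.seed(seed)
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  rna <- sample(.BASES, rna_len, replace = TRUE, prob = base_p)
  proms <- lapply(seq_len(n_promoters), function(i) {
    sample(.BASES, promoter_length, replace = TRUE, prob = base_p)
  })
  tract <- sample(c("A", "G"), tract_len, replace = TRUE)
  tts_start <- sample.int(promoter_length - tract_len - 3L, 1L) + 1L  # 1-based
  pp <- proms[[planted_promoter]]
  pp[tts_start:(tts_start + tract_len - 1L)] <- tract
  # pyrimidine flanks: no purine-strand match can extend the planted window
  if (tts_start > 1L) pp[tts_start - 1L] <- sample(c("C", "T"), 1L)
  if (tts_start + tract_len <= promoter_length) {
    pp[tts_start + tract_len] <- sample(c("C", "T"), 1L)
  }
  proms[[planted_promoter]] <- pp
  # parallel third strand: A:T pair read by U(T), G:C pair read by C
  window <- chartr("AG", "TC", tract)
  tfo_start <- sample.int(rna_len - tract_len - 3L, 1L) + 1L
  rna[tfo_start:(tfo_start + tract_len - 1L)] <- window
  ids <- sprintf("PR%02d", seq_len(n_promoters))
  list(rna = paste(rna, collapse = ""),
       promoters = promoter_set(ids, vapply(proms, paste, character(1),
                                            collapse = "")),
       truth = list(seed = seed,
                    gene_id = ids[planted_promoter],
                    tfo_start = tfo_start - 1L,
                    tfo_end = tfo_start - 1L + tract_len,
                    tts_start = tts_start - 1L,
                    tts_end = tts_start - 1L + tract_len,
                    orientation = "parallel", strand = "+"))
}

#' Generate a per-position protein-interaction profile with planted elements
#'
#' @param length Profile length in nt.
#' @param elements List of 0-based half-open `c(start, end)` element spans.
#' @param element_mean,base_mean Mean score inside/outside elements.
#' @param noise_sd Score noise SD.
#' @param seed RNG seed (required).
#' @return A list with `profile` (data.frame `position`, `score`) and
#'   `truth`.
#' @export
gen_binding_profile <- function(length = 800L,
                                elements = list(c(300L, 480L), c(660L, 730L)),
                                element_mean = 0.85, base_mean = 0.15,
                                noise_sd = 0.05, seed) {
  set.seed(seed)
  score <- stats::rnorm(length, base_mean, noise_sd)
  for (el in elements) {
    idx <- (el[1L] + 1L):el[2L]
    score[idx] <- stats::rnorm(length(idx), element_mean, noise_sd)
  }
  list(profile = data.frame(position = seq_len(length) - 1L, score = score),
       truth = list(seed = seed, elements = elements))
}
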