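# TF x gene evidence scoring, hierarchical clustering of TFs, selection of
# the high-coverage cluster, and intersection with enriched-TFBS TFs to
# nominate candidate lncRNA-partner transcription factors.

#' Evidence score for one TF-promoter pair
#'
#' Integer score from three evidence flags, strongest applicable category:
#' literature ChIP and ENCODE ChIP together score 10; ENCODE ChIP alone
#' (regardless of a predicted site) scores 8; literature ChIP alone scores
#' 6; a predicted binding site alone scores 2; no information scores 0.
#'
#' @param lit_predicted_tfbs Logical: literature-predicted binding site in
#'   the promoter.
#' @param lit_chip Logical: experimental literature evidence of recruitment.
#' @param encode_chip Logical: ENCODE evidence of recruitment.
#' @return Integer score in `{0, 2, 6, 8, 10}`; vectorized.
#' @export
evidence_score <- function(lit_predicted_tfbs, lit_chip, encode_chip) {
  ifelse(lit_chip & encode_chip, 10L,
         ifelse(encode_chip, 8L,
                ifelse(lit_chip, 6L,
                       ifelse(lit_predicted_tfbs, 2L, 0L))))
}

#' Build the TF x gene evidence score matrix
#'
#' Dense integer matrix with [evidence_score()] per observed (TF, gene)
#' record and 0 for absent pairs. Row/column order is the input order of the
#' records, followed lexicographically by any requested-but-unseen names.
#' Duplicate records for one pair are allowed only if their flags agree.
#'
#' @param records Data.frame with columns `tf`, `gene`, and logical
#'   `lit_predicted_tfbs`, `lit_chip`, `encode_chip`.
#' @param tfs,genes Optional explicit row/column name vectors.
#' @return Integer matrix (TFs x genes) with entries in `{0, 2, 6, 8, 10}`.
#' @export
build_score_matrix <- function(records, tfs = NULL, genes = NULL) {
  need <- c("tf", "gene", "lit_predicted_tfbs", "lit_chip", "encode_chip")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(records)) {
    key <- paste(records$tf, records$gene, sep = "\r")
    sig <- paste(records$lit_predicted_tfbs, records$lit_chip,
                 records$encode_chip)
    n_sig <- tapply(sig, key, function(x) length(unique(x)))
    if (any(n_sig > 1L)) {
      pair <- strsplit(names(n_sig)[n_sig > 1L][1L], "\r")[[1L]]
      stop(sprintf("conflicting evidence records for TF '%s', gene '%s'",
                   pair[1L], pair[2L]), call. = FALSE)
    }
    records <- records[!duplicated(key), , drop = FALSE]
  }
  seen_tfs <- unique(records$tf)
  seen_genes <- unique(records$gene)
  tfs <- if (is.null(tfs)) seen_tfs else c(tfs, sort(setdiff(seen_tfs, tfs)))
  genes <- if (is.null(genes)) seen_genes else {
    c(genes, sort(setdiff(seen_genes, genes)))
  }
  m <- matrix(0L, nrow = length(tfs), ncol = length(genes),
              dimnames = list(tfs, genes))
  if (nrow(records)) {
    keep <- records$tf %in% tfs & records$gene %in% genes
    r <- records[keep, , drop = FALSE]
    m[cbind(match(r$tf, tfs), match(r$gene, genes))] <-
      evidence_score(r$lit_predicted_tfbs, r$lit_chip, r$encode_chip)
  }
  m
}

#' Hierarchically cluster TFs by their evidence score vectors
#'
#' Agglomerative clustering of the rows of the score matrix (Euclidean
#' distance, complete linkage by default; Ward available), cut into `k`
#' clusters. `hclust` and `cutree` are deterministic for a fixed input
#' order, which provides the tie-breaking rule.
#'
#' @param scores TF x gene numeric matrix (rows are TFs).
#' @param k Number of clusters (default 4).
#' @param method Linkage: `"complete"` (default) or `"ward.D2"`.
#' @return Named integer vector of cluster ids per TF.
#' @export
cluster_tfs <- function(scores, k = 4L, method = c("complete", "ward.D2")) {
  method <- match.arg(method)
  if (is.null(rownames(scores))) {
    stop("score matrix must have TF row names", call. = FALSE)
  }
  if (k < 1L || k > nrow(scores)) {
    stop("k must lie between 1 and the number of TFs", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(scores, method = "euclidean"),
                      method = method)
  stats::cutree(hc, k = k)
}

#' Select the cluster covering the most target genes
#'
#' Per cluster, coverage is the fraction of genes whose within-cluster mean
#' score is positive; the winner has maximal coverage, ties broken by higher
#' overall mean score. A warning is emitted when even the winner covers no
#' more than `coverage_threshold` of the genes (the "majority" criterion).
#'
#' @param scores TF x gene score matrix.
#' @param assignment Cluster assignment from [cluster_tfs()].
#' @param coverage_threshold Majority threshold (fraction of genes).
#' @return A list with `cluster_id`, `tfs`, `coverage`, `mean_score` and a
#'   per-cluster summary table `clusters`.
#' @export
select_high_coverage_cluster <- function(scores, assignment,
                                         coverage_threshold = 0.5) {
  stopifnot(nrow(scores) == length(assignment))
  ids <- sort(unique(assignment))
  summ <- do.call(rbind, lapply(ids, function(cl) {
    rows <- scores[assignment == cl, , drop = FALSE]
    gm <- colMeans(rows)
    data.frame(cluster_id = cl, n_tfs = nrow(rows),
               coverage = mean(gm > 0), mean_score = mean(rows))
  }))
  best <- summ[order(-summ$coverage, -summ$mean_score, summ$cluster_id), ][1L, ]
  if (best$coverage <= coverage_threshold) {
    warning(sprintf(
      "winning cluster covers only %.0f%% of genes (threshold %.0f%%)",
      100 * best$coverage, 100 * coverage_threshold))
  }
  list(cluster_id = best$cluster_id,
       tfs = rownames(scores)[assignment == best$cluster_id],
       coverage = best$coverage,
       mean_score = best$mean_score,
       clusters = summ)
}

# case-insensitive, whitespace-stripped name normalization
.normalize_tf <- function(x) toupper(trimws(x))

#' Intersect cluster TFs with enriched-TFBS TFs
#'
#' The enriched TF list is the union of `tf_names` over significant TFBS
#' enrichment rows; the final candidate set is its name-normalized
#' (case-insensitive, whitespace-stripped) intersection with the cluster
#' TFs, sorted.
#'
#' @param cluster_tfs Character vector of TFs from the selected cluster.
#' @param enriched_rows Data.frame from [tfbs_enrichment()] (columns
#'   `tf_names` with `;`-separated names and logical `significant`).
#' @return A list with `cluster_tfs`, `enriched_tfbs_tfs` and `final_tfs`.
#' @export
intersect_candidates <- function(cluster_tfs, enriched_rows) {
  if (!all(c("tf_names", "significant") %in% names(enriched_rows))) {
    stop("enriched_rows needs columns tf_names, significant", call. = FALSE)
  }
  sig <- enriched_rows$tf_names[enriched_rows$significant]
  enriched <- unique(.normalize_tf(unlist(strsplit(sig, ";", fixed = TRUE))))
  enriched <- enriched[nzchar(enriched)]
  cl <- unique(.normalize_tf(cluster_tfs))
  list(cluster_tfs = sort(cl),
       enriched_tfbs_tfs = sort(enriched),
       final_tfs = sort(intersect(cl, enriched)))
}
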