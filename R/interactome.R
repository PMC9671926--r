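# Consensus selection of putative lncRNA-binding proteins from two predictor
# score tables, functional-class summarization, and protein-binding-element
# (PBE) calling on per-position interaction profiles.

#' Combined catRAPID-style score
#'
#' Arithmetic mean of the interaction score and the discriminative power.
#'
#' @param interaction,discriminative Numeric vectors.
#' @return Their elementwise mean.
#' @export
combine_catrapid <- function(interaction, discriminative) {
  (interaction + discriminative) / 2
}

#' Select consensus lncRNA-binding proteins from two predictors
#'
#' Only proteins present in both tables are candidates. Each candidate gets
#' the combined catRAPID score (mean of interaction score and discriminative
#' power) and its second-predictor score; the selection thresholds are the
#' means of the two scores over the candidate set, and a protein is selected
#' when it exceeds both. The realized thresholds are returned so they can be
#' reported next to the selection.
#'
#' @param catrapid Data.frame with columns `protein_id`, `interaction_score`,
#'   `discriminative_power`.
#' @param lncpro Data.frame with columns `protein_id`, `score`.
#' @param mode `"intersection"` (default) computes the mean thresholds over
#'   the common protein set; `"union"` over each predictor's full table.
#' @param strict If `TRUE` (default) selection requires strictly greater than
#'   both thresholds; ties are excluded.
#' @return A list with `predictions` (one row per common protein, including a
#'   `selected` flag) and `thresholds` (named numeric vector).
#' @export
select_consensus <- function(catrapid, lncpro,
                             mode = c("intersection", "union"),
                             strict = TRUE) {
  mode <- match.arg(mode)
  need_c <- c("protein_id", "interaction_score", "discriminative_power")
  need_l <- c("protein_id", "score")
  if (length(setdiff(need_c, names(catrapid)))) {
    stop("catrapid table needs columns: ", paste(need_c, collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(need_l, names(lncpro)))) {
    stop("lncpro table needs columns: ", paste(need_l, collapse = ", "),
         call. = FALSE)
  }
  common <- intersect(catrapid$protein_id, lncpro$protein_id)
  if (!length(common)) {
    stop("no proteins common to both predictor tables", call. = FALSE)
  }
  ic <- match(common, catrapid$protein_id)
  il <- match(common, lncpro$protein_id)
  combined <- combine_catrapid(catrapid$interaction_score[ic],
                               catrapid$discriminative_power[ic])
  lnc <- lncpro$score[il]
  if (mode == "intersection") {
    thr_cat <- mean(combined)
    thr_lnc <- mean(lnc)
  } else {
    thr_cat <- mean(combine_catrapid(catrapid$interaction_score,
                                     catrapid$discriminative_power))
    thr_lnc <- mean(lncpro$score)
  }
  op <- if (strict) `>` else `>=`
  selected <- op(combined, thr_cat) & op(lnc, thr_lnc)
  predictions <- data.frame(
    protein_id = common,
    catrapid_interaction = catrapid$interaction_score[ic],
    catrapid_discriminative = catrapid$discriminative_power[ic],
    catrapid_combined = combined,
    lncpro_score = lnc,
    selected = selected,
    stringsAsFactors = FALSE)
  list(predictions = predictions,
       thresholds = c(catrapid_combined = thr_cat, lncpro_score = thr_lnc))
}

#' Functional-class summary of selected candidates
#'
#' Summarizes the annotated candidates over the informative classes
#' (`transcriptional`, `post_transcriptional`; `other` and unannotated
#' proteins are excluded from the denominators) and reports the share of
#' transcription factors among the transcriptional class.
#'
#' @param selected_ids Character vector of selected protein ids.
#' @param annotations Data.frame with columns `protein_id`, `family`,
#'   `functional_class` (one of `transcriptional`, `post_transcriptional`,
#'   `other`) and logical `is_tf`.
#' @return A one-row data.frame with counts, denominators and percentages.
#' @export
classify_candidates <- function(selected_ids, annotations) {
  need <- c("protein_id", "functional_class", "is_tf")
  if (length(setdiff(need, names(annotations)))) {
    stop("annotations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ann <- annotations[annotations$protein_id %in% selected_ids, , drop = FALSE]
  informative <- ann[ann$functional_class %in%
                       c("transcriptional", "post_transcriptional"), , drop = FALSE]
  n <- nrow(informative)
  n_tr <- sum(informative$functional_class == "transcriptional")
  n_pt <- sum(informative$functional_class == "post_transcriptional")
  n_tf <- sum(informative$functional_class == "transcriptional" &
                informative$is_tf)
  if (n == 0L) {
    warning("no annotated candidates in an informative class (denominator 0)")
  }
  data.frame(
    n_classified = n,
    n_transcriptional = n_tr,
    pct_transcriptional = if (n > 0) 100 * n_tr / n else 0,
    n_post_transcriptional = n_pt,
    pct_post_transcriptional = if (n > 0) 100 * n_pt / n else 0,
    n_tf = n_tf,
    pct_tf_of_transcriptional = if (n_tr > 0) 100 * n_tf / n_tr else 0)
}

#' Call protein-binding elements from a per-position interaction profile
#'
#' Maximal runs of positions scoring at least `threshold`; runs separated by
#' fewer than `merge_gap` positions are merged; merged runs shorter than
#' `min_length` are dropped. Elements are labeled `PBE-1`, `PBE-2`, ... in
#' decreasing order of mean score over their span (gap positions included).
#'
#' @param profile Numeric vector of per-position scores (position 1 of the
#'   vector is coordinate 0), or a data.frame with columns `position`
#'   (0-based) and `score`.
#' @param threshold Minimum per-position score.
#' @param min_length Minimum element length in nt.
#' @param merge_gap Runs closer than this many nt are merged.
#' @return A data.frame with `label`, `start`, `end` (0-based half-open),
#'   `length`, `mean_score`, ordered by `start`.
#' @export
call_binding_elements <- function(profile, threshold, min_length = 50L,
                                  merge_gap = 10L) {
  if (is.data.frame(profile)) {
    if (!all(c("position", "score") %in% names(profile))) {
      stop("profile data.frame needs columns position, score", call. = FALSE)
    }
    profile <- profile$score[order(profile$position)]
  }
  assert_finite(threshold, "threshold")
  n <- length(profile)
  above <- profile >= threshold
  if (!any(above)) {
    return(data.frame(label = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      mean_score = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by a gap < merge_gap
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged$length <- merged$end - merged$start + 1L
  merged <- merged[merged$length >= min_length, , drop = FALSE]
  if (!nrow(merged)) {
    return(data.frame(label = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      mean_score = numeric(0)))
  }
  merged$mean_score <- vapply(seq_len(nrow(merged)), function(i) {
    mean(profile[merged$start[i]:merged$end[i]])
  }, numeric(1))
  rank <- order(-merged$mean_score, merged$start)
  merged$label[rank] <- paste0("PBE-", seq_along(rank))
  out <- data.frame(label = merged$label,
                    start = merged$start - 1L,      # 0-based half-open
                    end = merged$end,
                    length = merged$length,
                    mean_score = merged$mean_score,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}
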