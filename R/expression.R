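# RT-qPCR analytics: mean normalized expression (MNE), knockdown percent
# change with two-way ANOVA / Bonferroni post tests, subcellular
# fractionation percentages, and RIP percent-of-input / fold-over-IgG.

#' Mean normalized expression (MNE)
#'
#' MNE is the reference-gene-normalized expression measure
#' `E_ref^mean(Ct_ref) / E_target^mean(Ct_target)` where `E` is the
#' amplification efficiency per primer pair (2 means perfect doubling per
#' cycle).
#'
#' @param ct_target Replicate Ct values for the target gene.
#' @param ct_ref Replicate Ct values for the reference gene.
#' @param e_target,e_ref Amplification efficiencies in `[1.5, 2.2]`
#'   (default 2).
#' @return A strictly positive scalar.
#' @export
mne <- function(ct_target, ct_ref, e_target = 2, e_ref = 2) {
  assert_finite(ct_target, "ct_target")
  assert_finite(ct_ref, "ct_ref")
  if (any(c(ct_target, ct_ref) <= 0)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  if (e_target < 1.5 || e_target > 2.2 || e_ref < 1.5 || e_ref > 2.2) {
    stop("amplification efficiencies must lie in [1.5, 2.2]", call. = FALSE)
  }
  e_ref^mean(ct_ref) / e_target^mean(ct_target)
}

#' Percent change of expression between two conditions
#'
#' `100 * (treated - control) / control`, the per-gene statistic used to
#' summarize silencing experiments.
#'
#' @param mne_treated,mne_control MNE (or any positive expression measure)
#'   in the treated and control condition; vectorized.
#' @return Percent change (negative for a knockdown).
#' @export
percent_change <- function(mne_treated, mne_control) {
  assert_finite(mne_treated, "mne_treated")
  assert_finite(mne_control, "mne_control")
  if (any(mne_control <= 0)) stop("control expression must be > 0", call. = FALSE)
  100 * (mne_treated - mne_control) / mne_control
}

#' Two-way ANOVA with Bonferroni-adjusted pairwise contrasts
#'
#' Fits `response ~ A * B` and then, within each level of factor `A`
#' (typically the stimulation factor), compares all pairs of levels of factor
#' `B` (typically the silencing factor) with t tests on the pooled residual
#' mean square; each contrast p-value is multiplied by the contrast family
#' size and capped at 1 (Bonferroni).
#'
#' @param data A data.frame with the response and two factor columns.
#' @param response,factor_a,factor_b Column names.
#' @param family_size Number of comparisons the Bonferroni correction
#'   multiplies by; defaults to the number of contrasts performed.
#' @return A list with `anova` (the ANOVA table), `contrasts` (one row per
#'   pairwise comparison with `t`, `df`, `p`, `p_adj`) and `family_size`.
#' @export
anova2_bonferroni <- function(data, response = "mne", factor_a = "treatment",
                              factor_b = "silencing", family_size = NULL) {
  need <- c(response, factor_a, factor_b)
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  y <- data[[response]]
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  assert_finite(y, response)
  cell_n <- table(a, b)
  if (any(cell_n < 2L)) {
    stop("every design cell needs at least 2 replicates", call. = FALSE)
  }
  fit <- stats::aov(y ~ a * b)
  at <- stats::anova(fit)
  mse <- at["Residuals", "Mean Sq"]
  dfr <- at["Residuals", "Df"]

  lev_b <- levels(b)
  pairs_b <- utils::combn(lev_b, 2L, simplify = FALSE)
  rows <- list()
  for (la in levels(a)) {
    for (pb in pairs_b) {
      y1 <- y[a == la & b == pb[1L]]
      y2 <- y[a == la & b == pb[2L]]
      est <- mean(y2) - mean(y1)
      se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
      tval <- if (se > 0) est / se else if (abs(est) < .Machine$double.eps) 0 else sign(est) * Inf
      p <- 2 * stats::pt(-abs(tval), dfr)
      rows[[length(rows) + 1L]] <- data.frame(
        level_a = la, group1 = pb[1L], group2 = pb[2L],
        estimate = est, t = tval, df = dfr, p = p,
        stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)
  m <- family_size %||% nrow(contrasts)
  contrasts$p_adj <- pmin(1, m * contrasts$p)
  list(anova = at, contrasts = contrasts, family_size = m)
}

#' Subcellular fractionation percentages
#'
#' Expresses per-fraction quantities as percent of the total cell lysate,
#' where the total is by default the sum over the three fractions
#' (cytoplasm, nucleoplasm, chromatin); a separately measured total can be
#' supplied as `total`. The nuclear share (nucleoplasm + chromatin) is
#' attached as attribute `nuclear_percent`.
#'
#' @param values Named positive numeric vector with names `cytoplasm`,
#'   `nucleoplasm`, `chromatin` (any expression measure; the result is
#'   scale-invariant).
#' @param total Optional denominator replacing `sum(values)`.
#' @return A data.frame with columns `fraction` and `percent_of_total`.
#' @export
fraction_percentages <- function(values, total = NULL) {
  fr <- c("cytoplasm", "nucleoplasm", "chromatin")
  if (is.null(names(values)) || !setequal(names(values), fr)) {
    stop("values must be named cytoplasm, nucleoplasm, chromatin", call. = FALSE)
  }
  values <- values[fr]
  assert_finite(values, "values")
  if (any(values < 0)) stop("fraction quantities must be non-negative", call. = FALSE)
  denom <- total %||% sum(values)
  if (denom <= 0) stop("total must be > 0", call. = FALSE)
  pct <- 100 * values / denom
  out <- data.frame(fraction = fr, percent_of_total = as.numeric(pct),
                    stringsAsFactors = FALSE)
  attr(out, "nuclear_percent") <- sum(pct[c("nucleoplasm", "chromatin")])
  out
}

#' RIP yield as percent of input
#'
#' Adjusts the input Ct for the fraction of lysate the input represents
#' (`ct_input - log2(1/input_fraction)`) and returns
#' `100 * 2^(adjusted_input_ct - ct_ip)`.
#'
#' @param ct_ip Ct of the immunoprecipitated RNA (vectorized).
#' @param ct_input Ct of the non-immunoprecipitated input RNA.
#' @param input_fraction Fraction of lysate used as input, in `(0, 1]`.
#' @return Percent of input (>= 0), monotone decreasing in `ct_ip`.
#' @export
percent_of_input <- function(ct_ip, ct_input, input_fraction = 0.1) {
  assert_finite(ct_ip, "ct_ip")
  assert_finite(ct_input, "ct_input")
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("input_fraction must lie in (0, 1]", call. = FALSE)
  }
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

#' RNA enrichment as fold over the IgG control
#'
#' @param percent_input_ab Percent of input in the specific-antibody IP.
#' @param percent_input_igg Percent of input in the IgG control IP (> 0).
#' @return The enrichment ratio.
#' @export
fold_over_igg <- function(percent_input_ab, percent_input_igg) {
  assert_finite(percent_input_ab, "percent_input_ab")
  assert_finite(percent_input_igg, "percent_input_igg")
  if (any(percent_input_igg <= 0)) {
    stop("IgG percent of input is zero: degenerate control", call. = FALSE)
  }
  percent_input_ab / percent_input_igg
}

#' Relative quantities from per-fraction Ct values
#'
#' Converts Ct values to relative abundance `efficiency^(-ct)`; the absolute
#' scale is irrelevant downstream because [fraction_percentages()] is
#' scale-invariant.
#'
#' @param ct Named numeric vector of Ct values (names are fractions).
#' @param efficiency Amplification efficiency (default 2).
#' @return Named numeric vector of relative quantities.
#' @export
quantify_fractions <- function(ct, efficiency = 2) {
  assert_finite(ct, "ct")
  q <- efficiency^(-ct)
  # rescale so values are O(1); purely cosmetic
  q / max(q)
}

#' Full knockdown analysis of a long-format Ct table
#'
#' Computes per-donor MNE for every gene and condition, per-donor percent
#' change of the stimulated treated condition versus its control, and a
#' two-way ANOVA (treatment x silencing) with Bonferroni-adjusted contrasts
#' per gene.
#'
#' @param ct_table Long data.frame with columns `donor`, `treatment`,
#'   `silencing`, `gene`, `ct` (one row per technical replicate).
#' @param reference_gene Reference gene name (default `"ACTB"`).
#' @param e_target,e_ref Amplification efficiencies.
#' @param stimulus Level of `treatment` on which the knockdown is quantified.
#' @param control_level,treated_level Levels of `silencing` contrasted.
#' @return A list with `mne` (per donor/condition/gene), `percent_change`
#'   (per donor and gene) and `summary` (per gene: mean and SEM of the
#'   percent change plus the adjusted p for the stimulated contrast).
#' @export
analyze_knockdown <- function(ct_table, reference_gene = "ACTB",
                              e_target = 2, e_ref = 2, stimulus = "LPS",
                              control_level = "si_CTR",
                              treated_level = "si_NRIR") {
  need <- c("donor", "treatment", "silencing", "gene", "ct")
  missing <- setdiff(need, names(ct_table))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  genes <- setdiff(unique(ct_table$gene), reference_gene)
  if (!reference_gene %in% ct_table$gene) {
    stop("reference gene '", reference_gene, "' absent from table", call. = FALSE)
  }
  key <- function(d) interaction(d$donor, d$treatment, d$silencing, drop = TRUE)
  ref <- ct_table[ct_table$gene == reference_gene, ]
  ref_split <- split(ref$ct, key(ref))

  mne_rows <- list()
  for (g in genes) {
    tg <- ct_table[ct_table$gene == g, ]
    for (grp in split(tg, key(tg))) {
      k <- as.character(key(grp)[1L])
      if (is.null(ref_split[[k]])) {
        stop("no reference Ct for sample ", k, call. = FALSE)
      }
      mne_rows[[length(mne_rows) + 1L]] <- data.frame(
        donor = grp$donor[1L], treatment = grp$treatment[1L],
        silencing = grp$silencing[1L], gene = g,
        mne = mne(grp$ct, ref_split[[k]], e_target, e_ref),
        stringsAsFactors = FALSE)
    }
  }
  mne_df <- do.call(rbind, mne_rows)

  pc_rows <- list()
  sum_rows <- list()
  for (g in genes) {
    mg <- mne_df[mne_df$gene == g, ]
    donors <- sort(unique(mg$donor))
    pc <- vapply(donors, function(d) {
      tr <- mg$mne[mg$donor == d & mg$treatment == stimulus &
                     mg$silencing == treated_level]
      ct <- mg$mne[mg$donor == d & mg$treatment == stimulus &
                     mg$silencing == control_level]
      if (!length(tr) || !length(ct)) return(NA_real_)
      percent_change(tr, ct)
    }, numeric(1))
    pc_rows[[g]] <- data.frame(gene = g, donor = donors, pct_change = pc,
                               stringsAsFactors = FALSE)
    an <- anova2_bonferroni(mg, response = "mne", factor_a = "treatment",
                            factor_b = "silencing")
    hit <- an$contrasts[an$contrasts$level_a == stimulus, , drop = FALSE]
    sum_rows[[g]] <- data.frame(
      gene = g,
      mean_pct_change = mean(pc, na.rm = TRUE),
      sem_pct_change = stats::sd(pc, na.rm = TRUE) / sqrt(sum(!is.na(pc))),
      p_adj = if (nrow(hit)) min(hit$p_adj) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(mne = mne_df,
       percent_change = do.call(rbind, pc_rows),
       summary = do.call(rbind, sum_rows))
}

#' RIP quantification of a per-antibody Ct table
#'
#' @param rip_table Data.frame with columns `antibody`, `gene`, `ct_ip`,
#'   `ct_input`, `input_fraction`.
#' @param igg Name of the IgG control antibody (default `"IgG"`).
#' @return Data.frame with `percent_input` and `fold_over_igg` per
#'   antibody/gene.
#' @export
analyze_rip <- function(rip_table, igg = "IgG") {
  need <- c("antibody", "gene", "ct_ip", "ct_input", "input_fraction")
  missing <- setdiff(need, names(rip_table))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!igg %in% rip_table$antibody) {
    stop("IgG control antibody '", igg, "' absent from table", call. = FALSE)
  }
  out <- rip_table
  out$percent_input <- percent_of_input(out$ct_ip, out$ct_input,
                                        out$input_fraction)
  igg_pct <- stats::setNames(
    out$percent_input[out$antibody == igg],
    out$gene[out$antibody == igg])
  out$fold_over_igg <- fold_over_igg(out$percent_input,
                                     igg_pct[out$gene])
  rownames(out) <- NULL
  out
}
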