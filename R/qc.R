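#' Up/down differential counts for one contrast
#'
#' A protein is "up" when its fold change is at least `fc_cut` and its
#' adjusted p at most `p_cut`; "down" when the fold change is at most
#' `1/fc_cut` at the same significance. Both bounds are inclusive, so FC
#' exactly 2 with adjusted p exactly 0.05 counts as up, while FC 1.95 does
#' not. Records carrying an estimated fold change are excluded: they have no
#' p-value and are counted in the bait-only category instead.
#'
#' @param records a `pl_contrast` (or compatible data.frame).
#' @param fc_cut linear fold-change cutoff (default 2).
#' @param p_cut adjusted-p cutoff (default 0.05).
#' @return named integer vector `c(up = , down = )`.
#' @export
up_down_counts <- function(records, fc_cut = 2, p_cut = 0.05) {
  ok <- !records$fc_is_estimate & !is.na(records$fold_change) & !is.na(records$adj_p)
  up <- sum(ok & records$fold_change >= fc_cut & records$adj_p <= p_cut)
  down <- sum(ok & records$fold_change <= 1 / fc_cut & records$adj_p <= p_cut)
  c(up = up, down = down)
}

#' Quality-metric ratios
#'
#' `up_percent` is the share of up proteins among all differential proteins,
#' `100 * up / (up + down)`; `turboid_percent` is the analogous share of
#' bait-exclusive detections among all exclusive detections,
#' `100 * turboid_only / (turboid_only + n2_only)`. Both are `NA` when the
#' denominator is zero.
#'
#' @param up_count,down_count non-negative counts.
#' @return percentage in \[0, 100\], or `NA`.
#' @export
up_percent <- function(up_count, down_count) {
  tot <- up_count + down_count
  ifelse(tot > 0, 100 * up_count / tot, NA_real_)
}

#' @rdname up_percent
#' @param turboid_only_count,n2_only_count exclusive-detection counts.
#' @export
turboid_percent <- function(turboid_only_count, n2_only_count) {
  up_percent(turboid_only_count, n2_only_count)
}

#' Carboxylase share of total detected intensity
#'
#' Endogenously biotinylated carboxylases dominate a clean streptavidin
#' pulldown, so their share of the total signal tracks how well the sample
#' was enriched for biotinylated protein. Computed on pooled detected
#' intensity over the given runs: 100 * (summed intensity of carboxylase-set
#' proteins) / (summed intensity of all proteins). Pooling over replicates
#' (rather than averaging per-run ratios) is robust to per-run dropout; the
#' two aggregations coincide exactly only when per-run totals are equal.
#'
#' @param mat a `pl_matrix`.
#' @param runs run ids of one sample (non-empty).
#' @param carboxylase_set reference set of carboxylase identifiers.
#' @return percentage in \[0, 100\].
#' @export
carboxylase_percent <- function(mat, runs, carboxylase_set) {
  if (!length(runs)) stop("`runs` must be non-empty", call. = FALSE)
  check_runs(mat, runs)
  v <- unclass(mat)[, runs, drop = FALSE]
  total <- sum(v, na.rm = TRUE)
  if (total <= 0) stop("total detected intensity is zero", call. = FALSE)
  carb <- in_reference(rownames(mat), carboxylase_set)
  100 * sum(v[carb, , drop = FALSE], na.rm = TRUE) / total
}

#' Overlap of a candidate set with a tissue-expression reference
#'
#' The fraction of filtered candidates that appear in a reference of
#' proteins known to be expressed in the relevant tissue -- for an
#' epidermally expressed bait, the combined epidermal proteome/transcriptome
#' set. 100 * |candidates in reference| / |candidates|.
#'
#' @param protein_set character vector of candidate ids (non-empty).
#' @param tissue_reference reference set.
#' @return percentage in \[0, 100\].
#' @export
epidermal_percent <- function(protein_set, tissue_reference) {
  if (!length(protein_set)) stop("`protein_set` must be non-empty", call. = FALSE)
  100 * mean(in_reference(protein_set, tissue_reference))
}

#' Detection overlap among technical replicates
#'
#' Venn-region counts of protein detection across the runs of one sample:
#' each protein detected in at least one run is assigned to the region given
#' by its detection pattern (a binary string over runs). Reports region
#' counts, the total number of unique proteins, and the fraction detected in
#' every run.
#'
#' @param mat a `pl_matrix`.
#' @param runs at least two run ids.
#' @return list with `regions` (named integer vector keyed by pattern, runs
#'   in the order given), `n` (union size), `frac_all` (fraction of the
#'   union detected in all runs).
#' @export
replicate_overlap <- function(mat, runs) {
  if (length(runs) < 2) stop("need >= 2 runs", call. = FALSE)
  check_runs(mat, runs)
  det <- !is.na(unclass(mat)[, runs, drop = FALSE])
  any_det <- rowSums(det) > 0
  pattern <- apply(det[any_det, , drop = FALSE], 1, function(r) paste(as.integer(r), collapse = ""))
  all_patterns <- apply(expand.grid(rep(list(c(1L, 0L)), length(runs)))[, length(runs):1, drop = FALSE],
                        1, paste, collapse = "")
  all_patterns <- setdiff(all_patterns, strrep("0", length(runs)))
  regions <- table(factor(pattern, levels = all_patterns))
  n <- sum(any_det)
  list(regions = stats::setNames(as.integer(regions), names(regions)),
       n = n,
       frac_all = if (n > 0) unname(regions[[strrep("1", length(runs))]]) / n else NA_real_)
}

#' Intensity agreement between two replicate runs
#'
#' R-squared of an ordinary least-squares fit on log2 intensities of the
#' proteins detected in both runs. Proteins detected in only one of the two
#' runs do not enter the fit. Symmetric in its arguments; `NA` when fewer
#' than three proteins are co-detected.
#'
#' @param mat a `pl_matrix`.
#' @param run_a,run_b run ids.
#' @return R-squared, or `NA`.
#' @export
replicate_r2 <- function(mat, run_a, run_b) {
  check_runs(mat, c(run_a, run_b))
  v <- unclass(mat)
  shared <- !is.na(v[, run_a]) & !is.na(v[, run_b])
  if (sum(shared) < 3) return(NA_real_)
  x <- log2(v[shared, run_a]); y <- log2(v[shared, run_b])
  # exactly proportional replicates are legitimate; silence the perfect-fit note
  suppressWarnings(summary(stats::lm(y ~ x)))$r.squared
}

#' All pairwise replicate R-squared values for one sample
#' @param mat a `pl_matrix`.
#' @param runs run ids.
#' @return data.frame with columns `run_a`, `run_b`, `r2`.
#' @export
replicate_r2_pairs <- function(mat, runs) {
  pairs <- utils::combn(runs, 2)
  data.frame(run_a = pairs[1, ], run_b = pairs[2, ],
             r2 = apply(pairs, 2, function(p) replicate_r2(mat, p[1], p[2])),
             stringsAsFactors = FALSE)
}

#' Linear association between two quality metrics across experiments
#'
#' Simple linear regression of one metric on another over a set of
#' per-sample QC rows, used to ask e.g. whether Carboxylase % tracks Up %.
#'
#' @param reports data.frame of QC rows (e.g. from [summarize_study()]).
#' @param x_metric,y_metric column names.
#' @return list `r2`, `slope`, `p`; all `NA` when fewer than 3 complete
#'   pairs or when x has no variance.
#' @export
metric_correlation <- function(reports, x_metric, y_metric) {
  x <- reports[[x_metric]]; y <- reports[[y_metric]]
  ok <- !is.na(x) & !is.na(y)
  undefined <- list(r2 = NA_real_, slope = NA_real_, p = NA_real_)
  if (sum(ok) < 3) return(undefined)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0) return(undefined)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  list(r2 = sm$r.squared,
       slope = unname(stats::coef(fit)[2]),
       p = unname(sm$coefficients[2, 4]))
}

#' Per-sample QC metric panel for one bait contrast
#'
#' Assembles the quality-metric row for one (strain, experiment) bait
#' sample: up/down counts and Up %, exclusive-detection counts and
#' TurboID %, Carboxylase %, optionally Epidermal % of a filtered candidate
#' set, the bait's own (cis) fold change, and fold changes of known complex
#' partners (trans).
#'
#' @param contrast a `pl_contrast` for the bait vs negative control.
#' @param mat the `pl_matrix` (for Carboxylase %).
#' @param strain,experiment labels for the row.
#' @param carboxylase_set,tissue_reference optional reference sets.
#' @param bait_protein optional bait protein id.
#' @param partners optional character vector of complex-partner ids.
#' @param filtered_set optional candidate set for Epidermal %.
#' @param fc_cut,p_cut thresholds passed to [up_down_counts()].
#' @return one-row data.frame of class `pl_qc`.
#' @export
qc_report <- function(contrast, mat, strain, experiment,
                      carboxylase_set = NULL, tissue_reference = NULL,
                      bait_protein = NULL, partners = NULL, filtered_set = NULL,
                      fc_cut = 2, p_cut = 0.05) {
  ud <- up_down_counts(contrast, fc_cut, p_cut)
  tid <- sum(contrast$detection_category == "bait_only")
  n2o <- sum(contrast$detection_category == "control_only")
  carb <- if (is.null(carboxylase_set)) NA_real_ else
    carboxylase_percent(mat, attr(contrast, "bait_runs"), carboxylase_set)
  epi <- if (is.null(tissue_reference) || is.null(filtered_set) || !length(filtered_set))
    NA_real_ else epidermal_percent(filtered_set, tissue_reference)
  fc_of <- function(id) {
    if (is.null(id)) return(list(fc = NA_real_, est = NA))
    i <- match(tolower(id), tolower(contrast$protein_id))
    if (is.na(i)) return(list(fc = NA_real_, est = NA))
    list(fc = contrast$fold_change[i], est = contrast$fc_is_estimate[i])
  }
  bait <- fc_of(bait_protein)
  prey <- if (length(partners)) {
    vapply(partners, function(p) fc_of(p)$fc, numeric(1))
  } else numeric(0)
  out <- data.frame(strain_label = strain, experiment_id = experiment,
                    up_count = ud[["up"]], down_count = ud[["down"]],
                    up_percent = up_percent(ud[["up"]], ud[["down"]]),
                    turboid_only_count = tid, n2_only_count = n2o,
                    turboid_percent = turboid_percent(tid, n2o),
                    carboxylase_percent = carb,
                    epidermal_percent = epi,
                    bait_cis_fc = bait$fc,
                    bait_fc_estimated = isTRUE(bait$est),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prey_trans_fcs") <- prey
  class(out) <- c("pl_qc", "data.frame")
  out
}
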