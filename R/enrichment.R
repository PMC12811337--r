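#' Select run identifiers by sample annotation
#'
#' @param mat a `pl_matrix`.
#' @param strain,experiment,role optional filters; `NULL` matches anything.
#' @return character vector of run ids.
#' @export
run_ids <- function(mat, strain = NULL, experiment = NULL, role = NULL) {
  s <- pl_samples(mat)
  keep <- rep(TRUE, nrow(s))
  if (!is.null(strain)) keep <- keep & s$strain_label %in% strain
  if (!is.null(experiment)) keep <- keep & s$experiment_id %in% experiment
  if (!is.null(role)) keep <- keep & s$role %in% role
  s$run_id[keep]
}

check_runs <- function(mat, runs) {
  bad <- setdiff(runs, colnames(mat))
  if (length(bad)) stop("unknown run(s): ", paste(bad, collapse = ", "), call. = FALSE)
  runs
}

#' Group mean over detected replicates
#'
#' The arithmetic mean of a protein's intensity over the runs in which it was
#' detected; runs where it was not detected are skipped, not counted as zero,
#' so e.g. intensities (13, ND, ND) average to 13. Returns `NA` only when the
#' protein was detected in none of the runs.
#'
#' @param mat a `pl_matrix`.
#' @param runs run ids (non-empty).
#' @param protein protein id(s); all proteins when `NULL`.
#' @return named numeric vector of means (`NA` = absent from all runs).
#' @export
group_mean <- function(mat, runs, protein = NULL) {
  if (!length(runs)) stop("`runs` must be non-empty", call. = FALSE)
  check_runs(mat, runs)
  v <- unclass(mat)[protein %||% rownames(mat), runs, drop = FALSE]
  out <- rowMeans(v, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

n_detected <- function(mat, runs, protein = NULL) {
  v <- unclass(mat)[protein %||% rownames(mat), runs, drop = FALSE]
  rowSums(!is.na(v))
}

#' Classify detection pattern of proteins across two run groups
#'
#' Categories follow the exclusive-detection definitions used for the
#' "TurboID-only" and "N2-only" protein classes: `bait_only` means detected
#' in every bait run and in no control run; `control_only` the reverse;
#' `both` means detected in at least one run of each group; `neither` means
#' detected nowhere; `partial` means detected in a strict subset of exactly
#' one group's runs. The five categories partition the protein universe for
#' fixed run sets.
#'
#' @param mat a `pl_matrix`.
#' @param bait_runs,control_runs non-empty, disjoint run id vectors.
#' @param protein protein id(s); all when `NULL`.
#' @return named character vector of categories.
#' @export
classify_detection <- function(mat, bait_runs, control_runs, protein = NULL) {
  if (!length(bait_runs) || !length(control_runs))
    stop("both run sets must be non-empty", call. = FALSE)
  nb <- n_detected(mat, check_runs(mat, bait_runs), protein)
  nc <- n_detected(mat, check_runs(mat, control_runs), protein)
  Rb <- length(bait_runs); Rc <- length(control_runs)
  out <- rep("partial", length(nb))
  out[nb > 0 & nc > 0] <- "both"
  out[nb == Rb & nc == 0] <- "bait_only"
  out[nb == 0 & nc == Rc] <- "control_only"
  out[nb == 0 & nc == 0] <- "neither"
  names(out) <- names(nb)
  out
}

#' Conservative fold-change estimate for proteins absent from the control
#'
#' When a protein is missing from every negative-control replicate no direct
#' fold change exists. A detection-floor proxy is used instead: take the `k`
#' lowest control group means among proteins that were detected in every
#' control replicate, average them, and divide the bait mean by that floor.
#' Because the floor is taken from the weakest reliably detected proteins,
#' the resulting fold change is a conservative lower-bound style estimate.
#'
#' @param bait_mean positive bait-group mean (linear scale).
#' @param mat a `pl_matrix` providing the control intensities.
#' @param control_runs negative-control run ids.
#' @param k number of floor proteins to average (default 10).
#' @return estimated linear fold change.
#' @export
estimate_missing_fc <- function(bait_mean, mat, control_runs, k = 10) {
  floor_val <- detection_floor(mat, control_runs, k)
  bait_mean / floor_val
}

#' @rdname estimate_missing_fc
#' @export
detection_floor <- function(mat, control_runs, k = 10) {
  check_runs(mat, control_runs)
  nc <- n_detected(mat, control_runs)
  full <- names(nc)[nc == length(control_runs)]
  if (length(full) < k)
    stop("only ", length(full), " proteins detected in every control run; ",
         "need >= ", k, " - use a smaller k", call. = FALSE)
  means <- group_mean(mat, control_runs, full)
  mean(sort(means)[seq_len(k)])
}

welch_log2_p <- function(bait, ctrl) {
  # zero-variance groups crash t.test; equal constant groups are a clean null
  p <- tryCatch(stats::t.test(log2(bait), log2(ctrl), var.equal = FALSE)$p.value,
                error = function(e) {
                  if (isTRUE(all.equal(mean(log2(bait)), mean(log2(ctrl))))) 1 else NA_real_
                })
  p
}

#' Per-protein enrichment of a bait sample against its negative control
#'
#' For every protein: group means over detected replicates, the linear and
#' log2 fold change (bait/control), a Welch two-sample t-test on log2
#' intensities over the detected replicates (requiring at least
#' `min_reps` detected values per group), Benjamini-Hochberg adjustment over
#' all proteins with a defined p in this contrast, and the detection
#' category. Proteins detected in every bait replicate but in no control
#' replicate receive a conservative estimated fold change via
#' [estimate_missing_fc()] when `estimate = TRUE` and the control matrix
#' supports it; such records carry `fc_is_estimate = TRUE` and no p-value.
#'
#' Alternatively `test = "ingest"` takes p/adjusted-p values computed by
#' upstream software from columns of `ingest`, keeping fidelity to vendor
#' pipelines whose internal model is not reproduced here.
#'
#' @param mat a `pl_matrix`.
#' @param bait_runs,control_runs disjoint, non-empty run id vectors.
#' @param test `"welch"` (default) or `"ingest"`.
#' @param min_reps minimum detected replicates per group for a p-value.
#' @param estimate compute estimated fold changes for bait-only proteins.
#' @param estimate_k floor size for [estimate_missing_fc()].
#' @param ingest data.frame with columns `protein_id`, `p_value`, `adj_p`
#'   when `test = "ingest"`.
#' @return a `pl_contrast`: data.frame with one row per protein (columns
#'   `protein_id`, `bait_mean`, `control_mean`, `n_detected_bait`,
#'   `n_detected_control`, `fold_change`, `log2_fc`, `p_value`, `adj_p`,
#'   `fc_is_estimate`, `detection_category`) plus attributes recording the
#'   run sets and parameters.
#' @export
compute_enrichment <- function(mat, bait_runs, control_runs, test = c("welch", "ingest"),
                               min_reps = 2, estimate = TRUE, estimate_k = 10,
                               ingest = NULL) {
  test <- match.arg(test)
  check_runs(mat, bait_runs); check_runs(mat, control_runs)
  if (length(intersect(bait_runs, control_runs)))
    stop("bait and control run sets overlap", call. = FALSE)
  ids <- rownames(mat)
  bm <- group_mean(mat, bait_runs)
  cm <- group_mean(mat, control_runs)
  nb <- n_detected(mat, bait_runs)
  nc <- n_detected(mat, control_runs)
  cat_ <- classify_detection(mat, bait_runs, control_runs)
  fc <- ifelse(!is.na(bm) & !is.na(cm), bm / cm, NA_real_)
  est <- rep(FALSE, length(ids))

  if (estimate) {
    cand <- which(nb == length(bait_runs) & nc == 0)
    if (length(cand)) {
      floor_val <- tryCatch(detection_floor(mat, control_runs, estimate_k),
                            error = function(e) {
                              warning(conditionMessage(e), call. = FALSE)
                              NA_real_
                            })
      if (!is.na(floor_val)) {
        fc[cand] <- bm[cand] / floor_val
        est[cand] <- TRUE
      }
    }
  }

  p <- rep(NA_real_, length(ids))
  if (test == "welch") {
    v <- unclass(mat)
    testable <- which(nb >= min_reps & nc >= min_reps)
    for (i in testable) {
      b <- v[i, bait_runs]; ctl <- v[i, control_runs]
      p[i] <- welch_log2_p(b[!is.na(b)], ctl[!is.na(ctl)])
    }
    adj <- rep(NA_real_, length(ids))
    adj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  } else {
    if (is.null(ingest)) stop("test = 'ingest' requires `ingest`", call. = FALSE)
    idx <- match(tolower(ids), tolower(normalize_ids(ingest$protein_id)))
    p <- ingest$p_value[idx]
    adj <- ingest$adj_p[idx]
  }

  out <- data.frame(protein_id = ids,
                    bait_mean = bm, control_mean = cm,
                    n_detected_bait = nb, n_detected_control = nc,
                    fold_change = fc, log2_fc = log2(fc),
                    p_value = p, adj_p = adj,
                    fc_is_estimate = est,
                    detection_category = cat_,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out,
            bait_runs = bait_runs, control_runs = control_runs,
            n_bait_runs = length(bait_runs), n_control_runs = length(control_runs),
            test = test, min_reps = min_reps, estimate_k = estimate_k,
            class = c("pl_contrast", "data.frame"))
}

#' @export
print.pl_contrast <- function(x, fc_cut = 2, p_cut = 0.05, ...) {
  ud <- up_down_counts(x, fc_cut, p_cut)
  cat(sprintf("<pl_contrast> %d proteins (%d bait runs vs %d control runs, %s test)\n",
              nrow(x), attr(x, "n_bait_runs"), attr(x, "n_control_runs"),
              attr(x, "test")))
  cat(sprintf("  up: %d  down: %d  bait-only: %d  control-only: %d  estimated FC: %d\n",
              ud[["up"]], ud[["down"]],
              sum(x$detection_category == "bait_only"),
              sum(x$detection_category == "control_only"),
              sum(x$fc_is_estimate)))
  invisible(x)
}

#' @export
summary.pl_contrast <- function(object, fc_cut = 2, p_cut = 0.05, ...) {
  ud <- up_down_counts(object, fc_cut, p_cut)
  tab <- table(factor(object$detection_category,
                      levels = c("both", "bait_only", "control_only", "partial", "neither")))
  out <- list(n_proteins = nrow(object), up = ud[["up"]], down = ud[["down"]],
              up_percent = up_percent(ud[["up"]], ud[["down"]]),
              detection = tab, n_estimated = sum(object$fc_is_estimate))
  class(out) <- "summary.pl_contrast"
  out
}

#' @export
print.summary.pl_contrast <- function(x, ...) {
  cat(sprintf("proteins: %d  up: %d  down: %d  Up %%: %s  estimated FC: %d\n",
              x$n_proteins, x$up, x$down,
              ifelse(is.na(x$up_percent), "undef", sprintf("%.1f", x$up_percent)),
              x$n_estimated))
  print(x$detection)
  invisible(x)
}
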