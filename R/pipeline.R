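#' Assemble the run-level study configuration
#'
#' Normalizes a pipeline configuration given as a list or as a YAML/JSON
#' file. Recognized fields: `quant_table`, `sample_sheet` (paths; or pass a
#' `pl_matrix` directly to [run_pipeline()]), `out_dir`, `filter1_only`,
#' reference paths `carboxylase_set`, `tissue_reference`, `complex_members`,
#' a `baits` block (strain -> list(bait, partners)), and a `thresholds`
#' block (`fc_cut`, `p_cut`, `ratio_cut`, `remove_above_control_fc`,
#' `min_reps`, `estimate_k`) with the published defaults.
#'
#' @param config list or path to a YAML/JSON file.
#' @return normalized config list of class `pl_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  defaults <- list(fc_cut = 2, p_cut = 0.05, ratio_cut = 1.5,
                   remove_above_control_fc = 5, min_reps = 2, estimate_k = 10)
  th <- utils::modifyList(defaults, config$thresholds %||% list())
  if (any(unlist(th) <= 0)) stop("thresholds must be positive", call. = FALSE)
  config$thresholds <- th
  config$filter1_only <- isTRUE(config$filter1_only)
  class(config) <- "pl_config"
  config
}

load_ref <- function(x, name) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "pl_reference_set")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(read_reference_set(x, name))
  reference_set(x, name)
}

safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Run the full post-acquisition workflow
#'
#' For every bait strain in every experiment: enrichment against that
#' experiment's negative control, first-stage filtering, annotation against
#' the non-specific control reference, second-stage filtering, a QC metric
#' row, and an annotated per-protein table on disk. Control (promiscuous
#' ligase) contrasts across experiments are merged into the control
#' reference; occurrence tables across biological replicates and the study
#' summary are written alongside a JSON manifest listing every artifact
#' with its row count and every threshold used. The workflow is
#' deterministic: rerunning on identical inputs reproduces identical
#' outputs.
#'
#' @param config a [pipeline_config()] (or list/path coercible to one).
#' @param matrix optional `pl_matrix`, bypassing the file inputs.
#' @return (invisibly) list with `contrasts`, `filter1`, `filter2`,
#'   `annotations`, `control_reference`, `qc`, `summary`, `occurrence`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), matrix = NULL) {
  cfg <- if (inherits(config, "pl_config")) config else pipeline_config(config)
  th <- cfg$thresholds
  if (is.null(matrix)) {
    if (is.null(cfg$quant_table) || is.null(cfg$sample_sheet))
      stop("config must provide quant_table and sample_sheet (or pass `matrix`)",
           call. = FALSE)
    matrix <- read_quant_table(cfg$quant_table, cfg$sample_sheet)
  }
  s <- pl_samples(matrix)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  carb_ref <- load_ref(cfg$carboxylase_set, "carboxylases")
  tissue_ref <- load_ref(cfg$tissue_reference, "tissue")
  complex_ref <- load_ref(cfg$complex_members, "complex_members")

  experiments <- unique(s$experiment_id)
  contrast_of <- function(strain, exp) {
    bait_runs <- s$run_id[s$strain_label == strain & s$experiment_id == exp]
    neg_runs <- s$run_id[s$role == "negative_control" & s$experiment_id == exp]
    if (!length(neg_runs))
      stop("experiment ", exp, " has no negative_control runs; ",
           "cannot compute the contrast for ", strain, call. = FALSE)
    compute_enrichment(matrix, bait_runs, neg_runs,
                       min_reps = th$min_reps, estimate_k = th$estimate_k)
  }

  # control contrasts -> non-specific reference
  ns <- unique(s[s$role == "nonspecific_control", c("strain_label", "experiment_id")])
  control_contrasts <- list()
  if (nrow(ns)) {
    for (i in seq_len(nrow(ns)))
      control_contrasts[[ns$experiment_id[i]]] <-
        contrast_of(ns$strain_label[i], ns$experiment_id[i])
  }
  control_ref <- NULL
  if (length(control_contrasts)) {
    control_ref <- build_control_reference(control_contrasts,
                                           fc_cut = th$fc_cut, p_cut = th$p_cut)
  } else if (!cfg$filter1_only) {
    stop("no nonspecific_control runs present: the control-referenced filter ",
         "cannot be built; set filter1_only = TRUE to run first-stage ",
         "filtering only", call. = FALSE)
  }

  bait_pairs <- unique(s[s$role == "bait", c("strain_label", "experiment_id")])
  contrasts <- list(); f1 <- list(); f2 <- list(); ann <- list()
  qc_rows <- list(); files <- list()
  for (i in seq_len(nrow(bait_pairs))) {
    strain <- bait_pairs$strain_label[i]; exp <- bait_pairs$experiment_id[i]
    key <- paste(strain, exp, sep = ".")
    cc <- contrast_of(strain, exp)
    contrasts[[key]] <- cc
    set1 <- filter1(cc, th$fc_cut, th$p_cut)
    a <- annotate_filter1(set1, control_ref, cc, complex_ref)
    set2 <- if (cfg$filter1_only) NULL else
      filter2(a, th$ratio_cut, th$remove_above_control_fc)
    f1[[key]] <- set1; f2[[key]] <- set2; ann[[key]] <- a

    bait_info <- cfg$baits[[strain]]
    qc_rows[[key]] <- qc_report(cc, matrix, strain, exp,
                                carboxylase_set = carb_ref,
                                tissue_reference = tissue_ref,
                                bait_protein = bait_info$bait,
                                partners = bait_info$partners,
                                filtered_set = set2 %||% set1,
                                fc_cut = th$fc_cut, p_cut = th$p_cut)
    if (!is.null(out_dir)) {
      rec <- annotate_records(cc, a, set1, set2 %||% character(0))
      if (cfg$filter1_only) rec$filter2_pass <- NA
      path <- file.path(out_dir, sprintf("enrichment_%s.csv", safe_name(key)))
      write_annotated_table(rec, path)
      files[[basename(path)]] <- nrow(rec)
    }
  }

  qc <- do.call(rbind, c(qc_rows, list(make.row.names = FALSE)))
  filter_counts <- data.frame(strain_label = bait_pairs$strain_label,
                              experiment_id = bait_pairs$experiment_id,
                              filter1_count = lengths(f1),
                              filter2_count = if (cfg$filter1_only) NA_integer_
                                              else lengths(f2),
                              row.names = NULL, stringsAsFactors = FALSE)
  summary_tab <- summarize_study(qc, filter_counts)

  occurrence <- list()
  for (strain in unique(bait_pairs$strain_label)) {
    keys <- paste(strain, bait_pairs$experiment_id[bait_pairs$strain_label == strain],
                  sep = ".")
    sets <- if (cfg$filter1_only) f1[keys] else f2[keys]
    names(sets) <- sub("^.*\\.", "", keys)
    if (length(sets) >= 2) occurrence[[strain]] <- occurrence_frequency(sets)
  }

  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "qc_summary.csv")
    utils::write.table(summary_tab, p, sep = ",", row.names = FALSE, quote = FALSE, na = "")
    files[[basename(p)]] <- nrow(summary_tab)
    if (!is.null(control_ref)) {
      p <- file.path(out_dir, "control_reference.csv")
      utils::write.table(control_ref, p, sep = ",", row.names = FALSE, quote = FALSE, na = "")
      files[[basename(p)]] <- nrow(control_ref)
    }
    for (strain in names(occurrence)) {
      p <- file.path(out_dir, sprintf("occurrence_%s.csv", safe_name(strain)))
      utils::write.table(occurrence[[strain]]$table, p, sep = ",", row.names = FALSE,
                         quote = FALSE, na = "")
      files[[basename(p)]] <- nrow(occurrence[[strain]]$table)
    }
  }
  manifest <- list(files = files, thresholds = th,
                   filter1_only = cfg$filter1_only,
                   n_contrasts = length(contrasts),
                   n_control_contrasts = length(control_contrasts))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

  res <- list(contrasts = contrasts, filter1 = f1, filter2 = f2,
              annotations = ann, control_reference = control_ref,
              qc = qc, summary = summary_tab, occurrence = occurrence,
              manifest = manifest)
  class(res) <- "pl_study"
  invisible(res)
}

#' @export
print.pl_study <- function(x, ...) {
  cat(sprintf("<pl_study> %d bait contrasts, %d control contrasts\n",
              x$manifest$n_contrasts, x$manifest$n_control_contrasts))
  print(x$summary[, intersect(c("strain_label", "experiment_id", "up_count",
                                "down_count", "up_percent", "turboid_percent",
                                "carboxylase_percent", "filter1_count",
                                "filter2_count"), names(x$summary))])
  invisible(x)
}

#' Study-level metric summary
#'
#' One row per (strain, experiment) bait sample combining the QC metric
#' panel with the first- and second-stage retained counts; estimated bait
#' fold changes are marked with an asterisk flag. Study-level mean, SD and
#' range of the filter counts are attached as the `"study_stats"` attribute
#' (SD is empty with a single contrast).
#'
#' @param qc_rows data.frame of [qc_report()] rows.
#' @param filter_counts data.frame with `strain_label`, `experiment_id`,
#'   `filter1_count`, `filter2_count`.
#' @return merged data.frame with attribute `study_stats`.
#' @export
summarize_study <- function(qc_rows, filter_counts) {
  out <- merge(as.data.frame(qc_rows), filter_counts,
               by = c("strain_label", "experiment_id"), sort = TRUE)
  out$bait_fc_flag <- ifelse(!is.na(out$bait_fc_estimated) & out$bait_fc_estimated,
                             "*", "")
  stats_of <- function(v) {
    v <- v[!is.na(v)]
    list(mean = if (length(v)) mean(v) else NA_real_,
         sd = if (length(v) > 1) stats::sd(v) else NA_real_,
         min = if (length(v)) min(v) else NA_real_,
         max = if (length(v)) max(v) else NA_real_,
         n = length(v))
  }
  attr(out, "study_stats") <- list(filter1 = stats_of(out$filter1_count),
                                   filter2 = stats_of(out$filter2_count))
  out
}

#' Volcano-style tabular export of one contrast
#'
#' @param contrast a `pl_contrast`.
#' @param path optional output CSV.
#' @return data.frame `protein_id`, `log2_fc`, `neg_log10_adj_p`,
#'   `detection_category`.
#' @export
volcano_export <- function(contrast, path = NULL) {
  df <- data.frame(protein_id = contrast$protein_id,
                   log2_fc = contrast$log2_fc,
                   neg_log10_adj_p = -log10(contrast$adj_p),
                   detection_category = contrast$detection_category,
                   stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE, na = "")
  df
}
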