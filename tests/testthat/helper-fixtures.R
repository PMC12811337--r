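# Fixture builders shared across test files. Everything is generated in
# code; no data files are read from disk except ones a test writes itself.

`%||%` <- function(a, b) if (is.null(a)) b else a
in_reference <- proxifilt:::in_reference

# sample sheet for one experiment: one bait strain, one negative control,
# optionally a nonspecific-control strain, `reps` technical replicates each
toy_samples <- function(reps = 3, experiment = "Exp1", bait = "BAIT::TurboID",
                        nonspecific = NULL) {
  strains <- c(bait, "N2", nonspecific)
  roles <- c("bait", "negative_control",
             if (!is.null(nonspecific)) "nonspecific_control")
  do.call(rbind, lapply(seq_along(strains), function(i) {
    data.frame(run_id = sprintf("%s_%s_r%d", gsub("[^A-Za-z0-9]", "", strains[i]),
                                experiment, seq_len(reps)),
               strain_label = strains[i], experiment_id = experiment,
               replicate_index = seq_len(reps), role = roles[i],
               stringsAsFactors = FALSE)
  }))
}

# matrix from an explicit value table: `bait` and `ctrl` are matrices or
# vectors (proteins x reps) on the linear scale, NA = not detected
toy_matrix <- function(bait, ctrl, protein_ids = NULL, reps = NULL,
                       experiment = "Exp1") {
  bait <- as.matrix(bait); ctrl <- as.matrix(ctrl)
  stopifnot(nrow(bait) == nrow(ctrl))
  reps <- reps %||% ncol(bait)
  s <- toy_samples(reps = max(ncol(bait), ncol(ctrl)), experiment = experiment)
  ids <- protein_ids %||% sprintf("P%03d", seq_len(nrow(bait)))
  vals <- cbind(bait, ctrl)
  colnames(vals) <- c(s$run_id[s$role == "bait"][seq_len(ncol(bait))],
                      s$run_id[s$role == "negative_control"][seq_len(ncol(ctrl))])
  rownames(vals) <- ids
  pl_matrix(vals, s[s$run_id %in% colnames(vals), ])
}

bait_runs_of <- function(mat) run_ids(mat, role = "bait")
ctrl_runs_of <- function(mat) run_ids(mat, role = "negative_control")

# hand-built enrichment record table with pl_contrast attributes, for tests
# that exercise downstream modules on exactly specified statistics
make_records <- function(protein_id, fold_change = NA_real_, adj_p = NA_real_,
                         n_detected_bait = 3L, n_detected_control = 3L,
                         n_bait_runs = 3L, n_control_runs = 3L,
                         fc_is_estimate = FALSE, detection_category = "both",
                         bait_mean = NA_real_, control_mean = NA_real_,
                         p_value = NULL) {
  n <- length(protein_id)
  df <- data.frame(protein_id = protein_id,
                   bait_mean = rep_len(bait_mean, n),
                   control_mean = rep_len(control_mean, n),
                   n_detected_bait = rep_len(as.integer(n_detected_bait), n),
                   n_detected_control = rep_len(as.integer(n_detected_control), n),
                   fold_change = rep_len(fold_change, n),
                   log2_fc = log2(rep_len(fold_change, n)),
                   p_value = rep_len(p_value %||% adj_p, n),
                   adj_p = rep_len(adj_p, n),
                   fc_is_estimate = rep_len(fc_is_estimate, n),
                   detection_category = rep_len(detection_category, n),
                   stringsAsFactors = FALSE)
  structure(df, n_bait_runs = as.integer(n_bait_runs),
            n_control_runs = as.integer(n_control_runs),
            test = "welch", class = c("pl_contrast", "data.frame"))
}

# independent Benjamini-Hochberg step-up oracle: literal definition, kept
# free of p.adjust so the two routes stay independent
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# small simulated study reused by several files
small_sim <- function(seed = 7, n_experiments = 1, ...) {
  simulate_study(sim_config(n_proteins = 300, n_promiscuous = 15,
                            strains = list(list(name = "B1::TurboID", bait = "B1",
                                                cis_fc = 100,
                                                partners = c("P1" = 16, "P2" = 12),
                                                expression = 1)),
                            n_experiments = n_experiments, seed = seed, ...))
}
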