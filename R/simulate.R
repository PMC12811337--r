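#' Configuration for a synthetic proximity-labeling study
#'
#' Defines the generative model used by [simulate_study()]. Protein
#' abundances are log-normal on the log2 scale; a handful of endogenously
#' biotinylated carboxylases sit far above the bulk; each bait strain adds
#' cis enrichment to its own bait protein and trans enrichment to its
#' complex partners; a reproducible promiscuous-target set is enriched in
#' every ligase-bearing strain including the non-targeted control; all other
#' proteins form the sticky (non-biotinylated) background, present in every
#' run at a contamination-scaled intensity. Technical-replicate noise is
#' multiplicative log-normal, experiments carry batch shifts on a random
#' protein subset, and intensities below the detection floor are recorded as
#' not detected.
#'
#' @param n_proteins total proteins in the simulated proteome (default 3000).
#' @param n_carboxylases carboxylase count (default 4, ids PYC-1, PCCA-1,
#'   MCCC-1, POD-2).
#' @param baseline_log2_mean,baseline_log2_sd log2-abundance distribution of
#'   the bulk proteome (defaults 16, 2).
#' @param carboxylase_multiplier linear abundance multiplier for the
#'   carboxylases (default 100).
#' @param strains list of bait strain specs, each a list with `name`,
#'   `bait` (protein id), `cis_fc` (linear self-labeling fold change),
#'   `partners` (named numeric, partner id -> linear trans fold change) and
#'   `expression` (multiplier on cis and trans effects, default 1).
#' @param nonspecific_strain,negative_strain strain labels for the
#'   promiscuous-ligase control and the no-ligase control.
#' @param n_promiscuous size of the reproducible promiscuous-target set
#'   (default 40).
#' @param promiscuous_fc_range linear fold-change range of promiscuous
#'   enrichment, sampled log-uniformly (default `c(2, 132)`).
#' @param contamination_fraction intensity scale of non-biotin-captured
#'   (sticky) protein in every run, applied to every protein except the
#'   carboxylases (default 0.25; 0 removes unlabeled presence entirely).
#' @param sticky_noise_sd_log2 sd of the sample-level stickiness shift of
#'   background proteins, applied per (protein, strain, experiment) and
#'   scaled by the contamination fraction (default 2). This is what lets a
#'   dirty pulldown show spurious, replicate-consistent enrichment in either
#'   direction -- including in the no-ligase control.
#' @param compositional rescale every run to a common total intensity
#'   (default `FALSE`), emulating relative quantification within an
#'   experiment: runs loaded with strongly enriched biotinylated protein
#'   show correspondingly depressed background signal, including the
#'   reversed asymmetry seen with highly expressed non-targeted controls.
#' @param detection_floor_log2 log2 intensity below which a measurement is
#'   not detected (default 12).
#' @param noise_sd_log2 per-measurement log2 noise sd (default 0.2).
#' @param batch_sd_log2 sd of the per-experiment batch shift (default 1).
#' @param batch_fraction fraction of proteins carrying a batch shift in each
#'   experiment (default 0.15).
#' @param n_technical_replicates runs per strain per experiment (default 3).
#' @param n_experiments biological replicates (default 2).
#' @param control_experiments experiments that include the non-specific
#'   control strain (default all).
#' @param seed integer seed; the whole study is reproducible given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_proteins = 3000,
                       n_carboxylases = 4,
                       baseline_log2_mean = 16,
                       baseline_log2_sd = 2,
                       carboxylase_multiplier = 100,
                       strains = list(
                         list(name = "BAIT-1::TurboID", bait = "BAIT-1",
                              cis_fc = 100,
                              partners = c("PART-1" = 16, "PART-2" = 12),
                              expression = 1),
                         list(name = "BAIT-2::TurboID", bait = "BAIT-2",
                              cis_fc = 50,
                              partners = c("PART-1" = 8, "PART-3" = 16),
                              expression = 1)),
                       nonspecific_strain = "mNG::TurboID",
                       negative_strain = "N2",
                       n_promiscuous = 40,
                       promiscuous_fc_range = c(2, 132),
                       contamination_fraction = 0.25,
                       sticky_noise_sd_log2 = 2,
                       compositional = FALSE,
                       detection_floor_log2 = 12,
                       noise_sd_log2 = 0.2,
                       batch_sd_log2 = 1,
                       batch_fraction = 0.15,
                       n_technical_replicates = 3,
                       n_experiments = 2,
                       control_experiments = seq_len(n_experiments),
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_proteins > 0, n_carboxylases >= 0, n_promiscuous >= 0,
            n_technical_replicates >= 2, n_experiments >= 1,
            contamination_fraction >= 0, contamination_fraction <= 1,
            batch_fraction >= 0, batch_fraction <= 1,
            noise_sd_log2 >= 0, batch_sd_log2 >= 0, sticky_noise_sd_log2 >= 0,
            length(promiscuous_fc_range) == 2,
            all(promiscuous_fc_range > 0))
  for (s in strains) {
    stopifnot(is.character(s$name), is.character(s$bait), s$cis_fc > 0)
    if (length(s$partners)) stopifnot(all(s$partners > 0), !is.null(names(s$partners)))
  }
  class(cfg) <- "sim_config"
  cfg
}

local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a complete synthetic study
#'
#' Produces an intensity matrix with its sample sheet and a ground-truth
#' description, in exactly the shapes the rest of the package consumes, so
#' the full pipeline can be exercised and scored without any external data.
#' Deterministic given `config$seed`: the same configuration yields a
#' bit-identical study.
#'
#' Only the endogenously biotinylated carboxylases are captured at full
#' strength in every sample. Every other protein enters a pulldown at a
#' contamination-scaled sticky level, plus its planted enrichment (cis,
#' trans, or promiscuous) in the strains that label it; enriched levels are
#' floored a margin above the detection limit so the planted signal is
#' observable by construction. In a clean study genuine targets are
#' therefore invisible in the negative control (detected on the ligase side
#' only); rising contamination makes them control-visible and adds
#' control-exclusive sticky detections, which is what drives the quality
#' metrics down.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a `pl_matrix`), `samples` (the sample
#'   sheet), and `truth` (list: `classes` data.frame of protein_id/class,
#'   `strains` echo of the strain specs, `promiscuous_fc` named vector,
#'   `batch_members` logical matrix proteins x experiments, `config`).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    baits <- vapply(config$strains, `[[`, character(1), "bait")
    partners <- unique(unlist(lapply(config$strains, function(s) names(s$partners))))
    partners <- setdiff(partners, baits)
    carbs <- c("PYC-1", "PCCA-1", "MCCC-1", "POD-2",
               sprintf("CARB-%d", seq_len(max(0, config$n_carboxylases - 4))))
    carbs <- carbs[seq_len(config$n_carboxylases)]
    proms <- sprintf("PROM-%03d", seq_len(config$n_promiscuous))
    n_special <- length(baits) + length(partners) + length(carbs) + length(proms)
    if (n_special >= config$n_proteins)
      stop("n_proteins too small for the configured special classes", call. = FALSE)
    bgs <- sprintf("BG-%04d", seq_len(config$n_proteins - n_special))
    ids <- c(baits, partners, carbs, proms, bgs)
    cls <- c(rep("bait", length(baits)), rep("complex_partner", length(partners)),
             rep("carboxylase", length(carbs)), rep("promiscuous", length(proms)),
             rep("background", length(bgs)))
    n <- length(ids)
    floor_log2 <- config$detection_floor_log2

    prom_fc <- 2^stats::runif(length(proms),
                              log2(config$promiscuous_fc_range[1]),
                              log2(config$promiscuous_fc_range[2]))
    names(prom_fc) <- proms

    base <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    names(base) <- ids
    # carboxylases are endogenously biotinylated: captured at full strength
    # in every sample regardless of how dirty the pulldown is
    base[carbs] <- pmax(base[carbs], floor_log2 + 2) + log2(config$carboxylase_multiplier)
    # promiscuous targets are at least averagely abundant proteins
    base[proms] <- pmax(base[proms], config$baseline_log2_mean)
    # everything not biotin-captured enters a pulldown only as sticky
    # background, at a contamination-scaled level; this is what makes
    # genuine targets invisible in the negative control of a clean study
    # and progressively visible there as contamination rises
    nonbiotin <- c(baits, partners, proms, bgs)
    base[nonbiotin] <- base[nonbiotin] + log2(config$contamination_fraction)
    # enriched classes must be observable once labeled
    if (length(proms))
      base[proms] <- pmax(base[proms], floor_log2 + 2 - log2(prom_fc))
    for (s in config$strains) {
      base[s$bait] <- pmax(base[s$bait], floor_log2 + 2 - log2(s$cis_fc))
      for (p in names(s$partners))
        base[p] <- pmax(base[p], floor_log2 + 2 - log2(s$partners[[p]]))
    }

    # per-strain log2 effects, identical across experiments
    ligase_strains <- c(vapply(config$strains, `[[`, character(1), "name"),
                        config$nonspecific_strain)
    effects <- matrix(0, n, length(ligase_strains),
                      dimnames = list(ids, ligase_strains))
    effects[proms, ] <- log2(prom_fc)
    for (s in config$strains) {
      effects[s$bait, s$name] <- effects[s$bait, s$name] + log2(s$cis_fc * (s$expression %||% 1))
      for (p in names(s$partners))
        effects[p, s$name] <- effects[p, s$name] + log2(s$partners[[p]] * (s$expression %||% 1))
    }

    batch_members <- matrix(FALSE, n, config$n_experiments,
                            dimnames = list(ids, NULL))
    batch_shift <- matrix(0, n, config$n_experiments)
    for (e in seq_len(config$n_experiments)) {
      m <- sample.int(n, round(config$batch_fraction * n))
      batch_members[m, e] <- TRUE
      batch_shift[m, e] <- stats::rnorm(length(m), 0, config$batch_sd_log2)
    }

    target_total <- sum(2^base)
    sticky_sd <- config$sticky_noise_sd_log2 * config$contamination_fraction
    sheets <- list(); cols <- list()
    for (e in seq_len(config$n_experiments)) {
      strain_names <- c(config$negative_strain,
                        vapply(config$strains, `[[`, character(1), "name"),
                        if (e %in% config$control_experiments) config$nonspecific_strain)
      roles <- c("negative_control",
                 rep("bait", length(config$strains)),
                 if (e %in% config$control_experiments) "nonspecific_control")
      for (si in seq_along(strain_names)) {
        st <- strain_names[si]
        eff <- if (st %in% colnames(effects)) effects[, st] else rep(0, n)
        # stickiness is a property of the pulldown sample: consistent across
        # the technical replicates of one (strain, experiment)
        sticky <- rep(0, n)
        if (length(bgs) && sticky_sd > 0)
          sticky[match(bgs, ids)] <- stats::rnorm(length(bgs), 0, sticky_sd)
        for (r in seq_len(config$n_technical_replicates)) {
          run <- sprintf("%s.Exp%d.r%d", gsub("[^A-Za-z0-9_.-]", "_", st), e, r)
          noise <- stats::rnorm(n, 0, config$noise_sd_log2)
          l2 <- base + eff + batch_shift[, e] + sticky + noise
          v <- 2^l2
          if (config$compositional) v <- v * (target_total / sum(v))
          v[log2(v) < floor_log2] <- NA_real_
          v[is.nan(v)] <- NA_real_
          cols[[run]] <- v
          sheets[[run]] <- data.frame(run_id = run, strain_label = st,
                                      experiment_id = sprintf("Exp%d", e),
                                      replicate_index = r, role = roles[si],
                                      stringsAsFactors = FALSE)
        }
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- ids
    samples <- do.call(rbind, sheets)
    rownames(samples) <- NULL
    mat <- pl_matrix(values, samples)
    truth <- list(classes = data.frame(protein_id = ids, class = cls,
                                       stringsAsFactors = FALSE),
                  strains = config$strains,
                  promiscuous_fc = prom_fc,
                  batch_members = batch_members,
                  config = config)
    list(matrix = mat, samples = samples, truth = truth)
  })
}

#' Score a filtered candidate set against the simulation ground truth
#'
#' Sensitivity is the fraction of planted complex partners (of one strain,
#' or of any strain when `strain = NULL`) present in the retained set;
#' the false-discovery proportions are the fractions of the retained set
#' belonging to the promiscuous and background classes.
#'
#' @param truth `truth` element of [simulate_study()] output.
#' @param filter2_set retained protein ids.
#' @param strain optional strain name restricting the partner universe.
#' @return list `sensitivity`, `fdp_promiscuous`, `fdp_background`,
#'   `n_retained`.
#' @export
evaluate_recovery <- function(truth, filter2_set, strain = NULL) {
  specs <- truth$strains
  if (!is.null(strain)) specs <- Filter(function(s) s$name == strain, specs)
  partners <- unique(unlist(lapply(specs, function(s) names(s$partners))))
  set_lc <- tolower(filter2_set)
  sens <- if (length(partners)) mean(tolower(partners) %in% set_lc) else NA_real_
  cls <- truth$classes$class[match(set_lc, tolower(truth$classes$protein_id))]
  nr <- length(filter2_set)
  list(sensitivity = sens,
       fdp_promiscuous = if (nr) mean(cls == "promiscuous", na.rm = TRUE) else 0,
       fdp_background = if (nr) mean(cls == "background", na.rm = TRUE) else 0,
       n_retained = nr)
}
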