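#' Occurrence frequency of candidates across biological replicates
#'
#' Counts, for each protein in the union of per-experiment candidate sets,
#' how many experiments it appeared in, and summarizes the counts as a
#' frequency histogram. Independent biological replicates of the same bait
#' typically share only a small core, so the histogram is dominated by
#' singletons.
#'
#' @param filter_sets named list (>= 2 entries) of per-experiment protein id
#'   vectors, usually second-stage filtered sets.
#' @return list with `table` (data.frame: `protein_id`, `occurrence_count`,
#'   `experiments` comma-joined), `histogram` (named integer vector: how
#'   many proteins occur in exactly 1, 2, ... experiments) and `n` (union
#'   size). The histogram sums to `n`.
#' @export
occurrence_frequency <- function(filter_sets) {
  if (length(filter_sets) < 2) stop("need >= 2 experiments", call. = FALSE)
  if (is.null(names(filter_sets)))
    names(filter_sets) <- paste0("Exp", seq_along(filter_sets))
  long <- data.frame(
    id = tolower(unlist(filter_sets, use.names = FALSE)),
    disp = unlist(filter_sets, use.names = FALSE),
    exp = rep(names(filter_sets), lengths(filter_sets)),
    stringsAsFactors = FALSE)
  long <- long[!duplicated(paste(long$id, long$exp)), ]
  counts <- tapply(long$exp, long$id, function(e) length(unique(e)))
  exps <- tapply(long$exp, long$id, function(e) paste(sort(unique(e)), collapse = ","))
  disp <- long$disp[!duplicated(long$id)]
  names(disp) <- long$id[!duplicated(long$id)]
  ids <- names(counts)
  tab <- data.frame(protein_id = unname(disp[ids]),
                    occurrence_count = as.integer(counts),
                    experiments = unname(exps[ids]),
                    stringsAsFactors = FALSE, row.names = NULL)
  hist <- table(factor(tab$occurrence_count, levels = seq_along(filter_sets)))
  list(table = tab,
       histogram = stats::setNames(as.integer(hist), names(hist)),
       n = nrow(tab))
}

#' Batch-effect decomposition of all-replicate detection sets
#'
#' Takes, for several (strain, experiment) samples, the set of proteins
#' detected in every technical replicate of that sample (irrespective of
#' fold change) and decomposes the union into Venn regions. Proteins shared
#' by different strains of the same experiment but absent from other
#' experiments indicate batch effects. When an enrichment lookup is given,
#' each region additionally reports the fraction of its proteins with fold
#' change above `fc_cut` in the bait contrast; for regions spanning several
#' experiments the maximum across those experiments is reported.
#'
#' @param detection_sets named list of protein id vectors, one per
#'   (strain, experiment) sample; names like `"NEKL-3.Exp1"`.
#' @param enrichment_lookup optional named list: experiment id -> named
#'   numeric vector of bait fold changes per protein.
#' @param set_experiments optional character vector giving the experiment id
#'   of each detection set (defaults to the text after the last "." in the
#'   set name).
#' @param fc_cut fold-change threshold for the per-region fraction.
#' @return data.frame with one row per occupied region: `pattern`, `count`,
#'   and `frac_up` when a lookup is supplied. Region counts sum to the union
#'   size.
#' @export
batch_overlap <- function(detection_sets, enrichment_lookup = NULL,
                          set_experiments = NULL, fc_cut = 2) {
  if (length(detection_sets) < 2) stop("need >= 2 detection sets", call. = FALSE)
  if (is.null(set_experiments))
    set_experiments <- sub("^.*\\.", "", names(detection_sets))
  ids <- unique(tolower(unlist(detection_sets)))
  member <- sapply(detection_sets, function(s) ids %in% tolower(s))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  out <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(out) <- c("pattern", "count")
  if (!is.null(enrichment_lookup)) {
    out$frac_up <- vapply(out$pattern, function(p) {
      in_region <- ids[pattern == p]
      sets_in <- which(strsplit(p, "")[[1]] == "1")
      exps <- unique(set_experiments[sets_in])
      fracs <- vapply(exps, function(e) {
        fc <- enrichment_lookup[[e]]
        if (is.null(fc)) return(NA_real_)
        names(fc) <- tolower(names(fc))
        mean(!is.na(fc[in_region]) & fc[in_region] > fc_cut)
      }, numeric(1))
      if (all(is.na(fracs))) NA_real_ else max(fracs, na.rm = TRUE)
    }, numeric(1))
  }
  out
}

#' Proteins detected in every technical replicate of a sample
#' @param mat a `pl_matrix`.
#' @param runs run ids of the sample.
#' @return character vector of protein ids.
#' @export
detected_in_all <- function(mat, runs) {
  check_runs(mat, runs)
  nd <- n_detected(mat, runs)
  names(nd)[nd == length(runs)]
}

#' Pairwise Jaccard overlap of term lists
#'
#' For each pair of named sets (e.g. GO term lists of different baits):
#' shared-element count and Jaccard index |A n B| / |A u B|. Jaccard is `NA`
#' for pairs involving an empty set.
#'
#' @param term_lists named list (>= 2) of character vectors.
#' @return list of matrices `shared` (integer) and `jaccard` (numeric),
#'   both symmetric with unit diagonal for non-empty sets.
#' @export
term_set_jaccard <- function(term_lists) {
  if (length(term_lists) < 2) stop("need >= 2 lists", call. = FALSE)
  k <- length(term_lists)
  nm <- names(term_lists) %||% paste0("set", seq_len(k))
  sets <- lapply(term_lists, unique)
  shared <- matrix(0L, k, k, dimnames = list(nm, nm))
  jac <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    shared[i, j] <- inter
    jac[i, j] <- if (uni > 0) inter / uni else NA_real_
  }
  list(shared = shared, jaccard = jac)
}
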