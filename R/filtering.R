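#' First-stage retention filter for one bait contrast
#'
#' Retains proteins with at least `fc_cut`-fold enrichment over the negative
#' control, adjusted p at most `p_cut`, and detection in every bait
#' technical replicate; plus, irrespective of any test, proteins detected in
#' all bait replicates and in no control replicate (the bait-exclusive
#' class, which includes baits or partners never seen in the control).
#' Proteins detected in only a strict subset of the bait replicates are
#' excluded here but keep their category in the output table.
#'
#' @param records a `pl_contrast`.
#' @param fc_cut linear fold-change cutoff (default 2).
#' @param p_cut adjusted-p cutoff (default 0.05).
#' @return character vector of retained protein ids.
#' @export
filter1 <- function(records, fc_cut = 2, p_cut = 0.05) {
  Rb <- attr(records, "n_bait_runs")
  if (is.null(Rb)) Rb <- max(records$n_detected_bait)
  tested <- !records$fc_is_estimate &
    !is.na(records$fold_change) & !is.na(records$adj_p) &
    records$fold_change >= fc_cut & records$adj_p <= p_cut &
    records$n_detected_bait == Rb
  exclusive <- records$detection_category == "bait_only"
  records$protein_id[tested | exclusive]
}

#' Build the non-specific-target reference from promiscuous-ligase controls
#'
#' Merges one or more contrasts of a freely expressed ligase control strain
#' against the negative control into a per-protein reference of likely
#' non-bait-specific biotinylation targets. Entries fall into four buckets:
#' \describe{
#'   \item{enriched_both}{significant (adjusted p <= `p_cut`) with fold
#'     change >= `fc_cut` in every contrast and detected in all ligase
#'     replicates of every contrast; `control_fc` is the arithmetic mean of
#'     the per-contrast linear fold changes.}
#'   \item{enriched_single_<name>}{fold change >= `fc_cut`, significant, and
#'     detected in all ligase replicates of that contrast while absent from
#'     the negative-control runs of every other contrast; `control_fc` is
#'     the single available fold change.}
#'   \item{control_only}{detected in all ligase replicates of every contrast
#'     but in no negative-control replicate anywhere; no fold change
#'     exists.}
#' }
#' With two control experiments these buckets reproduce the published
#' two-experiment assembly; with k >= 3 "both" means all and "single" means
#' exactly one, a documented extension.
#'
#' @param control_contrasts named list of `pl_contrast` objects (ligase
#'   control vs negative control), one per control experiment.
#' @param fc_cut,p_cut admission thresholds (defaults 2, 0.05).
#' @return data.frame with columns `protein_id`, `category`, `control_fc`;
#'   `control_fc` is `NA` only for `control_only` entries.
#' @export
build_control_reference <- function(control_contrasts, fc_cut = 2, p_cut = 0.05) {
  if (!length(control_contrasts)) stop("need >= 1 control contrast", call. = FALSE)
  if (is.null(names(control_contrasts)) || any(!nzchar(names(control_contrasts))))
    names(control_contrasts) <- letters[seq_along(control_contrasts)]
  k <- length(control_contrasts)
  ids <- sort(unique(tolower(unlist(lapply(control_contrasts, `[[`, "protein_id")))))
  # canonical display id: first occurrence
  disp <- character(0)
  for (cc in control_contrasts) {
    new <- !(tolower(cc$protein_id) %in% names(disp))
    disp <- c(disp, stats::setNames(cc$protein_id[new], tolower(cc$protein_id[new])))
  }

  per <- lapply(control_contrasts, function(cc) {
    Rb <- attr(cc, "n_bait_runs")
    i <- match(ids, tolower(cc$protein_id))
    list(fc = cc$fold_change[i],
         est = ifelse(is.na(i), NA, cc$fc_is_estimate[i]),
         adj = cc$adj_p[i],
         full_ligase = ifelse(is.na(i), FALSE, cc$n_detected_bait[i] == Rb),
         absent_neg = ifelse(is.na(i), TRUE, cc$n_detected_control[i] == 0))
  })

  sig <- sapply(per, function(x)
    !is.na(x$fc) & !isTRUE_vec(x$est) & !is.na(x$adj) & x$fc >= fc_cut & x$adj <= p_cut)
  full <- sapply(per, `[[`, "full_ligase")
  absent <- sapply(per, `[[`, "absent_neg")
  fcs <- sapply(per, `[[`, "fc")
  if (is.null(dim(sig))) { # single protein edge case
    sig <- matrix(sig, nrow = 1); full <- matrix(full, nrow = 1)
    absent <- matrix(absent, nrow = 1); fcs <- matrix(fcs, nrow = 1)
  }

  category <- rep(NA_character_, length(ids))
  control_fc <- rep(NA_real_, length(ids))

  both <- rowSums(sig) == k & rowSums(full) == k
  category[both] <- "enriched_both"
  control_fc[both] <- rowMeans(fcs, na.rm = TRUE)[both]

  for (j in seq_len(k)) {
    # admission demands full ligase detection in the significant contrast;
    # elsewhere the protein only needs to miss the negative controls
    single <- is.na(category) & sig[, j] & full[, j] &
      (if (k > 1) rowSums(absent[, -j, drop = FALSE]) == k - 1 else TRUE)
    category[single] <- paste0("enriched_single_", names(control_contrasts)[j])
    control_fc[single] <- fcs[single, j]
  }

  conly <- is.na(category) & rowSums(full) == k & rowSums(absent) == k
  category[conly] <- "control_only"

  keep <- !is.na(category)
  data.frame(protein_id = unname(disp[ids[keep]]),
             category = category[keep],
             control_fc = control_fc[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Ratio of bait enrichment to control enrichment
#'
#' For a protein enriched in both a bait sample and the promiscuous-ligase
#' control, the ratio of the two linear fold changes (each versus the shared
#' negative control). Ratios well above 1 indicate bait-specific labeling on
#' top of the promiscuous background; ratios near or below 1 suggest a
#' non-specific target.
#'
#' @param bait_fc,control_fc positive linear fold changes.
#' @return `bait_fc / control_fc`.
#' @export
bait_control_ratio <- function(bait_fc, control_fc) bait_fc / control_fc

color_from_control_fc <- function(control_fc, category) {
  ifelse(category == "control_only", "gray",
  ifelse(is.na(control_fc), "white",
  ifelse(control_fc > 10, "red",
  ifelse(control_fc > 5, "orange",
  ifelse(control_fc >= 2, "yellow", "white")))))
}

#' Annotate a first-stage candidate set against the control reference
#'
#' Assigns each retained protein a color label from its fold change in the
#' promiscuous-ligase control: red for control fold change > 10, orange for
#' (5, 10], yellow for \[2, 5\], gray for proteins seen only in the ligase
#' control (no fold change exists), white for proteins below 2-fold or
#' absent from the reference, and green for members of the bait's own
#' complex. Boundary values 10 and 5 fall in the lower-severity bucket. Also
#' computes the bait-to-control fold-change ratio where both fold changes
#' exist; for bait-exclusive proteins the estimated fold change is used.
#'
#' @param filter1_set protein ids retained by [filter1()].
#' @param control_reference data.frame from [build_control_reference()]
#'   (may be `NULL` for annotation-free mode: everything non-green is white).
#' @param records the bait `pl_contrast` (source of bait fold changes).
#' @param complex_members optional reference set of bait-complex proteins.
#' @return data.frame with columns `protein_id`, `color`, `control_fc`,
#'   `control_category`, `bait_control_ratio`.
#' @export
annotate_filter1 <- function(filter1_set, control_reference, records,
                             complex_members = NULL) {
  ids <- filter1_set
  if (is.null(control_reference)) {
    ref_idx <- rep(NA_integer_, length(ids))
  } else {
    ref_idx <- match(tolower(ids), tolower(control_reference$protein_id))
  }
  category <- ifelse(is.na(ref_idx), NA_character_, control_reference$category[ref_idx])
  control_fc <- ifelse(is.na(ref_idx), NA_real_, control_reference$control_fc[ref_idx])
  color <- color_from_control_fc(control_fc,
                                 ifelse(is.na(category), "none", category))
  green <- in_reference(ids, complex_members)
  conflict <- green & !is.na(ref_idx)
  if (any(conflict))
    warning("complex member(s) also present in the control reference: ",
            paste(ids[conflict], collapse = ", "), call. = FALSE)
  color[green] <- "green"

  rec_idx <- match(tolower(ids), tolower(records$protein_id))
  bait_fc <- records$fold_change[rec_idx]
  ratio <- ifelse(!is.na(bait_fc) & !is.na(control_fc),
                  bait_control_ratio(bait_fc, control_fc), NA_real_)
  data.frame(protein_id = ids, color = color,
             control_fc = control_fc,
             control_category = category,
             bait_control_ratio = ratio,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Second-stage removal of control-enriched proteins
#'
#' Applied to a first-stage candidate set with its annotations. Removes
#' every protein enriched more than `remove_above_control_fc`-fold in the
#' promiscuous-ligase control (the red and orange labels at the default
#' cutoff of 5), and every protein in the \[2, `remove_above_control_fc`\]
#' band (yellow) whose bait-to-control fold-change ratio is below
#' `ratio_cut`. Proteins detected only in the ligase control (gray) are
#' retained but stay flagged, as are complex members (green) and proteins
#' with no control enrichment (white). Operating on the numeric control fold
#' change rather than frozen labels makes retention monotone in both
#' thresholds.
#'
#' @param annotations data.frame from [annotate_filter1()].
#' @param ratio_cut minimum bait-to-control ratio for yellow-band proteins
#'   (default 1.5).
#' @param remove_above_control_fc control fold change above which proteins
#'   are removed outright (default 5).
#' @return character vector of retained protein ids (a subset of the
#'   first-stage set).
#' @export
filter2 <- function(annotations, ratio_cut = 1.5, remove_above_control_fc = 5) {
  a <- annotations
  green <- a$color == "green"
  cf <- a$control_fc
  high <- !green & !is.na(cf) & cf > remove_above_control_fc
  band <- !green & !is.na(cf) & cf >= 2 & cf <= remove_above_control_fc
  low_ratio <- band & !is.na(a$bait_control_ratio) & a$bait_control_ratio < ratio_cut
  a$protein_id[!(high | low_ratio)]
}

#' Merge enrichment records with filter annotations into one table
#'
#' Produces the full annotated record set written by
#' [write_annotated_table()]: every protein of the contrast with its
#' statistics, plus control fold change, color, ratio and the two filter
#' flags (colors default to white outside the first-stage set).
#'
#' @param records a `pl_contrast`.
#' @param annotations data.frame from [annotate_filter1()].
#' @param filter1_set,filter2_set retained id vectors.
#' @return data.frame in the stable annotated-column order.
#' @export
annotate_records <- function(records, annotations, filter1_set, filter2_set) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  i <- match(tolower(df$protein_id), tolower(annotations$protein_id))
  df$control_fc <- annotations$control_fc[i]
  df$color <- ifelse(is.na(i), "white", annotations$color[i])
  df$bait_control_ratio <- annotations$bait_control_ratio[i]
  df$filter1_pass <- tolower(df$protein_id) %in% tolower(filter1_set)
  df$filter2_pass <- tolower(df$protein_id) %in% tolower(filter2_set)
  df[, ANNOTATED_COLUMNS]
}

#' Venn decomposition of candidate sets from several baits
#'
#' Region counts of the membership Venn diagram over two or more named
#' protein sets (e.g. the filtered sets of different baits in one
#' experiment), optionally with the color composition of each region.
#'
#' @param filter_sets named list of character vectors (>= 2).
#' @param colors optional named character vector protein id -> color.
#' @return data.frame with one row per non-empty-pattern region: `pattern`
#'   (binary membership string over sets in the given order), `count`, and
#'   one `n_<color>` column per color when colors are supplied.
#' @export
cross_bait_overlap <- function(filter_sets, colors = NULL) {
  if (length(filter_sets) < 2) stop("need >= 2 sets", call. = FALSE)
  ids <- unique(tolower(unlist(filter_sets)))
  member <- sapply(filter_sets, function(s) ids %in% tolower(s))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  out <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(out) <- c("pattern", "count")
  if (!is.null(colors)) {
    names(colors) <- tolower(names(colors))
    cl <- colors[ids]
    cl[is.na(cl)] <- "white"
    for (col in sort(unique(cl)))
      out[[paste0("n_", col)]] <- vapply(out$pattern, function(p)
        sum(pattern == p & cl == col), integer(1))
  }
  out
}
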