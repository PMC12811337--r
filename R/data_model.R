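#' Construct a protein intensity matrix
#'
#' The central container of the package: a numeric matrix of protein-level
#' intensities with one row per protein and one column per MS run, carrying
#' the sample sheet as an attribute. Not-detected measurements are stored as
#' `NA`; a stored intensity is always strictly positive. Zero is never used
#' to encode absence internally, because group means are taken over the
#' replicates in which a protein was detected and must skip absences rather
#' than average them in.
#'
#' @param values numeric matrix, proteins x runs; `NA` marks not-detected.
#' @param samples data.frame of run descriptors as returned by
#'   [read_sample_sheet()]; its `run_id` column must match `colnames(values)`.
#' @return an object of class `pl_matrix`.
#' @export
pl_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have protein row names and run column names", call. = FALSE)
  samples <- validate_sample_sheet(samples)
  ids <- normalize_ids(rownames(values))
  dup <- unique(ids[duplicated(tolower(ids))])
  if (length(dup))
    stop("duplicate protein identifiers after normalization: ",
         paste(dup, collapse = ", "), call. = FALSE)
  rownames(values) <- ids
  if (any(values <= 0, na.rm = TRUE))
    stop("intensities must be strictly positive; encode absence as NA", call. = FALSE)
  missing_runs <- setdiff(colnames(values), samples$run_id)
  if (length(missing_runs))
    stop("runs absent from sample sheet: ", paste(missing_runs, collapse = ", "),
         call. = FALSE)
  samples <- samples[match(colnames(values), samples$run_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(values, samples = samples, class = c("pl_matrix", "matrix", "array"))
}

#' @export
print.pl_matrix <- function(x, ...) {
  s <- attr(x, "samples")
  cat(sprintf("<pl_matrix> %d proteins x %d runs (%d detected cells)\n",
              nrow(x), ncol(x), sum(!is.na(x))))
  cat(sprintf("  strains: %s\n", paste(unique(s$strain_label), collapse = ", ")))
  cat(sprintf("  experiments: %s\n", paste(unique(s$experiment_id), collapse = ", ")))
  invisible(x)
}

#' Sample sheet accessor
#' @param x a `pl_matrix`.
#' @return the sample-descriptor data.frame.
#' @export
pl_samples <- function(x) attr(x, "samples")

normalize_ids <- function(x) trimws(as.character(x))

#' @keywords internal
validate_sample_sheet <- function(samples) {
  required <- c("run_id", "strain_label", "experiment_id", "replicate_index", "role")
  miss <- setdiff(required, names(samples))
  if (length(miss))
    stop("sample sheet lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  samples$run_id <- normalize_ids(samples$run_id)
  samples$strain_label <- normalize_ids(samples$strain_label)
  samples$experiment_id <- normalize_ids(samples$experiment_id)
  samples$replicate_index <- as.integer(samples$replicate_index)
  samples$role <- as.character(samples$role)
  roles <- c("bait", "negative_control", "nonspecific_control")
  bad <- setdiff(unique(samples$role), roles)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         " (expected bait, negative_control, nonspecific_control)", call. = FALSE)
  if (anyDuplicated(samples$run_id))
    stop("duplicate run_id: ",
         paste(unique(samples$run_id[duplicated(samples$run_id)]), collapse = ", "),
         call. = FALSE)
  key <- paste(samples$strain_label, samples$experiment_id, samples$replicate_index)
  if (anyDuplicated(key))
    stop("duplicate (strain, experiment, replicate) combination", call. = FALSE)
  if (any(samples$replicate_index < 1L, na.rm = TRUE) || anyNA(samples$replicate_index))
    stop("replicate_index must be a positive integer", call. = FALSE)
  # experiments with bait runs but no negative control: usable only once a
  # contrast is actually requested, so warn here and fail there
  bait_exp <- unique(samples$experiment_id[samples$role == "bait"])
  neg_exp <- unique(samples$experiment_id[samples$role == "negative_control"])
  orphan <- setdiff(bait_exp, neg_exp)
  if (length(orphan))
    warning("experiment(s) with bait runs but no negative_control runs: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  samples
}

#' Read a sample sheet
#'
#' @param path delimited text file with columns `run_id`, `strain_label`,
#'   `experiment_id`, `replicate_index`, `role`. Role must be one of
#'   `bait`, `negative_control`, `nonspecific_control`.
#' @param sep field separator; guessed from the extension when `NULL`
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return a validated data.frame of sample descriptors.
#' @export
read_sample_sheet <- function(path, sep = NULL) {
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"", comment.char = "")
  validate_sample_sheet(df)
}

guess_sep <- function(path) if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a protein quantification table
#'
#' Parses a wide protein-level table (first column protein identifier, one
#' column per MS run) into a [pl_matrix()]. Empty cells and the configured
#' missing tokens denote not-detected; exported tables often use 0 for
#' absence, so `zero_is_missing = TRUE` by default maps 0 to not-detected.
#'
#' @param path delimited text file.
#' @param samples sample sheet (data.frame or path readable by
#'   [read_sample_sheet()]).
#' @param sep field separator (guessed when `NULL`).
#' @param zero_is_missing treat numeric 0 as not-detected.
#' @param na_strings tokens denoting not-detected.
#' @return a `pl_matrix`. Parsing is independent of row/column order.
#' @export
read_quant_table <- function(path, samples, sep = NULL, zero_is_missing = TRUE,
                             na_strings = c("", "NA", "ND", "Filtered", "NaN")) {
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"", comment.char = "",
                          na.strings = na_strings, colClasses = NA)
  if (ncol(df) < 2) stop("quantification table needs >= 2 columns", call. = FALSE)
  ids <- normalize_ids(df[[1]])
  dup <- unique(ids[duplicated(tolower(ids))])
  if (length(dup))
    stop("duplicate protein identifiers: ", paste(dup, collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(vals < 0, na.rm = TRUE)) stop("negative intensity encountered", call. = FALSE)
  if (zero_is_missing) vals[!is.na(vals) & vals == 0] <- NA_real_
  else if (any(vals == 0, na.rm = TRUE))
    stop("zero intensity encountered with zero_is_missing = FALSE", call. = FALSE)
  rownames(vals) <- ids
  m <- pl_matrix(vals, samples)
  message(sprintf("read %d proteins x %d runs; %d detected cells",
                  nrow(m), ncol(m), sum(!is.na(m))))
  m
}

#' Write a quantification table
#'
#' Inverse of [read_quant_table()]: not-detected cells are emitted as empty
#' fields, so a read/write/read round trip preserves every value and every
#' not-detected state.
#'
#' @param mat a `pl_matrix`.
#' @param path output file.
#' @param sep field separator.
#' @export
write_quant_table <- function(mat, path, sep = ",") {
  v <- unclass(mat)
  # full double precision so a write/read cycle is lossless
  ch <- matrix(formatC(v, digits = 17, format = "g"), nrow(v),
               dimnames = dimnames(v))
  ch[is.na(v)] <- ""
  df <- data.frame(protein_id = rownames(mat), ch, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a reference identifier list
#'
#' One protein identifier per line; `#` starts a comment. Identifiers are
#' normalized exactly as in [read_quant_table()] and deduplicated.
#'
#' @param path plain-text file.
#' @param name label for the set (e.g. "carboxylases", "epidermal").
#' @return list with `name`, `protein_ids` (character), `source_note`.
#' @export
read_reference_set <- function(path, name, source_note = "") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  ids <- normalize_ids(lines)
  ids <- ids[nzchar(ids)]
  ids <- ids[!duplicated(tolower(ids))]
  if (!length(ids)) stop("reference set '", name, "' is empty: ", path, call. = FALSE)
  reference_set(ids, name, source_note)
}

#' @rdname read_reference_set
#' @param ids character vector of identifiers.
#' @export
reference_set <- function(ids, name, source_note = "") {
  ids <- normalize_ids(ids)
  ids <- ids[nzchar(ids)]
  ids <- ids[!duplicated(tolower(ids))]
  if (!length(ids)) stop("reference set '", name, "' is empty", call. = FALSE)
  structure(list(name = name, protein_ids = ids, source_note = source_note),
            class = "pl_reference_set")
}

#' Case-insensitive membership against a reference set
#' @keywords internal
in_reference <- function(ids, ref) {
  if (is.null(ref)) return(rep(FALSE, length(ids)))
  pool <- if (inherits(ref, "pl_reference_set")) ref$protein_ids else ref
  tolower(normalize_ids(ids)) %in% tolower(normalize_ids(pool))
}

ANNOTATED_COLUMNS <- c("protein_id", "bait_mean", "control_mean",
                       "n_detected_bait", "n_detected_control",
                       "fold_change", "fc_is_estimate", "log2_fc",
                       "p_value", "adj_p", "detection_category",
                       "control_fc", "color", "bait_control_ratio",
                       "filter1_pass", "filter2_pass")

#' Write an annotated enrichment table
#'
#' Emits one row per protein with a stable column order covering the
#' enrichment statistics, detection category, control-reference fold change,
#' color label, bait-to-control ratio and the two filter flags. Undefined
#' values are written as empty cells; the estimate flag is written as
#' "estimated"/"" so spreadsheets show it plainly.
#'
#' @param records annotated records (see [annotate_records()]).
#' @param path output file.
#' @param sep field separator.
#' @export
write_annotated_table <- function(records, path, sep = ",") {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in ANNOTATED_COLUMNS)
    if (is.null(df[[col]])) df[[col]] <- rep(NA, nrow(df))
  df <- df[, ANNOTATED_COLUMNS, drop = FALSE]
  df$fc_is_estimate <- ifelse(!is.na(df$fc_is_estimate) & df$fc_is_estimate,
                              "estimated", "")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read back an annotated enrichment table
#' @param path file written by [write_annotated_table()].
#' @param sep field separator.
#' @export
read_annotated_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          na.strings = "", quote = "\"", comment.char = "")
  df$fc_is_estimate <- !is.na(df$fc_is_estimate) & df$fc_is_estimate == "estimated"
  for (col in c("filter1_pass", "filter2_pass"))
    if (!is.null(df[[col]])) df[[col]] <- as.logical(df[[col]])
  df
}
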