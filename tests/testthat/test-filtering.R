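# two-contrast control reference built from exactly specified records
make_control_pair <- function() {
  # contrast A (first control experiment): ALDO-2 120-fold, a 3-fold single,
  # a ligase-exclusive protein, and assorted non-qualifiers
  a <- make_records(
    c("ALDO-2", "SINGLE-A", "GHOST", "WEAK", "PARTIAL", "NS"),
    fold_change = c(120, 3, 30, 1.5, 8, 4),
    adj_p = c(1e-6, 0.01, NA, 0.001, 0.001, 0.4),
    n_detected_bait = c(3, 3, 3, 3, 2, 3),
    n_detected_control = c(3, 3, 0, 3, 3, 3),
    fc_is_estimate = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    detection_category = c("both", "both", "bait_only", "both", "partial", "both"))
  # contrast B: ALDO-2 144-fold; SINGLE-A absent from B's negative controls;
  # GHOST ligase-exclusive again; WEAK significant here too but still < 2
  b <- make_records(
    c("ALDO-2", "SINGLE-A", "GHOST", "WEAK", "SINGLE-B"),
    fold_change = c(144, 50, 28, 1.4, 2.5),
    adj_p = c(1e-7, NA, NA, 0.01, 0.03),
    n_detected_bait = c(3, 3, 3, 3, 3),
    n_detected_control = c(3, 0, 0, 3, 3),
    fc_is_estimate = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    detection_category = c("both", "bait_only", "bait_only", "both", "both"))
  list(Exp6 = a, Exp8 = b)
}

test_that("the control reference reproduces the published category logic", {
  ref <- build_control_reference(make_control_pair())
  row <- function(id) ref[ref$protein_id == id, ]
  # 120- and 144-fold in the two experiments: mean control fold change 132
  expect_identical(row("ALDO-2")$category, "enriched_both")
  expect_equal(row("ALDO-2")$control_fc, 132)
  # significant in one experiment, absent from the other's negative controls
  expect_identical(row("SINGLE-A")$category, "enriched_single_Exp6")
  expect_equal(row("SINGLE-A")$control_fc, 3)
  expect_identical(row("SINGLE-B")$category, "enriched_single_Exp8")
  # present in all ligase replicates everywhere, never in a negative control
  expect_identical(row("GHOST")$category, "control_only")
  expect_true(is.na(row("GHOST")$control_fc))
  # sub-threshold, non-significant, or partially detected proteins stay out
  expect_false(any(c("WEAK", "PARTIAL", "NS") %in% ref$protein_id))
  # admission rule: every enriched entry carries a fold change >= 2
  enr <- ref[ref$category != "control_only", ]
  expect_true(all(enr$control_fc >= 2))
  expect_true(all(!is.na(enr$control_fc)))
  expect_error(build_control_reference(list()), "contrast")
})

test_that("first-stage filtering applies the retention rule and keeps exclusives", {
  rec <- make_records(
    c("EEA-1", "N-two-fold", "partial-det", "exclusive", "weak-p"),
    fold_change = c(17, 1.95, 4, 40, 3),
    adj_p = c(0.001, 0.015, 0.01, NA, 0.2),
    n_detected_bait = c(3, 3, 2, 3, 3),
    n_detected_control = c(3, 3, 0, 0, 3),
    fc_is_estimate = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    detection_category = c("both", "both", "partial", "bait_only", "both"))
  kept <- filter1(rec)
  expect_setequal(kept, c("EEA-1", "exclusive"))
})

test_that("color annotation follows the control fold-change buckets", {
  ref <- data.frame(protein_id = c("R", "O", "Y", "EDGE10", "EDGE5", "G"),
                    category = c(rep("enriched_both", 5), "control_only"),
                    control_fc = c(132, 7, 4, 10, 5, NA),
                    stringsAsFactors = FALSE)
  rec <- make_records(c("R", "O", "Y", "EDGE10", "EDGE5", "G", "W", "CPLX"),
                      fold_change = c(3, 3, 8, 3, 20, 6, 9, 50),
                      adj_p = 0.01)
  ann <- annotate_filter1(rec$protein_id, ref, rec,
                          complex_members = reference_set("CPLX", "complex"))
  cols <- setNames(ann$color, ann$protein_id)
  expect_identical(unname(cols[c("R", "O", "Y")]), c("red", "orange", "yellow"))
  # boundary values land in the lower-severity bucket
  expect_identical(unname(cols[["EDGE10"]]), "orange")
  expect_identical(unname(cols[["EDGE5"]]), "yellow")
  expect_identical(unname(cols[["G"]]), "gray")
  expect_identical(unname(cols[["W"]]), "white")
  expect_identical(unname(cols[["CPLX"]]), "green")
  # every first-stage protein gets exactly one color
  expect_true(all(ann$color %in% c("red", "orange", "yellow", "gray", "white", "green")))
  # ratio present exactly where both fold changes exist
  expect_equal(ann$bait_control_ratio[ann$protein_id == "Y"], 2)
  expect_true(is.na(ann$bait_control_ratio[ann$protein_id == "G"]))
})

test_that("complex members in the control reference trigger a conflict warning", {
  ref <- data.frame(protein_id = "CPLX", category = "enriched_both",
                    control_fc = 3, stringsAsFactors = FALSE)
  rec <- make_records("CPLX", fold_change = 9, adj_p = 0.01)
  expect_warning(
    ann <- annotate_filter1("CPLX", ref, rec, reference_set("CPLX", "complex")),
    "control reference")
  expect_identical(ann$color, "green")
})

test_that("bait-to-control ratios and second-stage decisions match the worked cases", {
  expect_equal(bait_control_ratio(17, 2.2), 17 / 2.2)  # ~7.7, retained
  expect_equal(bait_control_ratio(3.6, 4.0), 0.9)      # removed at 1.5
  expect_equal(bait_control_ratio(5, 5), 1)

  ref <- data.frame(protein_id = c("ALDO-2", "EEA-1", "MDT-6"),
                    category = "enriched_both",
                    control_fc = c(132, 2.2, 4.0), stringsAsFactors = FALSE)
  rec <- make_records(c("ALDO-2", "EEA-1", "MDT-6", "CLEAN"),
                      fold_change = c(60, 17, 3.6, 9), adj_p = 0.001)
  ann <- annotate_filter1(rec$protein_id, ref, rec)
  kept <- filter2(ann)
  expect_true("EEA-1" %in% kept)       # yellow, ratio >= 1.5
  expect_false("MDT-6" %in% kept)      # yellow, ratio 0.9 < 1.5
  expect_false("ALDO-2" %in% kept)     # red: removed regardless of bait FC
  expect_true("CLEAN" %in% kept)       # white
})

test_that("gray and green proteins are retained by the second-stage filter", {
  ref <- data.frame(protein_id = c("GRAY", "HOT"), category = c("control_only", "enriched_both"),
                    control_fc = c(NA, 50), stringsAsFactors = FALSE)
  rec <- make_records(c("GRAY", "HOT", "CPLX"), fold_change = c(5, 200, 30), adj_p = 0.001)
  ann <- annotate_filter1(rec$protein_id, ref, rec, reference_set("CPLX", "cplx"))
  kept <- filter2(ann)
  expect_setequal(kept, c("GRAY", "CPLX"))
})

test_that("second-stage retention is monotone in both thresholds and nested", {
  set.seed(21)
  n <- 120
  ids <- sprintf("P%03d", 1:n)
  rec <- make_records(ids, fold_change = 2^runif(n, -1, 6),
                      adj_p = runif(n, 0, 0.1))
  ref <- data.frame(protein_id = sample(ids, 80),
                    category = "enriched_both",
                    control_fc = 2^runif(80, 0.5, 7.5), stringsAsFactors = FALSE)
  set1 <- filter1(rec)
  ann <- annotate_filter1(set1, ref, rec)
  prev_sets <- list()
  for (cutfc in c(3, 5, 8, 12)) {
    for (rcut in c(2.5, 1.5, 1.0, 0.5)) {
      kept <- filter2(ann, ratio_cut = rcut, remove_above_control_fc = cutfc)
      expect_true(all(kept %in% set1))   # filter2 output nested in filter1
      key_prev <- paste(cutfc, "prev")
      if (!is.null(prev_sets[[key_prev]]))
        expect_true(all(prev_sets[[key_prev]] %in% kept),
                    label = sprintf("lowering ratio_cut to %.1f keeps retained set", rcut))
      prev_sets[[key_prev]] <- kept
    }
    if (!is.null(prev_sets[["cutfc"]]))
      expect_true(all(prev_sets[["cutfc"]] %in%
                        filter2(ann, ratio_cut = 1.5, remove_above_control_fc = cutfc)))
    prev_sets[["cutfc"]] <- filter2(ann, ratio_cut = 1.5, remove_above_control_fc = cutfc)
  }
})

test_that("cross-bait overlap counts equal exhaustive membership enumeration", {
  sets <- list(A = c("p1", "p2", "p3", "p5"),
               B = c("p2", "p3", "p4"),
               C = c("p3", "p5", "p6"))
  ov <- cross_bait_overlap(sets)
  ids <- unique(unlist(sets))
  brute <- table(sapply(ids, function(i)
    paste(as.integer(sapply(sets, function(s) i %in% s)), collapse = "")))
  for (i in seq_len(nrow(ov)))
    expect_equal(ov$count[i], unname(brute[[ov$pattern[i]]]))
  expect_equal(sum(ov$count), length(ids))

  same <- cross_bait_overlap(list(A = c("x", "y"), B = c("x", "y")))
  expect_identical(same$pattern, "11")
  disj <- cross_bait_overlap(list(A = "x", B = "y"))
  expect_false("11" %in% disj$pattern)

  # color composition per region
  ovc <- cross_bait_overlap(sets, colors = c(p3 = "red", p5 = "yellow"))
  expect_equal(ovc$n_red[ovc$pattern == "111"], 1)
})
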