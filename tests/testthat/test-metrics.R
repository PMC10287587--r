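arr2 <- function(v) array(v, c(1, 2, 2))

test_that("confusion counts and overlap metrics on the 2x2 toy", {
  # ref marks cells (1,1),(1,2); pred marks (1,2),(2,2)
  ref <- arr2(c(1, 0, 1, 0))
  pred <- arr2(c(0, 0, 1, 1))
  cc <- confusion_counts(pred, ref)
  expect_equal(unname(cc), c(1, 1, 1, 1))
  expect_equal(sum(cc), 4)
  expect_equal(dsc(pred, ref), 0.5)
  expect_equal(sensitivity(pred, ref), 0.5)
  expect_equal(specificity(pred, ref), 0.5)
})

test_that("overlap metrics match brute-force counting on random masks", {
  set.seed(31)
  for (t in 1:20) {
    d <- c(1, 16, 16)
    pred <- random_mask(d, runif(1, 0.1, 0.6))
    ref <- random_mask(d, runif(1, 0.1, 0.6))
    bc <- brute_confusion(pred, ref)
    expect_identical(confusion_counts(pred, ref), bc)
    if (bc["TP"] + bc["FN"] > 0) {
      expect_identical(dsc(pred, ref),
                       unname(2 * bc["TP"] / (2 * bc["TP"] + bc["FP"] + bc["FN"])))
      expect_identical(sensitivity(pred, ref), unname(bc["TP"] / (bc["TP"] + bc["FN"])))
    }
    expect_identical(specificity(pred, ref), unname(bc["TN"] / (bc["TN"] + bc["FP"])))
  }
})

test_that("overlap metric edge conventions", {
  m <- random_mask(c(1, 8, 8), 0.3)
  expect_equal(unname(confusion_counts(m, m)[c("FP", "FN")]), c(0, 0))
  expect_equal(unname(confusion_counts(1 - m, m)[c("TP", "TN")]), c(0, 0))
  expect_warning(d0 <- dsc(array(0, c(1, 4, 4)), array(0, c(1, 4, 4))), "empty")
  expect_equal(d0, 1)
  a <- array(0, c(1, 4, 4)); a[1, 1, 1] <- 1
  b <- array(0, c(1, 4, 4)); b[1, 4, 4] <- 1
  expect_equal(dsc(a, b), 0)
  expect_error(confusion_counts(array(0, c(1, 2, 2)), array(0, c(1, 2, 3))),
               "mismatch")
})

test_that("dsc complements dice_loss for binary predictions", {
  set.seed(32)
  pred <- random_mask(c(2, 8, 8), 0.4)
  ref <- random_mask(c(2, 8, 8), 0.4)
  expect_equal(suppressWarnings(dsc(pred, ref)), 1 - dice_loss(pred, ref),
               tolerance = 1e-5)
})

test_that("hd95: exact cases, spacing, symmetry, and undefined flags", {
  m <- segmentation_mask(random_mask(c(2, 10, 10), 0.3), c(4, 1, 1))
  expect_equal(hd95(m, m), 0)

  a <- array(0, c(1, 10, 10)); a[1, 2, 2] <- 1
  b <- array(0, c(1, 10, 10)); b[1, 2, 5] <- 1
  expect_equal(hd95(a, b, spacing = c(1, 1, 1)), 3)

  # anisotropic spacing honored: one slice apart at dz = 4 mm
  a3 <- array(0, c(2, 4, 4)); a3[1, 2, 2] <- 1
  b3 <- array(0, c(2, 4, 4)); b3[2, 2, 2] <- 1
  expect_equal(hd95(a3, b3, spacing = c(4, 1, 1)), 4)

  expect_true(is.na(hd95(array(0, c(1, 10, 10)), a, spacing = c(1, 1, 1))))
})

test_that("hd95 equals the brute-force all-pairs oracle on random masks", {
  set.seed(33)
  for (t in 1:10) {
    d <- c(sample(1:4, 1), sample(8:16, 1), sample(8:16, 1))
    sp <- c(runif(1, 1, 5), runif(1, 0.5, 2), runif(1, 0.5, 2))
    pred <- random_mask(d, 0.25)
    ref <- random_mask(d, 0.25)
    if (sum(pred) == 0 || sum(ref) == 0) next
    expect_equal(hd95(pred, ref, spacing = sp), brute_hd95(pred, ref, sp),
                 tolerance = 1e-9)
    expect_equal(hd95(pred, ref, spacing = sp), hd95(ref, pred, spacing = sp))
  }
})

test_that("slicewise hd95 uses in-plane distances only", {
  a <- array(0, c(2, 8, 8)); a[1, 3, 3] <- 1; a[2, 3, 3] <- 1
  b <- array(0, c(2, 8, 8)); b[1, 3, 6] <- 1; b[2, 3, 3] <- 1
  # 3D: distances pooled over both slices; slicewise: per-slice in-plane
  expect_equal(hd95(a, b, spacing = c(10, 1, 1), slicewise = TRUE),
               unname(quantile(c(3, 3, 0, 0), 0.95)))
})

test_that("roc_auc: hand example, degenerate maps, monotone invariance", {
  y <- array(c(0, 0, 1, 1), c(1, 1, 4))
  p <- array(c(0.1, 0.4, 0.35, 0.8), c(1, 1, 4))
  r <- roc_auc(p, y)
  expect_equal(r$auc, 0.75)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)

  perfect <- roc_auc(y, y)
  expect_equal(perfect$auc, 1.0)
  flat <- roc_auc(array(0.5, dim(y)), y)
  expect_equal(flat$auc, 0.5)

  # AUC invariant under strictly monotone transforms
  expect_equal(roc_auc(p^3, y)$auc, 0.75)

  expect_warning(na <- roc_auc(p, array(1, dim(y))), "single-class")
  expect_true(is.na(na$auc))
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  y <- array(rbinom(200, 1, 0.3), c(2, 10, 10))
  p <- array(runif(200), c(2, 10, 10))
  ours <- roc_auc(p, y)$auc
  theirs <- as.numeric(pROC::auc(as.numeric(y), as.numeric(p), quiet = TRUE,
                                 direction = "<"))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("per-location summary reproduces means and improvement rows", {
  mk <- function(eid, model, dsc, sens, spec, hd) {
    data.frame(exam_id = eid, model = model, dsc = dsc, sensitivity = sens,
               specificity = spec, hd95_mm = hd, auc = NA_real_)
  }
  reports <- rbind(
    mk("e1", "b1", 0.7, 0.7, 0.99, 11.0), mk("e1", "b2", 0.7, 0.7, 0.99, 12.0),
    mk("e1", "super_learner", 0.8, 0.75, 0.995, 1.7),
    mk("e2", "b1", 0.6, 0.6, 0.98, 20.0), mk("e2", "b2", 0.6, 0.6, 0.98, 24.0),
    mk("e2", "super_learner", 0.7, 0.65, 0.99, 10.0))
  labels <- c(e1 = "DUL", e2 = "T")
  tbl <- summarize_by_location(reports, labels)

  row <- function(metric, group) tbl[tbl$metric == metric & tbl$group == group, ]
  # individual means per location: e1 hd95 = (11+12)/2 = 11.5
  expect_equal(row("hd95_mm", "individual")$DUL, 11.5)
  expect_equal(row("hd95_mm", "super_learner")$DUL, 1.7)
  # percent reduction matches the printed-table convention: 11.5 -> 1.7 is 85.2%
  expect_equal(row("hd95_mm", "improvement_pct")$DUL, 85.2, tolerance = 0.05)
  # overlap improvement is the signed difference
  expect_equal(row("dsc", "improvement")$DUL, 0.1, tolerance = 1e-9)
  expect_equal(row("dsc", "improvement")$ALL, 0.75 - 0.65, tolerance = 1e-9)

  # one location, identical reports: means equal the report
  single <- rbind(mk("e1", "b1", 0.5, 0.5, 0.9, 3), mk("e1", "super_learner", 0.5, 0.5, 0.9, 3))
  t2 <- summarize_by_location(single, c(e1 = "PLL"))
  expect_equal(t2[t2$metric == "dsc" & t2$group == "individual", ]$PLL, 0.5)
  expect_equal(t2[t2$metric == "hd95_mm" & t2$group == "improvement_pct", ]$PLL, 0)

  expect_error(summarize_by_location(reports, c(e1 = "DUL")), "unlabeled")
})

test_that("evaluate_exam assembles a coherent report row", {
  set.seed(35)
  ref <- segmentation_mask(random_mask(c(2, 8, 8), 0.3), c(4, 1, 1), "e9")
  pm <- array(runif(128), c(2, 8, 8))
  pred <- binarize(pm, 0.5, c(4, 1, 1), "e9")
  row <- evaluate_exam(pred, ref, pm, exam_id = "e9", model = "m")
  expect_equal(row$exam_id, "e9")
  expect_true(row$dsc >= 0 && row$dsc <= 1)
  expect_true(row$auc >= 0 && row$auc <= 1)
  expect_true(is.finite(row$hd95_mm))
})
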