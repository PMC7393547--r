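# Metrics, ROC/AUC, cross-validation machinery, grid search and the
# paired t-test.

test_that("confusion metrics follow the printed formulas", {
  m <- confusion_metrics(50, 50, 0, 0)
  expect_equal(unname(m[c("sn", "sp", "precision", "acc", "mcc")]),
               c(1, 1, 1, 1, 1))
  expect_equal(unname(confusion_metrics(10, 5, 5, 10)["acc"]), 0.5)
  # direct arithmetic oracle
  tp <- 40; fp <- 10; tn <- 35; fn <- 15
  m2 <- confusion_metrics(tp, tn, fp, fn)
  expect_equal(unname(m2["mcc"]),
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  expect_equal(unname(m2["sn"]), tp / (tp + fn))
  expect_equal(unname(m2["sp"]), tn / (tn + fp))
  # zero denominators
  expect_true(is.na(confusion_metrics(0, 10, 0, 0)["sn"]))
  expect_equal(unname(confusion_metrics(0, 10, 0, 0)["mcc"]), 0)
  expect_error(confusion_metrics(-1, 1, 1, 1), "negative")
})

test_that("metrics stay in bounds on random confusion tables", {
  set.seed(41)
  for (k in 1:2000) {
    cc <- stats::rmultinom(1, 40, rep(0.25, 4))
    m <- confusion_metrics(cc[1], cc[2], cc[3], cc[4])
    ok <- !is.na(m)
    expect_true(all(m[ok & names(m) != "mcc"] >= 0 &
                    m[ok & names(m) != "mcc"] <= 1))
    expect_true(is.na(m["mcc"]) || (m["mcc"] >= -1 && m["mcc"] <= 1))
  }
})

test_that("trapezoidal AUC equals the rank statistic and handles ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  set.seed(42)
  for (k in 1:50) {
    sc <- round(stats::rnorm(60), 1)  # rounding forces ties
    lb <- stats::rbinom(60, 1, 0.4)
    if (length(unique(lb)) < 2) next
    a <- roc_auc(sc, lb)$auc
    # Mann-Whitney with midpoint tie handling
    r <- rank(sc)
    n1 <- sum(lb == 1); n0 <- sum(lb == 0)
    u <- sum(r[lb == 1]) - n1 * (n1 + 1) / 2
    expect_equal(a, u / (n1 * n0), tolerance = 1e-12)
    # AUC is invariant under strictly monotone transforms
    expect_equal(roc_auc(exp(sc / 2), lb)$auc, a, tolerance = 1e-12)
  }
  # independent labels: AUC near 0.5 within a 3-sigma binomial-type bound
  set.seed(43)
  sc <- stats::rnorm(1e4)
  lb <- stats::rbinom(1e4, 1, 0.5)
  expect_lt(abs(roc_auc(sc, lb)$auc - 0.5), 0.02)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(44)
  sc <- stats::rnorm(200)
  lb <- stats::rbinom(200, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, lb)$auc, ref, tolerance = 1e-10)
})

test_that("paired t-test matches stats::t.test and degenerate cases", {
  a <- c(0.9, 0.92, 0.91, 0.95, 0.88)
  expect_equal(paired_t_test(a, a)$p, 1)
  expect_equal(paired_t_test(a, a)$t, 0)
  d <- paired_t_test(a + 0.01, a)
  expect_equal(d$p, 0)
  expect_true(is.infinite(d$t))
  set.seed(45)
  for (k in 1:20) {
    x <- stats::rnorm(10); y <- stats::rnorm(10)
    ref <- stats::t.test(x, y, paired = TRUE)
    got <- paired_t_test(x, y)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the specificity threshold is the smallest achieving the target", {
  sc <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  lb <- c(0, 0, 0, 1, 1)
  th <- threshold_at_specificity(sc, lb, 0.99)
  expect_equal(th, 0.8)  # smallest observed score with all negatives below
  # negatives above positives: threshold exceeds the maximum score
  th2 <- threshold_at_specificity(c(0.9, 0.95, 0.1), c(0, 0, 1), 0.99)
  expect_gt(th2, 0.95)
  # recount on random data
  set.seed(46)
  sc3 <- stats::runif(500)
  lb3 <- stats::rbinom(500, 1, 0.3)
  th3 <- threshold_at_specificity(sc3, lb3, 0.99)
  sp <- mean(sc3[lb3 == 0] < th3)
  expect_gte(sp, 0.99)
})

test_that("stratified folds are seeded, balanced and class-complete", {
  labs <- rep(c(1, 0), c(20, 20))
  f1 <- crfcleave:::stratified_folds(labs, 5, 9)
  f2 <- crfcleave:::stratified_folds(labs, 5, 9)
  expect_identical(f1, f2)
  for (f in 1:5) {
    expect_equal(sum(labs[f1 == f] == 1), 4)
    expect_equal(sum(labs[f1 == f] == 0), 4)
  }
  expect_error(crfcleave:::stratified_folds(c(1, 0, 0, 0), 3, 1),
               "fewer")
})

test_that("preprocessing state is fitted inside training folds only", {
  d <- structure_only_dataset()$prep
  arm <- preset_config("seq_chem_smooth")
  tr <- 1:20
  fitted1 <- crfcleave:::fit_fold_config(arm, d$profiles[tr])
  # corrupting profiles outside the training fold changes nothing
  prof2 <- d$profiles
  for (k in 21:length(prof2)) prof2[[k]] <- lapply(prof2[[k]], `*`, 100)
  fitted2 <- crfcleave:::fit_fold_config(arm, prof2[tr])
  expect_identical(fitted1$smoothing$edges, fitted2$smoothing$edges)
  # and using test-fold profiles does change the edges
  fitted3 <- crfcleave:::fit_fold_config(arm, prof2[21:32])
  expect_false(identical(fitted1$smoothing$edges,
                         fitted3$smoothing$edges))
})

test_that("cross-validation is seed-reproducible and near 0.5 on permuted labels", {
  d <- sequence_only_dataset()$prep
  cv1 <- cross_validate(d$windows, d$profiles, preset = "seq_chem",
                        folds = 3, repeats = 2, seed = 4)
  cv2 <- cross_validate(d$windows, d$profiles, preset = "seq_chem",
                        folds = 3, repeats = 2, seed = 4)
  expect_identical(cv1$auc_per_repeat, cv2$auc_per_repeat)
  expect_gte(cv1$mean_auc, 0.95)  # planted motif is recoverable

  set.seed(47)
  wperm <- d$windows
  wperm$label <- sample(wperm$label)
  cvp <- cross_validate(wperm, d$profiles, preset = "seq_chem",
                        folds = 3, repeats = 2, seed = 4)
  expect_lt(abs(cvp$mean_auc - 0.5), 0.2)
})

test_that("the candidate grid enumerates 50 configurations per feature", {
  g <- grid_candidates()
  expect_equal(nrow(g), 50)
  expect_equal(nrow(unique(g)), 50)
  # tie-break ordering: fewer bins first, then smaller range
  expect_equal(g$bins[1], 1)
  expect_equal(g$range[1], 1)
  expect_true(all(diff(g$bins) >= 0))
})

test_that("grid search keeps signal features binned and collapses noise", {
  # noise feature on a sequence-signal dataset: every config ties at the
  # motif-driven AUC, so the tie-break selects bins = 1, range = 1
  d <- sequence_only_dataset()$prep
  gs <- grid_search_smoothing(d$windows, d$profiles,
                              features = "bfactor_mean",
                              ranges = 1:2, bins = c(1, 2, 4),
                              folds = 3, seed = 2, max_iter = 60)
  expect_equal(gs$bins, 1)
  expect_equal(gs$range, 1)

  # a feature carrying the only signal must keep more than one bin
  d2 <- structure_only_dataset()$prep
  gs2 <- grid_search_smoothing(d2$windows, d2$profiles,
                               features = "rel_all",
                               ranges = 1:2, bins = c(1, 3),
                               folds = 3, seed = 2, max_iter = 60)
  expect_gt(gs2$bins, 1)
  expect_gt(gs2$auc, 0.6)
})
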