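# Performance evaluation: confusion-matrix metrics, ROC/AUC, repeated
# stratified cross-validation, the smoothing-range/bin grid search, the
# paired t-test between feature arms, and the high-specificity operating
# threshold.

#' Confusion-matrix metrics
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), precision =
#' TP/(TP+FP), accuracy = (TP+TN)/total and Matthews correlation
#' coefficient.  A zero denominator yields `NA` for the affected rate;
#' by convention MCC is 0 when its denominator vanishes.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return named numeric vector `sn`, `sp`, `precision`, `acc`, `mcc`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(sn = safe(tp, tp + fn),
    sp = safe(tn, tn + fp),
    precision = safe(tp, tp + fp),
    acc = (tp + tn) / total,
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

#' ROC curve and AUC
#'
#' Trapezoidal AUC over all distinct score thresholds, tie-aware (tied
#' scores move the operating point diagonally, equivalent to the
#' midpoint-rank convention), so the value equals the Mann-Whitney rank
#' statistic.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return list with `auc` and `roc` (data frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # collapse tied scores into single operating points
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l == 1)[last_of_group]
  fp <- cumsum(l == 0)[last_of_group]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc,
       roc = data.frame(threshold = c(Inf, s[last_of_group]),
                        fpr = fpr, tpr = tpr))
}

#' Paired t-test between two AUC vectors
#'
#' Paired two-sided Student's t-test across repeats: t = mean(d) /
#' (sd(d)/sqrt(n)) on the differences d, with p from the t distribution
#' on n-1 degrees of freedom.  Identical vectors give t = 0, p = 1; a
#' constant nonzero shift (zero variance) is the degenerate case t =
#' +/-Inf, p = 0.
#'
#' @param auc_a,auc_b paired numeric vectors of equal length.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_test <- function(auc_a, auc_b) {
  stopifnot(length(auc_a) == length(auc_b), length(auc_a) >= 2)
  d <- auc_a - auc_b
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t <- mean(d) / (sdd / sqrt(n))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, df = n - 1, p = p, mean_diff = mean(d))
}

#' Operating threshold at a target specificity
#'
#' Smallest score threshold (calls are `score >= threshold`) achieving
#' specificity at or above `target_sp` on the supplied evaluation set.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param target_sp target specificity (default 0.99).
#' @return the threshold (a value above the maximum score when even the
#'   strictest observed score does not reach the target).
#' @export
threshold_at_specificity <- function(scores, labels, target_sp = 0.99) {
  labels <- as.integer(labels)
  neg <- scores[labels == 0]
  if (!length(neg)) stop("no negatives to estimate specificity from")
  cand <- sort(unique(scores))
  for (t in cand) {
    sp <- mean(neg < t)
    if (sp >= target_sp) return(t)
  }
  max(scores) + 1e-8
}

# stratified fold assignment: within each class, a seeded permutation is
# dealt round-robin into folds
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      stop("class ", cl, " has fewer members (", length(idx),
           ") than folds (", folds, ")")
    }
    assign[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  assign
}

# fit the preset's smoothing/bin state on the training windows only
fit_fold_config <- function(arm, profiles_train) {
  if (is.null(arm$smoothing)) return(arm)
  arm$smoothing <- fit_config(arm$smoothing, profiles_train)
  arm
}

encode_set <- function(windows, profiles, arm) {
  lapply(seq_len(nrow(windows)), function(k) {
    encode_instance(windows$window[k],
                    profile = if (is.null(arm$smoothing)) NULL
                              else profiles[[k]],
                    cfg = arm$smoothing,
                    use_sequence = arm$use_sequence,
                    use_chemical = arm$use_chemical)
  })
}

train_and_score <- function(windows, profiles, arm, train_idx, test_idx,
                            l2_sigma = 1.0, max_iter = 120) {
  arm <- fit_fold_config(arm, profiles[train_idx])
  inst_train <- encode_set(windows[train_idx, , drop = FALSE],
                           profiles[train_idx], arm)
  inst_test <- encode_set(windows[test_idx, , drop = FALSE],
                          profiles[test_idx], arm)
  model <- crf_train(inst_train, windows$label[train_idx],
                     l2_sigma = l2_sigma, max_iter = max_iter,
                     config = arm$smoothing,
                     use_sequence = arm$use_sequence,
                     use_chemical = arm$use_chemical)
  vapply(inst_test, function(x) predict_site(model, x), numeric(1))
}

#' Repeated stratified cross-validation of a feature arm
#'
#' Runs `repeats` rounds of stratified `folds`-fold cross-validation;
#' the fold assignment is re-randomized each repeat from the seed, and
#' all preprocessing state (smoothing, bin edges) is fitted inside each
#' training fold only.  The per-repeat AUC is the mean of the fold AUCs.
#'
#' @param windows `site_windows` data frame (positives and negatives).
#' @param profiles per-window structural profiles (parallel to
#'   `windows`); may be `NULL` for sequence-only presets.
#' @param preset feature combination, see [preset_config()].
#' @param range,bins smoothing parameters for structural presets.
#' @param folds,repeats cross-validation layout.
#' @param seed base seed; repeat r uses `seed + r - 1`.
#' @param l2_sigma,max_iter CRF training controls.
#' @return an `evaluation_report`: list with `preset`, `auc_per_repeat`,
#'   `mean_auc`, `folds` (per-fold data frame) and the pooled
#'   `scores`/`labels` of the last repeat.
#' @export
cross_validate <- function(windows, profiles = NULL,
                           preset = "seq_chem_smooth", range = 2,
                           bins = 5, folds = 5, repeats = 10, seed = 1,
                           l2_sigma = 1.0, max_iter = 120) {
  stopifnot(folds >= 2)
  labels <- windows$label
  if (length(unique(labels)) < 2) stop("both classes required")
  if (is.null(profiles)) {
    profiles <- vector("list", nrow(windows))
  }
  arm0 <- preset_config(preset, range = range, bins = bins)
  per_repeat <- numeric(repeats)
  fold_rows <- list()
  scores_last <- labels_last <- NULL
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(labels, folds, seed + r - 1L)
    fold_auc <- numeric(folds)
    sc <- numeric(length(labels))
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      s <- train_and_score(windows, profiles, arm0, tr, te,
                           l2_sigma = l2_sigma, max_iter = max_iter)
      sc[te] <- s
      fold_auc[f] <- roc_auc(s, labels[te])$auc
      fold_rows[[length(fold_rows) + 1]] <-
        data.frame(repeat_ = r, fold = f, auc = fold_auc[f],
                   n_test = length(te))
    }
    per_repeat[r] <- mean(fold_auc)
    scores_last <- sc
    labels_last <- labels
  }
  out <- list(preset = preset, range = range, bins = bins,
              folds_k = folds, repeats = repeats, seed = seed,
              auc_per_repeat = per_repeat,
              mean_auc = mean(per_repeat),
              folds = do.call(rbind, fold_rows),
              scores = scores_last, labels = labels_last)
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %s  %dx%d-fold CV  mean AUC %.4f\n",
              x$preset, x$repeats, x$folds_k, x$mean_auc))
  cat("  per-repeat AUC:",
      paste(sprintf("%.3f", x$auc_per_repeat), collapse = " "), "\n")
  invisible(x)
}

#' The (range, bins) candidate grid
#'
#' @param ranges,bins candidate smoothing ranges and bin counts.
#' @return data frame of candidates ordered by bins then range (the
#'   tie-break order of the search).
#' @export
grid_candidates <- function(ranges = 1:5, bins = 1:10) {
  g <- expand.grid(range = ranges, bins = bins)
  g[order(g$bins, g$range), , drop = FALSE]
}

#' Sequential grid search over smoothing range and bin count
#'
#' For each structural feature in turn (all other features held at the
#' defaults), evaluates every (range, bins) candidate by stratified
#' cross-validated AUC and keeps the best; ties resolve toward fewer
#' bins, then smaller range.  One pass over the features in the given
#' order.
#'
#' @param windows,profiles the dataset, as for [cross_validate()].
#' @param features features to optimize (and the optimization order).
#' @param ranges,bins candidate values.
#' @param folds,seed CV layout for the objective.
#' @param default_range,default_bins values held for the other features.
#' @param l2_sigma,max_iter CRF training controls.
#' @return data frame with one row per feature: `feature`, `range`,
#'   `bins`, `auc`.
#' @export
grid_search_smoothing <- function(windows, profiles,
                                  features = STRUCT_FEATURES,
                                  ranges = 1:5, bins = 1:10, folds = 5,
                                  seed = 1, default_range = 2,
                                  default_bins = 5, l2_sigma = 1.0,
                                  max_iter = 120) {
  labels <- windows$label
  fold_id <- stratified_folds(labels, folds, seed)
  cand <- grid_candidates(ranges, bins)
  chosen_range <- stats::setNames(rep(default_range, length(features)),
                                  features)
  chosen_bins <- stats::setNames(rep(default_bins, length(features)),
                                 features)
  out <- list()
  for (f in features) {
    best <- NULL
    for (k in seq_len(nrow(cand))) {
      cfg <- smoothing_config(features, range = chosen_range,
                              bins = chosen_bins)
      cfg$range[[f]] <- cand$range[k]
      cfg$bins[[f]] <- cand$bins[k]
      arm <- list(preset = "grid", use_sequence = TRUE,
                  use_chemical = TRUE, smoothing = cfg)
      aucs <- numeric(folds)
      for (fd in seq_len(folds)) {
        tr <- which(fold_id != fd)
        te <- which(fold_id == fd)
        s <- train_and_score(windows, profiles, arm, tr, te,
                             l2_sigma = l2_sigma, max_iter = max_iter)
        aucs[fd] <- roc_auc(s, labels[te])$auc
      }
      a <- mean(aucs)
      if (is.null(best) || a > best$auc + 1e-12) {
        best <- list(range = cand$range[k], bins = cand$bins[k], auc = a)
      }
    }
    chosen_range[[f]] <- best$range
    chosen_bins[[f]] <- best$bins
    out[[f]] <- data.frame(feature = f, range = best$range,
                           bins = best$bins, auc = best$auc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
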