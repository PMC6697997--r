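# Statistical layer: ROC with the closest-to-corner operating point,
# Wilcoxon rank-sum (exact + tie-corrected normal approximation), Pearson
# correlation, and stratified k-fold cross-validation with fold averaging.

# Trapezoidal AUC of `scores` for indicator `y` (TRUE = positive), higher
# scores indicating the positive class. Equals the Mann-Whitney statistic
# (concordant + half ties) / (n_pos * n_neg).
auc_oriented <- function(scores, y) {
  pts <- roc_points(scores, y)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

# ROC curve points for decreasing thresholds; starts at (0,0), ends at (1,1).
roc_points <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  npos <- sum(y)
  nneg <- sum(!y)
  tp <- cumsum(yy)
  fp <- cumsum(!yy)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  data.frame(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp[last] / npos),
    fpr = c(0, fp[last] / nneg)
  )
}

#' ROC analysis with the closest-to-corner optimal operating point
#'
#' Computes the full ROC curve and trapezoidal AUC of a score for a binary
#' benign/malignant label, then selects the operating point nearest the
#' upper-left corner of the ROC plot: the threshold minimizing
#' `sqrt((1 - sens)^2 + (1 - spec)^2)`. Equidistant candidates are broken
#' toward higher specificity, then toward the lower threshold, so the choice
#' is deterministic. The reported threshold is the midpoint of the selected
#' operating point's equivalence interval (all thresholds in the interval
#' give the identical training confusion; the midpoint splits the margin
#' when the threshold is applied to new cases).
#'
#' Orientation: with `"higher"`, `score >= threshold` predicts malignancy;
#' with `"lower"`, `score <= threshold` does (busyness runs higher and
#' coarseness lower in benign lesions, so coarseness-like features orient
#' `"higher"`, busyness-like features `"lower"`). The default `"auto"` picks
#' the direction whose AUC is at least 0.5.
#'
#' @param scores numeric feature values, finite.
#' @param labels vector with exactly two classes present.
#' @param positive label value counting as positive (default
#'   `"malignant"`).
#' @param orientation `"auto"`, `"higher"`, or `"lower"`.
#' @return List of class `"roc_summary"`: `auc`, `threshold` (in feature
#'   units), `sensitivity`, `specificity`, `accuracy`, `orientation`, and
#'   `curve` (data frame of threshold/FPR/TPR).
#' @export
roc_analysis <- function(scores, labels, positive = "malignant",
                         orientation = c("auto", "higher", "lower")) {
  orientation <- match.arg(orientation)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  y <- labels == positive
  if (!any(y) || all(y))
    stop("both classes must be present for ROC analysis", call. = FALSE)
  if (length(scores) != length(y))
    stop("scores and labels differ in length", call. = FALSE)

  if (orientation == "auto") {
    orientation <- if (auc_oriented(scores, y) >= 0.5) "higher" else "lower"
  }
  s <- if (orientation == "higher") scores else -scores
  pts <- roc_points(s, y)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)

  cand <- pts[is.finite(pts$threshold), , drop = FALSE]
  sens <- cand$tpr
  spec <- 1 - cand$fpr
  # report the midpoint of each threshold's equivalence interval: the same
  # training confusion, but new cases falling inside the margin split it
  u <- cand$threshold  # unique oriented scores, descending
  mid <- if (length(u) > 1) c((u[-length(u)] + u[-1]) / 2, u[length(u)]) else u
  dist <- sqrt((1 - sens)^2 + (1 - spec)^2)
  ord <- order(dist, -spec, mid)
  best <- ord[1]
  thr_oriented <- mid[best]
  npos <- sum(y)
  nneg <- sum(!y)
  acc <- (sens[best] * npos + spec[best] * nneg) / (npos + nneg)

  curve <- data.frame(
    threshold = if (orientation == "higher") pts$threshold else -pts$threshold,
    fpr = pts$fpr, tpr = pts$tpr)
  structure(list(
    auc = auc,
    threshold = if (orientation == "higher") thr_oriented else -thr_oriented,
    sensitivity = sens[best],
    specificity = spec[best],
    accuracy = acc,
    orientation = orientation,
    positive = positive,
    curve = curve
  ), class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  rule <- if (x$orientation == "higher") ">=" else "<="
  cat(sprintf(
    "ROC: AUC = %.3f; optimal rule score %s %.4g -> %s (sens %.3f, spec %.3f, acc %.3f)\n",
    x$auc, rule, x$threshold, x$positive,
    x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

# Classify with a fitted roc_summary's threshold; returns logical (positive).
classify_roc <- function(roc, scores) {
  if (roc$orientation == "higher") scores >= roc$threshold
  else scores <= roc$threshold
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic (sum of average ranks of `group_a` in the pooled
#' sample) with a two-sided p-value. For small samples
#' (`length(a) + length(b) <= 12`, or `exact = TRUE`) the p-value is
#' computed by exhaustive enumeration of all group assignments; otherwise a
#' normal approximation with tie and continuity corrections is used. The
#' reported `z` is the tie-corrected deviate without the continuity shift
#' (the descriptive statistic conventionally tabulated); the approximate
#' p-value applies the shift. Fully tied data yield `p = 1`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 1.
#' @param exact force (`TRUE`) or suppress (`FALSE`) enumeration; default
#'   `NULL` enumerates when the pooled size is at most 12.
#' @return List: `statistic` (rank sum of `group_a`), `z` (tie-corrected
#'   normal deviate), `p`, and `method`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact = NULL) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 1L || length(b) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  if (!all(is.finite(pooled))) stop("values must be finite", call. = FALSE)
  n <- length(pooled)
  na <- length(a)
  nb <- length(b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  if (is.null(exact)) exact <- n <= 12L
  if (exact) {
    sums <- combn_rank_sums(r, na)
    p <- min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
    method <- "exact enumeration"
  } else if (sigma2 > 0) {
    zc <- max(abs(W - mu) - 0.5, 0) / sqrt(sigma2)
    p <- 2 * pnorm(-zc)
    method <- "normal approximation with tie and continuity correction"
  } else {
    p <- 1
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = W, z = z, p = p, method = method)
}

combn_rank_sums <- function(r, na) {
  n <- length(r)
  if (na == n) return(sum(r))
  combn(n, na, function(ix) sum(r[ix]))
}

#' Pearson correlation with a t-based p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from the
#' t transform with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return List: `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Build a cross-validation plan
#'
#' Randomly partitions lesions into `n_folds` folds of as-equal-as-possible
#' size; each lesion appears in exactly one test fold. With
#' `stratified = TRUE` (default) class proportions are balanced across folds
#' while keeping total fold sizes within one of each other (with 116 lesions
#' and 11 folds: six folds of 11 and five of 10). Stratification degrades
#' gracefully when a class has fewer members than folds.
#'
#' @param lesion_ids vector of unique lesion identifiers.
#' @param labels class labels (required when `stratified = TRUE`).
#' @param n_folds number of folds (default 11); must not exceed the number
#'   of lesions.
#' @param seed RNG seed; the same seed yields the identical plan.
#' @param stratified balance classes across folds.
#' @return Data frame `id`, `label`, `fold` with attribute `n_folds`.
#' @export
make_cv_plan <- function(lesion_ids, labels = NULL, n_folds = 11L, seed = 1L,
                         stratified = TRUE) {
  n <- length(lesion_ids)
  n_folds <- as.integer(n_folds)
  if (anyDuplicated(lesion_ids)) stop("lesion ids must be unique", call. = FALSE)
  if (n_folds < 2L) stop("`n_folds` must be at least 2", call. = FALSE)
  if (n_folds > n)
    stop(sprintf("`n_folds` (%d) exceeds the number of lesions (%d)",
                 n_folds, n), call. = FALSE)
  if (stratified && is.null(labels))
    stop("stratified assignment requires `labels`", call. = FALSE)
  if (!is.null(labels) && length(labels) != n)
    stop("`labels` must match `lesion_ids` in length", call. = FALSE)

  fold <- integer(n)
  with_seed(seed, {
    if (!stratified) {
      fold[sample.int(n)] <- rep(seq_len(n_folds), length.out = n)
    } else {
      fold_tot <- integer(n_folds)
      for (cl in names(sort(table(labels), decreasing = TRUE))) {
        members <- which(labels == cl)
        m <- length(members)
        base <- m %/% n_folds
        extra <- m %% n_folds
        counts <- rep(base, n_folds)
        if (extra > 0L) {
          # remainders go to the folds with the smallest totals so far
          ord <- order(fold_tot, runif(n_folds))
          counts[ord[seq_len(extra)]] <- base + 1L
        }
        fold[members[sample.int(m)]] <- rep(seq_len(n_folds), counts)
        fold_tot <- fold_tot + counts
      }
    }
  })
  out <- data.frame(id = lesion_ids,
                    label = if (is.null(labels)) NA_character_ else labels,
                    fold = fold, stringsAsFactors = FALSE)
  attr(out, "n_folds") <- n_folds
  out
}

#' Cross-validated threshold evaluation of one feature
#'
#' For each fold, fits the ROC optimal threshold on the training portion
#' ([roc_analysis()]), applies it to the held-out test portion, and records
#' test sensitivity, specificity, accuracy and AUC; fold metrics are then
#' averaged arithmetically. A test or training fold containing a single
#' class is skipped with a warning and recorded.
#'
#' @param records data frame with columns `id`, `label`, and the feature.
#' @param feature_name name of the feature column to evaluate.
#' @param plan a [make_cv_plan()] covering all record ids.
#' @param positive positive class label.
#' @param orientation passed to [roc_analysis()] (fitted per training fold
#'   when `"auto"`).
#' @return List: `folds` (per-fold data frame), `average` (named numeric),
#'   `skipped` (fold indices skipped).
#' @export
cross_validated_auc <- function(records, feature_name, plan,
                                positive = "malignant",
                                orientation = "auto") {
  stopifnot(is.data.frame(records), feature_name %in% names(records))
  if (!all(records$id %in% plan$id))
    stop("plan does not cover all records", call. = FALSE)
  fold_of <- plan$fold[match(records$id, plan$id)]
  n_folds <- attr(plan, "n_folds")
  rows <- list()
  skipped <- integer(0)
  for (f in seq_len(n_folds)) {
    test <- records[fold_of == f, , drop = FALSE]
    train <- records[fold_of != f, , drop = FALSE]
    if (length(unique(train$label)) < 2L || length(unique(test$label)) < 2L) {
      warning(sprintf("fold %d skipped: a partition contains a single class", f))
      skipped <- c(skipped, f)
      next
    }
    roc_train <- roc_analysis(train[[feature_name]], train$label,
                              positive = positive, orientation = orientation)
    pred <- classify_roc(roc_train, test[[feature_name]])
    truth <- test$label == positive
    test_scores <- if (roc_train$orientation == "higher")
      test[[feature_name]] else -test[[feature_name]]
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f,
      auc_train = roc_train$auc,
      auc_test = auc_oriented(test_scores, truth),
      threshold = roc_train$threshold,
      sensitivity = mean(pred[truth]),
      specificity = mean(!pred[!truth]),
      accuracy = mean(pred == truth)
    )
  }
  if (length(rows) == 0L) stop("every fold was skipped", call. = FALSE)
  folds <- do.call(rbind, rows)
  avg <- colMeans(folds[, setdiff(names(folds), "fold"), drop = FALSE])
  list(folds = folds, average = avg, skipped = skipped)
}
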