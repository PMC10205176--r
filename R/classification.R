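#' Feature tables
#'
#' A feature table is a plain data.frame with a `subject_id` column, a `group`
#' column (labels `"AD"` / `"HC"`) and one numeric column per feature. These
#' helpers validate the layout and pull out the numeric matrix.
#'
#' @param df a data.frame with `subject_id`, `group` and numeric features.
#' @return `feature_table` returns the validated data.frame;
#'   `feature_matrix` the numeric matrix of features (rownames = subject ids).
#' @export
feature_table <- function(df) {
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop("feature table needs subject_id and group columns")
  }
  if (anyNA(df$group) || !all(df$group %in% c("AD", "HC"))) {
    stop("group labels must be AD or HC, no missing values")
  }
  feats <- setdiff(names(df), c("subject_id", "group"))
  if (length(feats) == 0L) stop("no feature columns")
  if (anyDuplicated(feats)) stop("feature names must be unique")
  m <- as.matrix(df[feats])
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("features must be finite numerics")
  }
  df
}

#' @rdname feature_table
#' @export
feature_matrix <- function(df) {
  feats <- setdiff(names(df), c("subject_id", "group"))
  m <- as.matrix(df[feats])
  rownames(m) <- df$subject_id
  m
}

#' Cap on the number of features for a given cohort
#'
#' Applies a samples-per-feature rule: with the default cohort-total reading,
#' `k = floor((n_a + n_b) / ratio)` (a 40-subject cohort at ratio 10 gives 4).
#' The stricter per-class reading `k = floor(min(n_a, n_b) / ratio)` is
#' available via `per_class = TRUE`.
#'
#' @param n_per_class integer length-2, subjects per class.
#' @param ratio samples required per retained feature (default 10).
#' @param per_class use the strict per-class reading (default FALSE).
#' @return integer k >= 1.
#' @export
#' @examples
#' max_features(c(19, 21))  # 4
max_features <- function(n_per_class, ratio = 10, per_class = FALSE) {
  if (any(n_per_class < 1) || ratio <= 0) stop("invalid counts or ratio")
  k <- if (per_class) floor(min(n_per_class) / ratio) else {
    floor(sum(n_per_class) / ratio)
  }
  if (k < 1) stop("cohort too small for even one feature at this ratio")
  as.integer(k)
}

#' Remove highly correlated features
#'
#' Zero-variance features are removed first. Then, while any pair of features
#' has `|Pearson r|` strictly above the threshold, the member of the
#' worst (most correlated) pair with the larger mean absolute correlation to
#' all other remaining features is dropped; ties are broken by dropping the
#' alphabetically later name, so the result is deterministic.
#'
#' @param table a [feature_table()].
#' @param threshold correlation threshold (default 0.9).
#' @return character vector of retained feature names.
#' @export
correlation_filter <- function(table, threshold = 0.9) {
  m <- feature_matrix(feature_table(table))
  if (nrow(m) < 2L) stop("need at least 2 subjects")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    message("dropping zero-variance features: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  keep <- colnames(m)
  while (length(keep) > 1L) {
    r <- abs(stats::cor(m[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- colSums(r) / (length(keep) - 1L)
    drop_name <- pair[order(-mean_abs[pair], pair)][1]
    keep <- setdiff(keep, drop_name)
  }
  keep
}

# Ridge-penalised logistic regression by Newton iteration on the penalised
# log-likelihood (intercept unpenalised). The objective is strictly convex,
# so the optimum is unique and exactly symmetric in duplicated columns —
# which makes the ranking's alphabetical tie-break well defined.
ridge_logistic <- function(x, y01, lambda, max_iter = 100, tol = 1e-10) {
  n <- nrow(x); p <- ncol(x)
  X <- cbind(1, x)
  beta <- numeric(p + 1)
  pen <- c(0, rep(lambda, p))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- crossprod(X, y01 - mu) / n - pen * beta
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) / n + diag(pen, p + 1)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta[-1]
}

#' Rank features by penalised logistic-regression importance
#'
#' Fits one ridge-penalised (light L2) logistic regression of the group label
#' on all z-scored features jointly; importance is the absolute standardized
#' coefficient. The penalty guarantees a finite fit even on separable data.
#' Ties are broken alphabetically.
#'
#' @param table a [feature_table()].
#' @param lambda ridge penalty on the standardized coefficients (default
#'   0.01).
#' @return data.frame with columns `feature` and `importance`, in descending
#'   importance order.
#' @export
rank_by_logistic <- function(table, lambda = 0.01) {
  table <- feature_table(table)
  if (length(unique(table$group)) < 2L) stop("both classes must be present")
  m <- feature_matrix(table)
  m <- scale(m)
  if (any(!is.finite(m))) stop("zero-variance feature: filter first")
  y01 <- as.numeric(table$group == "AD")
  beta <- abs(ridge_logistic(m, y01, lambda))
  out <- data.frame(feature = colnames(m), importance = beta)
  # coefficients equal up to solver round-off are ties, broken alphabetically
  out[order(-signif(out$importance, 10), out$feature), , drop = FALSE]
}

#' Full feature-selection stage
#'
#' Correlation filter, penalised-logistic ranking, then the top `k` features
#' where `k` comes from the samples-per-feature cap.
#'
#' @param table a [feature_table()].
#' @param ratio samples-per-feature ratio (default 10).
#' @param threshold correlation threshold (default 0.9).
#' @param per_class strict per-class cap reading (default FALSE).
#' @return list with `retained_after_correlation`, `ranking` (data.frame),
#'   `selected` (character, length `k`) and `k`.
#' @export
select_features <- function(table, ratio = 10, threshold = 0.9,
                            per_class = FALSE) {
  table <- feature_table(table)
  counts <- table(table$group)
  k <- max_features(as.integer(counts), ratio = ratio, per_class = per_class)
  retained <- correlation_filter(table, threshold = threshold)
  sub <- table[c("subject_id", "group", retained)]
  ranking <- rank_by_logistic(sub)
  selected <- utils::head(ranking$feature, k)
  list(retained_after_correlation = retained, ranking = ranking,
       selected = selected, k = k)
}

#' Leave-one-out cross-validated linear SVM
#'
#' For each subject in turn: z-score the selected features using the
#' remaining n-1 subjects only, train a linear soft-margin SVM on them and
#' predict the held-out subject, so every subject is classified exactly once
#' and no test information leaks into the fold's standardisation or fit.
#'
#' @param table a [feature_table()].
#' @param selected feature names to use.
#' @param cost SVM soft-margin cost parameter (default 1).
#' @return Object of class `loocv_result`: data.frame with `subject_id`,
#'   `truth`, `predicted`; attribute `n_folds`.
#' @export
loocv_svm <- function(table, selected, cost = 1) {
  table <- feature_table(table)
  if (length(selected) == 0L) stop("selected feature set is empty")
  if (min(table(table$group)) < 2L) stop("need >= 2 subjects per class")
  m <- feature_matrix(table)[, selected, drop = FALSE]
  y <- factor(table$group, levels = c("HC", "AD"))
  n <- nrow(m)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr_x <- m[-i, , drop = FALSE]
    tr_y <- y[-i]
    if (length(unique(tr_y)) < 2L) stop("training fold lost a class")
    mu <- colMeans(tr_x)
    sdv <- apply(tr_x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    z_tr <- sweep(sweep(tr_x, 2, mu), 2, sdv, "/")
    z_te <- (m[i, ] - mu) / sdv
    fit <- e1071::svm(z_tr, tr_y, kernel = "linear", cost = cost,
                      scale = FALSE)
    pred[i] <- as.character(stats::predict(fit, matrix(z_te, nrow = 1)))
  }
  out <- data.frame(subject_id = table$subject_id,
                    truth = as.character(y), predicted = pred)
  attr(out, "n_folds") <- n
  class(out) <- c("loocv_result", "data.frame")
  out
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity, specificity and balanced accuracy (mean of the
#' last two), with `"AD"` as the positive class by default. Undefined ratios
#' are reported as `NaN` with a warning.
#'
#' @param result a [loocv_svm()] result (or any data.frame with `truth` and
#'   `predicted` columns).
#' @param positive positive-class label (default `"AD"`).
#' @return named numeric vector: `accuracy`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`.
#' @export
performance_metrics <- function(result, positive = "AD") {
  truth <- result$truth
  pred <- result$predicted
  if (!any(truth == positive) || !any(truth != positive)) {
    stop("need at least one positive and one negative true label")
  }
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  ratio <- function(num, den) {
    if (den == 0) { warning("undefined performance ratio"); NaN } else num / den
  }
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2)
}

#' Cochran's Q test for k matched binary responses
#'
#' \deqn{Q = k(k-1) \sum_j (G_j - \bar G)^2 / (k \sum_i L_i - \sum_i L_i^2)}
#' with column totals \eqn{G_j} and row totals \eqn{L_i}; rows with all-equal
#' responses contribute nothing. `df = k - 1`; the p-value is the chi-square
#' upper tail. When the denominator is zero (all rows concordant) Q is
#' defined as 0 and p as 1. For k = 2 the statistic reduces to McNemar's
#' uncorrected \eqn{(b - c)^2 / (b + c)}.
#'
#' @param responses subjects x classifiers matrix of 0/1 (or logical) values.
#' @param alpha significance level for the rejection flag (default 0.05).
#' @return Object of class `cochran_q`: list with `Q`, `df`, `p_value`,
#'   `reject_at_alpha`, `alpha`.
#' @export
cochran_q <- function(responses, alpha = 0.05) {
  x <- as.matrix(responses) * 1
  if (!all(x %in% c(0, 1))) stop("responses must be binary")
  if (ncol(x) < 2L || nrow(x) < 2L) stop("need >= 2 classifiers and subjects")
  k <- ncol(x)
  G <- colSums(x)
  L <- rowSums(x)
  denom <- k * sum(L) - sum(L^2)
  Q <- if (denom == 0) 0 else k * (k - 1) * sum((G - mean(G))^2) / denom
  df <- k - 1L
  p <- if (denom == 0) 1 else stats::pchisq(Q, df, lower.tail = FALSE)
  structure(list(Q = Q, df = df, p_value = p,
                 reject_at_alpha = p < alpha, alpha = alpha),
            class = "cochran_q")
}

#' @export
print.cochran_q <- function(x, ...) {
  cat(sprintf("Cochran's Q: Q = %.4f, df = %d, p = %.4f (%s H0 at alpha = %g)\n",
              x$Q, x$df, x$p_value,
              if (x$reject_at_alpha) "reject" else "do not reject", x$alpha))
  invisible(x)
}

#' Compare two feature families as paired classifiers
#'
#' Runs the full selection stage and leave-one-out linear SVM independently
#' on each feature table (same subjects, same labels), computes performance
#' metrics for both, and compares the two classifiers with Cochran's Q on
#' their binary per-subject responses. The default response convention is
#' "predicted the positive class" (the null hypothesis that both classifiers
#' call the disease label equally often); `response = "correct"` compares
#' correctness instead.
#'
#' @param kinetic_table,texture_table [feature_table()]s over the same
#'   subjects (matched by `subject_id`).
#' @param ratio,threshold selection-stage parameters (defaults 10, 0.9).
#' @param cost SVM cost (default 1).
#' @param positive positive class (default `"AD"`).
#' @param response `"predicted_positive"` (default) or `"correct"`.
#' @param alpha significance level for the Q test flag.
#' @return Object of class `classifier_comparison`: list with `selection`
#'   (per family), `loocv` (per family), `metrics` (per family), `cochran`
#'   and `predictions` (one row per subject with both predictions).
#' @export
compare_classifiers <- function(kinetic_table, texture_table, ratio = 10,
                                threshold = 0.9, cost = 1, positive = "AD",
                                response = c("predicted_positive", "correct"),
                                alpha = 0.05) {
  response <- match.arg(response)
  kinetic_table <- feature_table(kinetic_table)
  texture_table <- feature_table(texture_table)
  texture_table <- texture_table[match(kinetic_table$subject_id,
                                       texture_table$subject_id), ]
  if (anyNA(texture_table$subject_id) ||
      !identical(kinetic_table$group, texture_table$group)) {
    stop("both tables must cover the same subjects with the same labels")
  }
  run_one <- function(tab) {
    sel <- select_features(tab, ratio = ratio, threshold = threshold)
    cv <- loocv_svm(tab, sel$selected, cost = cost)
    list(selection = sel, loocv = cv,
         metrics = performance_metrics(cv, positive = positive))
  }
  kin <- run_one(kinetic_table)
  tex <- run_one(texture_table)
  resp <- function(cv) {
    if (response == "predicted_positive") cv$predicted == positive
    else cv$predicted == cv$truth
  }
  q <- cochran_q(cbind(kinetic = resp(kin$loocv), texture = resp(tex$loocv)),
                 alpha = alpha)
  preds <- data.frame(subject_id = kin$loocv$subject_id,
                      truth = kin$loocv$truth,
                      pred_kinetic = kin$loocv$predicted,
                      pred_texture = tex$loocv$predicted)
  structure(list(selection = list(kinetic = kin$selection,
                                  texture = tex$selection),
                 loocv = list(kinetic = kin$loocv, texture = tex$loocv),
                 metrics = list(kinetic = kin$metrics, texture = tex$metrics),
                 cochran = q, predictions = preds,
                 response = response),
            class = "classifier_comparison")
}

#' @export
print.classifier_comparison <- function(x, ...) {
  cat("Classifier comparison (LOOCV linear SVM)\n")
  m <- rbind(kinetic = x$metrics$kinetic, texture = x$metrics$texture)
  print(round(m, 4))
  print(x$cochran)
  invisible(x)
}
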