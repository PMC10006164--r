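#' Overlay original and synthetic data in the original FAMD space
#'
#' Fits the projection on the original data only and places both datasets
#' in that space, the standard visual check that a synthetic dataset
#' occupies the same region as the data it imitates.
#'
#' @param original a `tabular_dataset`.
#' @param synthetic a `tabular_dataset` with the same schema.
#' @return list with `original` and `synthetic` full score matrices,
#'   `original_2d` / `synthetic_2d` (first two components), and the fitted
#'   `model`.
#' @export
overlay_coordinates <- function(original, synthetic) {
  chk <- validate_against(synthetic, original$schema)
  if (!chk$valid)
    avt_stop(paste("synthetic data does not match the original schema:",
                   paste(chk$issues, collapse = "; ")), "avt_schema_error")
  model <- fit_famd(original)
  oc <- famd_transform(model, original)
  sc <- famd_transform(model, synthetic)
  k2 <- seq_len(min(2L, model$ncomp))
  list(original = oc, synthetic = sc,
       original_2d = oc[, k2, drop = FALSE], synthetic_2d = sc[, k2, drop = FALSE],
       model = model)
}

#' Two-arm survival comparison (Kaplan-Meier, log-rank, Cox)
#'
#' Fits a single-covariate Cox proportional-hazards model (Efron ties),
#' reporting the hazard ratio with its 95% confidence interval and Wald
#' p-value, the per-arm Kaplan-Meier estimates and the log-rank test —
#' the comparison battery used to judge whether synthetic data preserve a
#' trial's treatment effect.
#'
#' @param data a `tabular_dataset`.
#' @param time_col name of the positive time-to-event column.
#' @param event_col name of the event indicator column (1/TRUE = event,
#'   0/FALSE = censored).
#' @param arm_col name of the binary arm column; the hazard ratio contrasts
#'   the second level against the first.
#' @return object of class `survival_comparison`: `hr`, `ci` (lower, upper),
#'   `wald_p`, `log_hr`, `km` (a [survival::survfit] object), `logrank_p`.
#' @export
survival_comparison <- function(data, time_col, event_col, arm_col) {
  df <- as.data.frame(data)
  time <- as.numeric(df[[time_col]])
  event <- df[[event_col]]
  event <- if (is.logical(event)) as.numeric(event) else as.numeric(as.character(event))
  arm <- df[[arm_col]]
  arm <- if (is.factor(arm)) droplevels(arm) else factor(arm)
  if (nlevels(arm) != 2L)
    avt_stop(sprintf("arm column '%s' must have exactly 2 observed levels", arm_col),
             "avt_utility_error")
  if (any(time <= 0))
    avt_stop("event times must be positive", "avt_utility_error")
  if (!all(event %in% c(0, 1)))
    avt_stop("event indicator must be binary", "avt_utility_error")
  ev_by_arm <- tapply(event, arm, sum)
  if (any(ev_by_arm == 0))
    avt_stop(sprintf("arm '%s' has no events; hazard ratio undefined",
                     names(ev_by_arm)[ev_by_arm == 0][1L]), "avt_utility_error")
  fit <- survival::coxph(survival::Surv(time, event) ~ arm, ties = "efron",
                         data = data.frame(time = time, event = event, arm = arm))
  s <- summary(fit)
  km <- survival::survfit(survival::Surv(time, event) ~ arm,
                          data = data.frame(time = time, event = event, arm = arm))
  lr <- survival::survdiff(survival::Surv(time, event) ~ arm,
                           data = data.frame(time = time, event = event, arm = arm))
  structure(list(
    hr = unname(exp(coef(fit))),
    ci = unname(exp(confint(fit))[1, ]),
    wald_p = unname(s$coefficients[1, "Pr(>|z|)"]),
    log_hr = unname(coef(fit)),
    arms = levels(arm),
    km = km,
    logrank_p = 1 - stats::pchisq(lr$chisq, length(lr$n) - 1L)),
    class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("HR (%s vs %s) = %.3f [95%% CI %.3f-%.3f], Wald p = %.3g, log-rank p = %.3g\n",
              x$arms[2], x$arms[1], x$hr, x$ci[1], x$ci[2], x$wald_p, x$logrank_p))
  invisible(x)
}

#' F-score of features against a binary outcome
#'
#' For feature i with overall mean `m`, class means `m+`/`m-` and class
#' sample variances `v+`/`v-`:
#' `F(i) = ((m+ - m)^2 + (m- - m)^2) / (v+ + v-)`,
#' the between-class squared deviation of the class means from the overall
#' mean over the summed within-class variances. Zero when a feature is
#' identical in both classes; invariant to row permutation.
#'
#' @param X numeric matrix or data frame of features.
#' @param y binary outcome (logical or two-level factor; the second level /
#'   TRUE is the positive class).
#' @return named numeric vector of F-scores.
#' @export
f_scores <- function(X, y) {
  X <- as.matrix(X)
  pos <- if (is.logical(y)) y else y == levels(factor(y))[2L]
  if (length(unique(pos)) < 2L)
    avt_stop("outcome has a single class", "avt_utility_error")
  m <- colMeans(X)
  mp <- colMeans(X[pos, , drop = FALSE]); mn <- colMeans(X[!pos, , drop = FALSE])
  vp <- apply(X[pos, , drop = FALSE], 2L, stats::var)
  vn <- apply(X[!pos, , drop = FALSE], 2L, stats::var)
  num <- (mp - m)^2 + (mn - m)^2
  out <- num / (vp + vn)
  out[num == 0] <- 0  # a feature identical in both classes scores 0, not 0/0
  out
}

#' Classification comparison: F-score feature ranking + radial SVM AUC
#'
#' Repeats a stratified 70/30 train/test split; on each training split it
#' computes F-scores for every feature, keeps the top `n_features`,
#' standardizes them on the training data, trains a radial-kernel SVM
#' (default regularization) and evaluates the area under the ROC curve on
#' the test split. AUC is reported on the percent scale.
#'
#' @param data a `tabular_dataset`.
#' @param outcome_col name of the binary outcome column.
#' @param n_repeats number of split repetitions (default 100).
#' @param n_features number of top features kept per repeat (default 5).
#' @param seed integer seed for the split sequence.
#' @return object of class `classification_comparison`: `auc_mean`,
#'   `auc_sd`, `auc_values`, `f_score_mean`, `f_score_ci` (95% normal CI
#'   per feature), `f_score_values` (repeats x features), `selection_freq`.
#' @export
classification_comparison <- function(data, outcome_col, n_repeats = 100,
                                      n_features = 5, seed = NULL) {
  df <- as.data.frame(data)
  y <- df[[outcome_col]]
  pos <- if (is.logical(y)) y else as.character(y) == sort(unique(as.character(y)))[2L]
  if (length(unique(pos)) < 2L)
    avt_stop("outcome has a single class", "avt_utility_error")
  feat_names <- setdiff(names(df), outcome_col)
  num_ok <- vapply(feat_names, function(nm) is.numeric(df[[nm]]) || inherits(df[[nm]], "Date"),
                   TRUE)
  feat_names <- feat_names[num_ok]
  X <- as.matrix(as.data.frame(lapply(df[feat_names], as.numeric)))
  colnames(X) <- feat_names
  n_features <- min(n_features, ncol(X))
  if (!is.null(seed)) set.seed(seed)

  idx_pos <- which(pos); idx_neg <- which(!pos)
  auc_values <- numeric(n_repeats)
  f_values <- matrix(NA_real_, n_repeats, ncol(X), dimnames = list(NULL, feat_names))
  sel <- matrix(FALSE, n_repeats, ncol(X), dimnames = list(NULL, feat_names))
  for (r in seq_len(n_repeats)) {
    tr <- c(sample(idx_pos, floor(0.7 * length(idx_pos))),
            sample(idx_neg, floor(0.7 * length(idx_neg))))
    te <- setdiff(seq_len(nrow(X)), tr)
    fs <- f_scores(X[tr, , drop = FALSE], pos[tr])  # Inf = perfect separation
    f_values[r, ] <- fs
    top <- order(fs, decreasing = TRUE)[seq_len(n_features)]
    sel[r, top] <- TRUE
    mu <- colMeans(X[tr, top, drop = FALSE])
    sg <- apply(X[tr, top, drop = FALSE], 2L, stats::sd)
    sg[sg == 0] <- 1
    scale_mat <- function(M) sweep(sweep(M, 2L, mu, "-"), 2L, sg, "/")
    fit <- e1071::svm(scale_mat(X[tr, top, drop = FALSE]), factor(pos[tr]),
                      kernel = "radial", scale = FALSE, probability = TRUE)
    pr <- attr(predict(fit, scale_mat(X[te, top, drop = FALSE]),
                       probability = TRUE), "probabilities")[, "TRUE"]
    roc <- pROC::roc(response = pos[te], predictor = as.numeric(pr),
                     levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    auc_values[r] <- 100 * as.numeric(pROC::auc(roc))
  }
  fm <- colMeans(f_values)
  fse <- apply(f_values, 2L, stats::sd) / sqrt(n_repeats)
  structure(list(
    auc_mean = mean(auc_values), auc_sd = stats::sd(auc_values),
    auc_values = auc_values,
    f_score_mean = fm,
    f_score_ci = rbind(lower = fm - 1.96 * fse, upper = fm + 1.96 * fse),
    f_score_values = f_values,
    selection_freq = colMeans(sel)),
    class = "classification_comparison")
}

#' @export
print.classification_comparison <- function(x, ...) {
  cat(sprintf("AUC = %.2f (sd %.2f) over %d stratified 70/30 splits\n",
              x$auc_mean, x$auc_sd, length(x$auc_values)))
  top <- sort(x$f_score_mean, decreasing = TRUE)
  cat("top F-scores:\n")
  for (nm in names(head(top, 5))) cat(sprintf("  %-20s %.3f\n", nm, top[[nm]]))
  invisible(x)
}
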