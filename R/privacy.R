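#' Distance to closest record (DCR)
#'
#' For every synthetic record, the Euclidean distance to its nearest real
#' record in the shared projection space. Higher distances mean synthetic
#' points sit further from any real individual.
#'
#' @param real_coords numeric matrix of real-record coordinates.
#' @param synth_coords numeric matrix of synthetic-record coordinates (same
#'   column count).
#' @return list with `values` (one distance per synthetic record) and
#'   `summary` (median, 5% and 95% quantiles).
#' @export
dcr <- function(real_coords, synth_coords) {
  real_coords <- as.matrix(real_coords); synth_coords <- as.matrix(synth_coords)
  if (nrow(real_coords) < 1L)
    avt_stop("DCR needs at least one real record", "avt_metric_error")
  D <- cross_dist(synth_coords, real_coords)
  v <- apply(D, 1L, min)
  list(values = v, summary = summarize_metric(v))
}

#' Nearest-neighbor distance ratio (NNDR)
#'
#' Per synthetic record, the ratio of the nearest to second-nearest real
#' record distance. Bounded in \[0, 1\]; values near 1 mean the synthetic
#' point is not isolated next to a unique real record. When the two nearest
#' real records coincide with the synthetic point (duplicates, both
#' distances zero) the ratio is defined as 1, the maximally non-isolated
#' case.
#'
#' @inheritParams dcr
#' @return list with `values` and `summary` (median, q0.05, q0.95).
#' @export
nndr <- function(real_coords, synth_coords) {
  real_coords <- as.matrix(real_coords); synth_coords <- as.matrix(synth_coords)
  if (nrow(real_coords) < 2L)
    avt_stop("NNDR needs at least two real records", "avt_metric_error")
  D <- cross_dist(synth_coords, real_coords)
  v <- apply(D, 1L, function(d) {
    two <- sort(d, partial = 1:2)[1:2]
    if (two[2L] == 0) 1 else two[1L] / two[2L]
  })
  list(values = v, summary = summarize_metric(v))
}

#' Local cloaking
#'
#' For each original record, counts the avatar records strictly closer to it
#' than its own avatar. A count of 0 means a nearest-avatar linkage attack
#' identifies the true avatar; ties with the own avatar do not hide the
#' individual (strict inequality, conservative for the attacker).
#'
#' @param original_coords coordinates of the original records.
#' @param avatar_coords coordinates of the avatar records (same space).
#' @param linkage integer vector: original row i's avatar is avatar row
#'   `linkage[i]` (a bijection).
#' @return list with `values` (integer counts in `[0, n-1]`) and `median`.
#' @export
local_cloaking <- function(original_coords, avatar_coords, linkage) {
  original_coords <- as.matrix(original_coords)
  avatar_coords <- as.matrix(avatar_coords)
  n <- nrow(original_coords)
  if (length(linkage) != n || anyNA(linkage) ||
      !setequal(linkage, seq_len(nrow(avatar_coords))))
    avt_stop("linkage must be a bijection between original and avatar rows",
             "avt_metric_error")
  D <- cross_dist(original_coords, avatar_coords)
  own <- D[cbind(seq_len(n), linkage)]
  counts <- as.integer(rowSums(D < own))  # own column contributes 0 (d < d is FALSE)
  list(values = counts, median = stats::median(counts))
}

#' Hidden rate
#'
#' Percentage of original records whose avatar is not their closest avatar,
#' i.e. whose local cloaking is at least 1: the probability that a
#' distance-based linkage attack picks the wrong avatar.
#'
#' @param local_cloaking_counts integer vector of local cloaking counts.
#' @return percentage in `[0, 100]`.
#' @export
hidden_rate <- function(local_cloaking_counts) {
  100 * mean(local_cloaking_counts >= 1)
}

#' Full privacy report for an avatar run
#'
#' All distances are computed in the full-rank FAMD space fitted on the
#' original data (the model carried by the avatar run); the avatar records
#' are projected into that space with the model's stored centers and
#' scales. The report records the space descriptor so audits are
#' reproducible.
#'
#' @param original the original `tabular_dataset`.
#' @param avatar an `avatar_dataset` from [generate_avatars()].
#' @return object of class `privacy_report` with DCR, NNDR, local cloaking
#'   and hidden rate.
#' @export
privacy_report <- function(original, avatar) {
  stopifnot(inherits(avatar, "avatar_dataset"))
  model <- avatar$model
  oc <- famd_transform(model, original)
  ac <- famd_transform(model, avatar$data)
  d <- dcr(oc, ac)
  r <- nndr(oc, ac)
  lc <- local_cloaking(oc, ac, avatar$linkage)
  structure(list(
    dcr = d, nndr = r, local_cloaking = lc,
    hidden_rate = hidden_rate(lc$values),
    space = list(ncomp = model$ncomp, nd_search = avatar$nd_used,
                 distance = avatar$config$distance)),
    class = "privacy_report")
}

#' @export
print.privacy_report <- function(x, ...) {
  cat("<privacy_report>\n")
  cat(sprintf("  DCR    median %.4g  [q05 %.4g, q95 %.4g]\n",
              x$dcr$summary["median"], x$dcr$summary["q05"], x$dcr$summary["q95"]))
  cat(sprintf("  NNDR   median %.4g  [q05 %.4g, q95 %.4g]\n",
              x$nndr$summary["median"], x$nndr$summary["q05"], x$nndr$summary["q95"]))
  cat(sprintf("  local cloaking median %g\n", x$local_cloaking$median))
  cat(sprintf("  hidden rate %.1f%%\n", x$hidden_rate))
  invisible(x)
}

# Serializable view of a report: summaries and per-record arrays, never the
# linkage map.
privacy_report_as_list <- function(x) {
  list(dcr = list(summary = as.list(x$dcr$summary), values = x$dcr$values),
       nndr = list(summary = as.list(x$nndr$summary), values = x$nndr$values),
       local_cloaking = list(median = x$local_cloaking$median,
                             values = x$local_cloaking$values),
       hidden_rate = x$hidden_rate,
       space = x$space)
}

summarize_metric <- function(v) {
  c(median = stats::median(v),
    q05 = unname(stats::quantile(v, 0.05)),
    q95 = unname(stats::quantile(v, 0.95)))
}

# Cross Euclidean distance matrix (rows of A x rows of B). Computed from
# explicit differences, not the quadratic expansion, so coincident points
# give exactly zero and duplicates are detected reliably.
cross_dist <- function(A, B) {
  tB <- t(B)
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    out[i, ] <- sqrt(colSums((tB - A[i, ])^2))
  out
}
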