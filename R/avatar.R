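#' Configuration of an avatar generation run
#'
#' Two families of parameters control the generator. Local-environment
#' parameters: `k` (neighborhood size), `nd` (number of leading components
#' used for the neighbor search; `"auto"` picks the smallest count reaching
#' 90% cumulative explained variance), `distance` (plain Euclidean, or
#' Mahalanobis implemented as Euclidean distance on variance-standardized
#' component scores, which is its definition in an orthogonal factor basis)
#' and per-variable `column_weights`. Stochasticity parameters: the
#' `contribution_law` over neighbors (`"halving"` assigns contributions
#' 1/2, 1/4, ..., 1/2^k in a uniformly shuffled order; `"equal"` gives every
#' neighbor contribution 1), the `exponential_rate` of the random factor,
#' and an experimental per-variable `perturbation_level`.
#'
#' @param k number of nearest neighbors (>= 1, <= n-1 at run time).
#' @param nd integer >= 1 or `"auto"`.
#' @param distance `"euclidean"` or `"mahalanobis"`.
#' @param contribution_law `"halving"` or `"equal"`.
#' @param exponential_rate rate of the exponential random factor, default 1.
#' @param column_weights optional named positive projection weights.
#' @param perturbation_level value in `[0, 1]` (scalar or named per
#'   variable): convex shrinkage of each avatar value toward the unweighted
#'   neighbor centroid. Default 0 (off); experimental.
#' @param seed integer seed driving every random draw of the run.
#' @return an object of class `avatar_config`.
#' @export
avatar_config <- function(k = 20, nd = "auto",
                          distance = c("euclidean", "mahalanobis"),
                          contribution_law = c("halving", "equal"),
                          exponential_rate = 1, column_weights = NULL,
                          perturbation_level = 0, seed = NULL) {
  distance <- match.arg(distance)
  contribution_law <- match.arg(contribution_law)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
    avt_stop("k must be an integer >= 1", "avt_config_error")
  if (!identical(nd, "auto") &&
      (!is.numeric(nd) || length(nd) != 1L || nd < 1 || nd != floor(nd)))
    avt_stop("nd must be an integer >= 1 or \"auto\"", "avt_config_error")
  if (!is.numeric(exponential_rate) || exponential_rate <= 0)
    avt_stop("exponential_rate must be > 0", "avt_config_error")
  if (any(perturbation_level < 0) || any(perturbation_level > 1))
    avt_stop("perturbation_level must lie in [0, 1]", "avt_config_error")
  structure(list(k = as.integer(k), nd = nd, distance = distance,
                 contribution_law = contribution_law,
                 exponential_rate = exponential_rate,
                 column_weights = column_weights,
                 perturbation_level = perturbation_level,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "avatar_config")
}

#' Exact k-nearest-neighbor search with deterministic tie-breaks
#'
#' Brute-force all-pairs search (no approximation). Each row's own index is
#' excluded; equal distances are broken by the lower row index.
#'
#' @param coords numeric matrix of coordinates (rows = individuals). Only
#'   the first `nd` columns are used.
#' @param k neighbors per row.
#' @param nd number of leading columns used (default: all).
#' @return list with integer matrix `indices` (n x k) and numeric matrix
#'   `distances` (n x k, non-decreasing within each row).
#' @export
find_neighbors <- function(coords, k, nd = ncol(coords)) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k > n - 1L)
    avt_stop(sprintf("k = %d exceeds n - 1 = %d", k, n - 1L), "avt_config_error")
  nd <- min(nd, ncol(coords))
  D <- as.matrix(stats::dist(coords[, seq_len(nd), drop = FALSE]))
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(n))[seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- d[ord]
  }
  list(indices = idx, distances = dst,
       median_positive_distance = stats::median(D[upper.tri(D)][D[upper.tri(D)] > 0]))
}

#' Neighbor weights from distances, contributions and random factors
#'
#' The deterministic kernel of the weight draw: given the k neighbor
#' distances, a shuffled contribution exponent vector `j` and random factors
#' `R`, each raw weight is the product of the inverse distance, the random
#' factor and the contribution `(1/2)^j`; weights are then normalized to sum
#' to one.
#'
#' @param distances positive neighbor distances (length k).
#' @param shuffle permutation of `1:k` giving each neighbor's contribution
#'   exponent (ignored under `contribution_law = "equal"`).
#' @param R positive random factors (length k).
#' @param contribution_law `"halving"` or `"equal"`.
#' @return list with `P` (raw products) and `W` (normalized weights).
#' @export
avatar_weights <- function(distances, shuffle, R,
                           contribution_law = c("halving", "equal")) {
  contribution_law <- match.arg(contribution_law)
  if (any(distances <= 0))
    avt_stop("non-positive neighbor distance; apply the zero-distance floor first",
             "avt_weight_error")
  C <- if (contribution_law == "halving") 0.5^shuffle else rep(1, length(distances))
  P <- (1 / distances) * R * C
  list(P = P, W = P / sum(P))
}

#' Draw normalized neighbor weights
#'
#' Consumes the current RNG stream: first the contribution shuffle, then the
#' exponential random factors (this draw order is fixed for
#' reproducibility).
#'
#' @param distances positive neighbor distances.
#' @param config an [avatar_config()].
#' @return normalized weight vector summing to one.
#' @export
draw_weights <- function(distances, config) {
  k <- length(distances)
  shuffle <- if (k > 1L) sample.int(k) else 1L
  R <- stats::rexp(k, rate = config$exponential_rate)
  avatar_weights(distances, shuffle, R, config$contribution_law)$W
}

#' Generate one avatar dataset
#'
#' Runs the full generation pipeline: fit the FAMD model on the original
#' data, search each row's k nearest neighbors in the leading `nd`
#' components, draw normalized stochastic weights per row, place the avatar
#' at the weighted center of the neighbors' full-rank coordinates,
#' reconstruct schema values by the inverse projection, and shuffle the
#' output rows to sever the positional link with the originals. The
#' pre-shuffle linkage is retained in the returned object (for metric
#' computation only) and is never written to disk.
#'
#' Zero distances (exact duplicate records) are floored at
#' `1e-9 * median positive pairwise distance` in the search space, so
#' duplicates receive the largest finite inverse-distance weight instead of
#' breaking the weight computation.
#'
#' @param original a [tabular_dataset()].
#' @param config an [avatar_config()].
#' @return an object of class `avatar_dataset` with fields `data` (shuffled
#'   `tabular_dataset`), `linkage` (original row i -> row of its avatar in
#'   `data`), `permutation`, `model`, `nd_used`, `config`.
#' @export
generate_avatars <- function(original, config = avatar_config()) {
  stopifnot(inherits(original, "tabular_dataset"), inherits(config, "avatar_config"))
  n <- original$n
  if (config$k > n - 1L)
    avt_stop(sprintf("k = %d exceeds n - 1 = %d", config$k, n - 1L), "avt_config_error")
  if (!is.null(config$seed)) set.seed(config$seed)

  model <- fit_famd(original, config$column_weights)
  full_coords <- famd_transform(model, original)
  nd <- if (identical(config$nd, "auto")) choose_nd(model) else min(config$nd, model$ncomp)

  search_coords <- full_coords
  if (config$distance == "mahalanobis")
    search_coords <- sweep(search_coords, 2L, model$component_sd, "/")
  nb <- find_neighbors(search_coords, config$k, nd = nd)

  eps <- 1e-9 * nb$median_positive_distance
  if (!is.finite(eps) || eps <= 0) eps <- 1e-12
  dists <- pmax(nb$distances, eps)

  avatar_coords <- matrix(0, n, model$ncomp)
  centroid_coords <- matrix(0, n, model$ncomp)
  weights <- matrix(0, n, config$k)
  for (i in seq_len(n)) {
    W <- draw_weights(dists[i, ], config)
    weights[i, ] <- W
    nbr <- full_coords[nb$indices[i, ], , drop = FALSE]
    avatar_coords[i, ] <- as.numeric(crossprod(W, nbr))
    centroid_coords[i, ] <- colMeans(nbr)
  }

  avatar_ds <- decode_with_perturbation(model, avatar_coords, centroid_coords,
                                        config$perturbation_level)
  perm <- sample.int(n)
  shuffled <- ds_subset(avatar_ds, perm)
  linkage <- match(seq_len(n), perm)  # avatar of original i sits at row linkage[i]

  structure(list(data = shuffled, linkage = linkage, permutation = perm,
                 model = model, nd_used = nd, neighbors = nb$indices,
                 weights = weights, config = config),
            class = "avatar_dataset")
}

# Perturbation (experimental): per-variable convex shrinkage of the avatar's
# reconstructed value toward the unweighted neighbor centroid, applied in
# encoded space before decoding. level = 0 leaves the weighted center as is.
decode_with_perturbation <- function(model, avatar_coords, centroid_coords, level) {
  if (all(level == 0))
    return(famd_inverse_transform(model, avatar_coords))
  alpha <- rep(0, length(model$centers))
  for (nm in names(model$column_map)) {
    a <- if (length(level) == 1L) level else (level[[nm]] %||% 0)
    alpha[model$column_map[[nm]]$cols] <- a
  }
  Za <- avatar_coords %*% t(model$axes)
  Zc <- centroid_coords %*% t(model$axes)
  Z <- sweep(Za, 2L, 1 - alpha, "*") + sweep(Zc, 2L, alpha, "*")
  raw <- sweep(sweep(Z, 2L, model$weights, "/"), 2L, model$scales, "*")
  raw <- sweep(raw, 2L, model$centers, "+")
  decode_encoded(model, raw)
}

#' @export
print.avatar_dataset <- function(x, ...) {
  cat(sprintf("<avatar_dataset> %d rows x %d columns (k = %d, nd = %d, %s)\n",
              x$data$n, x$data$p, x$config$k, x$nd_used, x$config$distance))
  invisible(x)
}

#' Run an end-to-end avatarization with file outputs
#'
#' Reads the input (CSV path or `tabular_dataset`), generates the avatar
#' dataset, computes the privacy report, and writes the avatar CSV, a JSON
#' metrics report and a JSON run manifest (configuration, seed, package
#' version). The original-to-avatar linkage map exists only in memory and is
#' deliberately absent from every file written.
#'
#' @param input CSV path or `tabular_dataset`.
#' @param config an [avatar_config()].
#' @param output path of the avatar CSV to write.
#' @param schema optional schema (list or YAML path) for reading `input`.
#' @param report_path optional path for the JSON privacy report.
#' @param manifest_path optional path for the JSON run manifest.
#' @return the [privacy_report()] of the run, invisibly.
#' @export
avatarize <- function(input, config = avatar_config(), output,
                      schema = NULL, report_path = NULL, manifest_path = NULL) {
  original <- if (inherits(input, "tabular_dataset")) input
              else read_dataset(input, schema = schema)
  av <- generate_avatars(original, config)
  write_dataset(av$data, output)
  rep <- privacy_report(original, av)
  if (!is.null(report_path)) {
    jsonlite::write_json(privacy_report_as_list(rep), report_path,
                         digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(manifest_path)) {
    manifest <- list(
      software = "avatarize", version = as.character(utils::packageVersion("avatarize")),
      seed = config$seed, k = config$k, nd = config$nd, nd_used = av$nd_used,
      distance = config$distance, contribution_law = config$contribution_law,
      exponential_rate = config$exponential_rate,
      perturbation_level = config$perturbation_level,
      n = original$n, p = original$p)
    jsonlite::write_json(manifest, manifest_path, digits = NA, auto_unbox = TRUE,
                         null = "null")
  }
  invisible(rep)
}
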