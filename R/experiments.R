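#' Repeated avatarization: stochasticity of the re-identification risk
#'
#' Runs `n_runs` independent avatarizations (run r uses seed
#' `base_seed + r - 1`) and, for every original individual, counts the runs
#' in which a distance-based linkage attack would have re-identified them
#' (local cloaking equal to 0). A protected dataset shows low counts for
#' (almost) every individual: re-identification, when it happens, happens
#' at random across runs rather than repeatedly for the same people.
#'
#' @param data a `tabular_dataset`.
#' @param n_runs number of independent avatarizations (default 25).
#' @param config template [avatar_config()]; its seed is overridden per run.
#' @param base_seed integer base seed.
#' @return object of class `repeated_avatarization`: `zero_counts` (per
#'   individual, in `[0, n_runs]`), `histogram` (table of counts),
#'   `hidden_rates` and `median_cloakings` per run.
#' @export
repeated_avatarization <- function(data, n_runs = 25, config = avatar_config(),
                                   base_seed = 1) {
  zero_counts <- integer(data$n)
  hidden_rates <- numeric(n_runs)
  medians <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r - 1L)
    av <- generate_avatars(data, cfg)
    oc <- famd_transform(av$model, data)
    ac <- famd_transform(av$model, av$data)
    lc <- local_cloaking(oc, ac, av$linkage)
    zero_counts <- zero_counts + (lc$values == 0L)
    hidden_rates[r] <- hidden_rate(lc$values)
    medians[r] <- lc$median
  }
  structure(list(zero_counts = zero_counts,
                 histogram = table(factor(zero_counts, levels = 0:n_runs)),
                 hidden_rates = hidden_rates, median_cloakings = medians,
                 n_runs = n_runs),
            class = "repeated_avatarization")
}

#' Sweep the neighborhood size k
#'
#' For each k, runs `n_runs` seeded avatarizations and records the
#' configured utility endpoint together with the local cloaking
#' distribution, tracing the utility/privacy balance as the local model
#' grows from a handful of neighbors to a large fraction of the dataset.
#'
#' @param data a `tabular_dataset`.
#' @param k_values ascending integer vector of neighborhood sizes.
#' @param n_runs avatarizations per k (default 10).
#' @param endpoint optional function `tabular_dataset -> numeric scalar`
#'   (e.g. a hazard ratio or an AUC); `NA` is recorded if it errors.
#' @param config template [avatar_config()].
#' @param base_seed integer base seed; run r of k index j uses seed
#'   `base_seed + 1000 * (j - 1) + r - 1`, so adding k values or runs never
#'   perturbs earlier ones.
#' @return object of class `k_sweep`: tidy per-run data frame `runs`
#'   (k, run, seed, endpoint, median_cloaking, hidden_rate) and a
#'   `summary` data frame with endpoint means and 95% CI per k.
#' @export
k_sweep <- function(data, k_values, n_runs = 10, endpoint = NULL,
                    config = avatar_config(), base_seed = 1) {
  if (is.unsorted(k_values))
    avt_stop("k_values must be ascending", "avt_config_error")
  if (max(k_values) > data$n - 1L)
    avt_stop("largest k exceeds n - 1", "avt_config_error")
  rows <- list()
  for (j in seq_along(k_values)) {
    for (r in seq_len(n_runs)) {
      cfg <- config
      cfg$k <- as.integer(k_values[j])
      cfg$seed <- as.integer(base_seed + 1000L * (j - 1L) + r - 1L)
      av <- generate_avatars(data, cfg)
      oc <- famd_transform(av$model, data)
      ac <- famd_transform(av$model, av$data)
      lc <- local_cloaking(oc, ac, av$linkage)
      ep <- NA_real_
      if (!is.null(endpoint))
        ep <- tryCatch(as.numeric(endpoint(av$data)), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k_values[j], run = r, seed = cfg$seed, endpoint = ep,
        median_cloaking = lc$median, hidden_rate = hidden_rate(lc$values))
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, runs$k), function(g) {
    m <- mean(g$endpoint); se <- stats::sd(g$endpoint) / sqrt(nrow(g))
    data.frame(k = g$k[1L], endpoint_mean = m,
               endpoint_lo = m - 1.96 * se, endpoint_hi = m + 1.96 * se,
               median_cloaking = stats::median(g$median_cloaking),
               hidden_rate = mean(g$hidden_rate))
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ), class = "k_sweep")
}

#' DCR/NNDR sampling protocol with a holdout baseline
#'
#' Draws `n_samples` seeded 70/30 partitions of the original data. On each
#' partition a synthetic dataset is generated from the 70% sample, and
#' DCR/NNDR are computed between the synthetic data and the sample; as the
#' "real data versus itself" reference, DCR/NNDR are also computed between
#' the 30% holdout and the same sample. Per-record values are pooled across
#' partitions and summarized by the median and the 0.05/0.95 quantiles.
#' Distances live in the full-rank FAMD space fitted on each 70% sample.
#'
#' @param data a `tabular_dataset`.
#' @param generator function `(tabular_dataset, seed) -> tabular_dataset`
#'   producing schema-conforming synthetic data; defaults to the avatar
#'   generator with `config`. Any external method honoring the contract can
#'   be slotted in.
#' @param n_samples number of 70% samples (default 10).
#' @param frac sampling fraction (default 0.7).
#' @param config [avatar_config()] used by the default generator.
#' @param base_seed integer base seed; sample r uses sampling seed
#'   `base_seed + 500000 + r` and generation seed `base_seed + r`.
#' @return object of class `dcr_nndr_protocol`: pooled `synthetic` and
#'   `holdout` summaries (`dcr_summary`, `nndr_summary`, pooled values).
#' @export
dcr_nndr_protocol <- function(data, generator = NULL, n_samples = 10,
                              frac = 0.7, config = avatar_config(),
                              base_seed = 1) {
  if (frac <= 0 || frac >= 1)
    avt_stop("sampling fraction must lie in (0, 1)", "avt_config_error")
  if (is.null(generator)) {
    generator <- function(ds, seed) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      generate_avatars(ds, cfg)$data
    }
  }
  syn_dcr <- c(); syn_nndr <- c(); hold_dcr <- c(); hold_nndr <- c()
  for (r in seq_len(n_samples)) {
    set.seed(as.integer(base_seed + 500000L + r))
    idx <- sample.int(data$n, floor(frac * data$n))
    train <- ds_subset(data, sort(idx))
    hold <- ds_subset(data, setdiff(seq_len(data$n), idx))
    synth <- generator(train, base_seed + r)
    model <- fit_famd(train)
    tc <- famd_transform(model, train)
    sc <- famd_transform(model, synth)
    hc <- famd_transform(model, hold)
    syn_dcr <- c(syn_dcr, dcr(tc, sc)$values)
    syn_nndr <- c(syn_nndr, nndr(tc, sc)$values)
    hold_dcr <- c(hold_dcr, dcr(tc, hc)$values)
    hold_nndr <- c(hold_nndr, nndr(tc, hc)$values)
  }
  structure(list(
    synthetic = list(dcr_values = syn_dcr, nndr_values = syn_nndr,
                     dcr_summary = summarize_metric(syn_dcr),
                     nndr_summary = summarize_metric(syn_nndr)),
    holdout = list(dcr_values = hold_dcr, nndr_values = hold_nndr,
                   dcr_summary = summarize_metric(hold_dcr),
                   nndr_summary = summarize_metric(hold_nndr)),
    n_samples = n_samples, frac = frac),
    class = "dcr_nndr_protocol")
}

#' @export
print.dcr_nndr_protocol <- function(x, ...) {
  cat(sprintf("<dcr_nndr_protocol> %d samples at %.0f%%\n", x$n_samples, 100 * x$frac))
  cat(sprintf("  synthetic: DCR median %.3g, NNDR median %.3g\n",
              x$synthetic$dcr_summary["median"], x$synthetic$nndr_summary["median"]))
  cat(sprintf("  holdout:   DCR median %.3g, NNDR median %.3g\n",
              x$holdout$dcr_summary["median"], x$holdout$nndr_summary["median"]))
  invisible(x)
}
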