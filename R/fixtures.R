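#' Mixed-type clustered fixture
#'
#' Seeded generator of a mixed continuous/categorical dataset with known
#' Gaussian-mixture structure, the kind of cluster-plus-outlier geometry
#' biomedical cohorts show in a factor projection. Cluster labels are drawn
#' from the mixture weights, continuous columns from per-cluster Gaussians,
#' categorical columns from per-cluster multinomials; a stated fraction of
#' exact duplicate rows can be appended to exercise zero-distance handling.
#'
#' @param n rows before duplication (default 1000).
#' @param weights mixture weights (sum to 1); default two balanced clusters.
#' @param means matrix (clusters x continuous variables) of cluster means;
#'   default two well-separated 3-D clusters.
#' @param sds matrix like `means` of per-cluster standard deviations
#'   (default 1).
#' @param cat_probs list of per-categorical-variable probability matrices
#'   (clusters x levels); default one 3-level variable tilted by cluster.
#' @param duplicate_frac fraction in `[0, 1)` of exact duplicate rows to
#'   append (default 0).
#' @param seed integer seed.
#' @return a `tabular_dataset` with a `cluster` categorical column last.
#' @export
generate_mixed <- function(n = 1000,
                           weights = c(0.5, 0.5),
                           means = rbind(c(0, 0, 0), c(6, 6, 6)),
                           sds = NULL,
                           cat_probs = list(g1 = rbind(c(0.7, 0.2, 0.1),
                                                       c(0.1, 0.2, 0.7))),
                           duplicate_frac = 0,
                           seed = 1) {
  if (abs(sum(weights) - 1) > 1e-8)
    avt_stop("mixture weights must sum to 1", "avt_fixture_error")
  if (duplicate_frac < 0 || duplicate_frac >= 1)
    avt_stop("duplicate_frac must lie in [0, 1)", "avt_fixture_error")
  nc <- length(weights)
  means <- as.matrix(means)
  if (is.null(sds)) sds <- matrix(1, nc, ncol(means))
  sds <- as.matrix(sds)
  if (any(sds <= 0)) avt_stop("standard deviations must be positive", "avt_fixture_error")
  set.seed(as.integer(seed))
  z <- sample.int(nc, n, replace = TRUE, prob = weights)
  cont <- sapply(seq_len(ncol(means)), function(j)
    stats::rnorm(n, mean = means[z, j], sd = sds[z, j]))
  df <- as.data.frame(cont)
  names(df) <- paste0("x", seq_len(ncol(means)))
  for (nm in names(cat_probs)) {
    P <- as.matrix(cat_probs[[nm]])
    levs <- colnames(P) %||% paste0("L", seq_len(ncol(P)))
    df[[nm]] <- vapply(seq_len(n), function(i)
      sample(levs, 1L, prob = P[z[i], ]), "")
  }
  df$cluster <- paste0("c", z)
  if (duplicate_frac > 0) {
    ndup <- floor(n * duplicate_frac)
    src <- sample.int(n, ndup, replace = TRUE)
    df <- rbind(df, df[src, , drop = FALSE])
    rownames(df) <- NULL
  }
  schema <- c(
    lapply(paste0("x", seq_len(ncol(means))), variable_spec, vtype = "continuous"),
    lapply(names(cat_probs), function(nm) {
      P <- as.matrix(cat_probs[[nm]])
      variable_spec(nm, "categorical",
                    categories = colnames(P) %||% paste0("L", seq_len(ncol(P))))
    }),
    list(variable_spec("cluster", "categorical",
                       categories = paste0("c", seq_len(nc)))))
  tabular_dataset(df, schema = schema)
}

#' Two-arm survival fixture with a known hazard ratio
#'
#' Arm assignment is Bernoulli(0.5); event times are exponential with a
#' rate ratio equal to the target hazard ratio (arm 1 versus arm 0);
#' censoring times are independent Uniform(0, b), with b calibrated by root
#' finding so the expected censoring fraction matches `censoring`. Two
#' continuous noise covariates are included so the table has mixed
#' structure worth projecting.
#'
#' @param n rows (default 2000).
#' @param hr target hazard ratio of arm 1 vs arm 0 (> 0, default 0.5).
#' @param base_rate exponential event rate in arm 0 (default 0.1).
#' @param censoring target censoring fraction in `[0, 1)` (default 0.2).
#' @param seed integer seed.
#' @return a `tabular_dataset` with columns `time` (continuous), `event`
#'   (boolean), `arm` (categorical "0"/"1"), `z1`, `z2` (continuous noise).
#' @export
generate_survival <- function(n = 2000, hr = 0.5, base_rate = 0.1,
                              censoring = 0.2, seed = 1) {
  if (hr <= 0) avt_stop("target hazard ratio must be > 0", "avt_fixture_error")
  if (censoring < 0 || censoring >= 1)
    avt_stop("censoring rate must lie in [0, 1)", "avt_fixture_error")
  set.seed(as.integer(seed))
  arm <- stats::rbinom(n, 1L, 0.5)
  rate <- base_rate * hr^arm
  t_event <- stats::rexp(n, rate = rate)
  if (censoring == 0) {
    time <- t_event; event <- rep(TRUE, n)
  } else {
    # P(C < T) for C ~ U(0,b), T ~ Exp(lambda): (1 - (1 - exp(-lambda b)) / (lambda b)),
    # averaged over the two arms; solve for b.
    cens_prob <- function(b) {
      mean(vapply(c(base_rate, base_rate * hr), function(l)
        (1 - exp(-l * b)) / (l * b), 0)) - censoring
    }
    b <- stats::uniroot(cens_prob, lower = 1e-6, upper = 1e6)$root
    cens <- stats::runif(n, 0, b)
    event <- t_event <= cens
    time <- pmin(t_event, cens)
  }
  df <- data.frame(time = time, event = event, arm = as.character(arm),
                   z1 = stats::rnorm(n), z2 = stats::rnorm(n),
                   stringsAsFactors = FALSE)
  schema <- list(variable_spec("time", "continuous"),
                 variable_spec("event", "boolean"),
                 variable_spec("arm", "categorical", categories = c("0", "1")),
                 variable_spec("z1", "continuous"),
                 variable_spec("z2", "continuous"))
  tabular_dataset(df, schema = schema)
}

#' Graded-feature classification fixture
#'
#' Emulates an observational study with ordinal imaging grades: features
#' are Gaussian draws around class-conditional means, rounded and clipped
#' to the 1-10 integer scale, with class separation controlled per feature
#' by `effect_sizes` (difference of class means in SD units). An optional
#' perfectly separating feature takes value 2 in the negative and 9 in the
#' positive class.
#'
#' @param n rows (default 600).
#' @param effect_sizes named or unnamed numeric vector of per-feature class
#'   mean offsets (default `c(3, 2, 1, 0.5, 0)`).
#' @param prevalence positive-class probability (default 0.35).
#' @param separable add a perfectly separating feature `sep` (default
#'   FALSE).
#' @param seed integer seed.
#' @return a `tabular_dataset` with continuous graded features `v1..` (and
#'   `sep` if requested) and a boolean `outcome` column.
#' @export
generate_classification <- function(n = 600, effect_sizes = c(3, 2, 1, 0.5, 0),
                                    prevalence = 0.35, separable = FALSE,
                                    seed = 1) {
  set.seed(as.integer(seed))
  y <- stats::runif(n) < prevalence
  df <- list()
  for (j in seq_along(effect_sizes)) {
    mu <- 4 + effect_sizes[j] * as.numeric(y) * 1.5
    v <- round(stats::rnorm(n, mean = mu, sd = 1.5))
    df[[paste0("v", j)]] <- pmin(pmax(v, 1), 10)
  }
  if (separable) df$sep <- ifelse(y, 9, 2)
  df$outcome <- y
  df <- as.data.frame(df)
  schema <- c(lapply(setdiff(names(df), "outcome"), variable_spec,
                     vtype = "continuous"),
              list(variable_spec("outcome", "boolean")))
  tabular_dataset(df, schema = schema)
}
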