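# Independent brute-force oracles used to pin the production kernels.
# These deliberately use naive all-pairs loops and direct formulas only.

oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j) sqrt(sum((coords[i, ] - coords[j, ])^2)), 0)
    d[i] <- Inf
    ord <- order(d, seq_len(n))[seq_len(k)]
    idx[i, ] <- ord; dst[i, ] <- d[ord]
  }
  list(indices = idx, distances = dst)
}

oracle_dcr <- function(real, synth) {
  vapply(seq_len(nrow(synth)), function(i) {
    min(vapply(seq_len(nrow(real)), function(j)
      sqrt(sum((synth[i, ] - real[j, ])^2)), 0))
  }, 0)
}

oracle_nndr <- function(real, synth) {
  vapply(seq_len(nrow(synth)), function(i) {
    d <- sort(vapply(seq_len(nrow(real)), function(j)
      sqrt(sum((synth[i, ] - real[j, ])^2)), 0))
    if (d[2L] == 0) 1 else d[1L] / d[2L]
  }, 0)
}

oracle_local_cloaking <- function(orig, avat, linkage) {
  vapply(seq_len(nrow(orig)), function(i) {
    own <- sqrt(sum((orig[i, ] - avat[linkage[i], ])^2))
    cnt <- 0L
    for (j in seq_len(nrow(avat))) {
      if (j == linkage[i]) next
      if (sqrt(sum((orig[i, ] - avat[j, ])^2)) < own) cnt <- cnt + 1L
    }
    cnt
  }, 0L)
}

# Textbook MCA on an indicator matrix: correspondence analysis of the
# n x J table. Returns row principal coordinates and principal inertias.
oracle_mca <- function(df) {
  inds <- lapply(df, function(f) {
    f <- factor(f)
    I <- matrix(0, length(f), nlevels(f))
    I[cbind(seq_along(f), as.integer(f))] <- 1
    I
  })
  Z0 <- do.call(cbind, inds)
  n <- nrow(Z0); Q <- length(inds)
  P <- Z0 / (n * Q)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  keep <- sv$d > 1e-12
  rows <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], sum(keep))
  list(row_coords = rows, inertia = sv$d[keep]^2)
}

# Tiny mixed dataset used across tests.
toy_mixed <- function() {
  tabular_dataset(
    data.frame(age = c(30, 41, 55, 28, 47, 39),
               bmi = c(22.1, 27.3, 31.0, 20.5, 25.8, 24.4),
               sex = c("M", "F", "F", "M", "F", "M"),
               smoker = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
               visit = as.Date(c("2020-01-01", "2020-03-15", "2019-11-30",
                                 "2020-06-01", "2020-02-20", "2020-04-10")),
               stringsAsFactors = FALSE))
}

# Avatar rows re-aligned with their originating records (undoes the
# output shuffle via the in-memory linkage).
ds_pre_shuffle <- function(av) {
  df <- av$data$data[av$linkage, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Deposited reference datasets (AIDS clinical trial, WBCD) are expected at
# this location when available; the repository does not bundle them.
deposited_path <- function(name) {
  dir <- getOption("avatarize.deposited_dir", testthat::test_path("deposited"))
  file.path(dir, name)
}
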