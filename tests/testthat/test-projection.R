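test_that("FAMD reduces to standardized PCA when all columns are continuous", {
  set.seed(11)
  X <- matrix(rnorm(40 * 4), 40, 4) %*% diag(c(3, 2, 1, 0.5))
  ds <- tabular_dataset(as.data.frame(X))
  m <- fit_famd(ds)
  Zs <- scale(X)  # oracle: z-score then SVD directly
  sv <- svd(Zs)
  expect_equal(m$explained_variance, sv$d^2 / sum(sv$d^2), tolerance = 1e-10)
  sc <- famd_transform(m, ds)
  ref <- sv$u %*% diag(sv$d)
  for (j in seq_len(4))
    expect_equal(abs(sc[, j]), abs(ref[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("FAMD on all-categorical data matches MCA up to per-component scaling", {
  df <- data.frame(a = c("x", "x", "y", "y", "x", "y"),
                   b = c("u", "v", "u", "v", "v", "u"),
                   stringsAsFactors = FALSE)
  ds <- tabular_dataset(df, max_levels = 3)
  m <- fit_famd(ds)
  sc <- famd_transform(m, ds)
  mca <- oracle_mca(df)
  keep <- seq_len(min(ncol(sc), ncol(mca$row_coords)))
  for (j in keep) {
    if (sd(mca$row_coords[, j]) < 1e-12) next
    expect_gt(abs(cor(sc[, j], mca$row_coords[, j])), 1 - 1e-8)
  }
  # principal inertias are proportional, so variance ratios agree
  expect_equal(m$explained_variance[keep] / sum(m$explained_variance[keep]),
               mca$inertia[keep] / sum(mca$inertia[keep]), tolerance = 1e-8)
})

test_that("axes are orthonormal and variance ratios are sorted", {
  ds <- toy_mixed()
  m <- fit_famd(ds)
  G <- t(m$axes) %*% m$axes
  expect_equal(G, diag(m$ncomp), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  expect_true(all(m$explained_variance >= 0))
  expect_lte(sum(m$explained_variance), 1 + 1e-12)
})

test_that("full-rank round trip recovers the data", {
  ds <- toy_mixed()
  m <- fit_famd(ds)
  sc <- famd_transform(m, ds)
  back <- famd_inverse_transform(m, sc)
  for (nm in c("age", "bmi"))
    expect_equal(back$data[[nm]], ds$data[[nm]], tolerance = 1e-8)
  expect_identical(as.character(back$data$sex), as.character(ds$data$sex))
  expect_identical(back$data$smoker, ds$data$smoker)
  expect_identical(back$data$visit, ds$data$visit)
})

test_that("transform is consistent: refit-free, duplicate-stable, centered", {
  ds <- toy_mixed()
  m <- fit_famd(ds)
  sc <- famd_transform(m, ds)
  # duplicated rows map to identical coordinates
  dup <- tabular_dataset(ds$data[c(1, 1, 3, 3, 5, 5), ], schema = ds$schema)
  sd2 <- famd_transform(m, dup)
  expect_equal(sd2[1, ], sd2[2, ], tolerance = 1e-12)
  expect_equal(sd2[1, ], sc[1, ], tolerance = 1e-12)
  # the zero coordinate decodes to column means / heaviest-centered levels
  center <- famd_inverse_transform(m, matrix(0, 1, m$ncomp))
  expect_equal(center$data$age, mean(ds$data$age), tolerance = 1e-8)
  expect_equal(center$data$bmi, mean(ds$data$bmi), tolerance = 1e-8)
})

test_that("convex combinations of coordinates decode to convex value mixes", {
  ds <- tabular_dataset(data.frame(u = c(1, 5, 9), v = c(10, 2, 4)))
  m <- fit_famd(ds)
  sc <- famd_transform(m, ds)
  mix <- 0.25 * sc[1, , drop = FALSE] + 0.75 * sc[2, , drop = FALSE]
  got <- famd_inverse_transform(m, mix)
  expect_equal(got$data$u, 0.25 * 1 + 0.75 * 5, tolerance = 1e-8)
  expect_equal(got$data$v, 0.25 * 10 + 0.75 * 2, tolerance = 1e-8)
})

test_that("distances in score space equal distances in encoded space", {
  set.seed(21)
  ds <- generate_mixed(n = 60, seed = 21)
  m <- fit_famd(ds)
  sc <- famd_transform(m, ds)
  Z <- avatarize:::encode_dataset(m, ds)
  expect_equal(as.matrix(dist(sc)), as.matrix(dist(Z)), tolerance = 1e-8)
})

test_that("degenerate columns and unseen labels raise typed errors", {
  expect_error(fit_famd(tabular_dataset(data.frame(x = c(2, 2, 2)),
                        schema = list(variable_spec("x", "continuous")))),
               class = "avt_fit_error")
  ds <- toy_mixed()
  m <- fit_famd(ds)
  other <- ds$data
  other$sex <- as.character(other$sex)
  other$sex[2] <- "X"
  ds2 <- tabular_dataset(other,
    schema = modifyList(ds$schema,
      list(sex = variable_spec("sex", "categorical", categories = c("F", "M", "X")))))
  expect_error(famd_transform(m, ds2), class = "avt_transform_error")
  expect_error(famd_inverse_transform(m, matrix(NaN, 1, m$ncomp)),
               class = "avt_transform_error")
})

test_that("a persisted model reloads and transforms identically", {
  ds <- toy_mixed()
  m <- fit_famd(ds)
  path <- tempfile(fileext = ".json")
  write_famd_model(m, path)
  m2 <- read_famd_model(path)
  expect_equal(famd_transform(m2, ds), famd_transform(m, ds), tolerance = 1e-12)
})

test_that("column weights scale the encoded columns", {
  ds <- tabular_dataset(data.frame(a = c(1, 2, 3, 4), b = c(4, 1, 3, 2)))
  m1 <- fit_famd(ds)
  m2 <- fit_famd(ds, column_weights = c(a = 10))
  # variable a dominates the first axis once upweighted
  expect_gt(abs(m2$axes[1, 1]), abs(m2$axes[2, 1]))
  expect_gt(m2$explained_variance[1], m1$explained_variance[1])
})
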