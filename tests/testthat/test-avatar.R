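test_that("the k=2 worked example gives P = (1/12, 1/10) and W = (5/11, 6/11)", {
  w <- avatar_weights(c(3, 5), shuffle = c(2, 1), R = c(1, 1))
  expect_identical(w$P, c(1 / 3 * 1 / 4, 1 / 5 * 1 / 2))
  expect_equal(w$W, c(5 / 11, 6 / 11), tolerance = 1e-15)
  # k = 1 normalizes to weight one whatever the draw
  expect_equal(avatar_weights(2.7, shuffle = 1, R = 0.013)$W, 1)
})

test_that("weight draws satisfy the construction invariants", {
  set.seed(101)
  cfg <- avatar_config(k = 5, seed = NULL)
  for (rep in seq_len(2000)) {
    k <- sample(1:8, 1)
    d <- runif(k, 0.01, 10)
    W <- draw_weights(d, cfg)
    expect_true(all(W >= 0) && all(W <= 1))
    expect_lt(abs(sum(W) - 1), 1e-12)
  }
  # the contribution multiset is exactly {2^-1 ... 2^-k}: reproduce the
  # stream (shuffle drawn first, then the exponential factors)
  for (rep in seq_len(50)) {
    k <- sample(2:7, 1)
    d <- runif(k, 0.1, 5)
    seed <- 7000 + rep
    set.seed(seed); W <- draw_weights(d, cfg)
    set.seed(seed)
    shuffle <- sample.int(k); R <- rexp(k, rate = 1)
    expect_equal(sort(0.5^shuffle), 0.5^(k:1))
    expect_equal(W, avatar_weights(d, shuffle, R)$W, tolerance = 1e-15)
  }
})

test_that("nearer neighbors get heavier weights on average", {
  set.seed(77)
  cfg <- avatar_config(k = 3)
  W <- replicate(10000, draw_weights(c(1, 2, 4), cfg))
  mw <- rowMeans(W)
  expect_true(mw[1] > mw[2] && mw[2] > mw[3])
})

test_that("neighbor search is exact, self-excluding and tie-stable", {
  nb <- find_neighbors(matrix(c(0, 1, 10), 3, 1), k = 1)
  expect_equal(nb$indices[, 1], c(2L, 1L, 2L))
  # five duplicates: ties resolved toward lower indices, distance zero
  nb2 <- find_neighbors(matrix(1, 5, 2), k = 2)
  expect_equal(nb2$indices[1, ], c(2L, 3L))
  expect_equal(nb2$indices[4, ], c(1L, 2L))
  expect_true(all(nb2$distances == 0))
  # brute-force agreement on a random instance
  set.seed(5)
  co <- matrix(rnorm(200 * 3), 200, 3)
  got <- find_neighbors(co, k = 7)
  ref <- oracle_knn(co, k = 7)
  expect_equal(got$indices, ref$indices)
  expect_equal(got$distances, ref$distances, tolerance = 1e-12)
  expect_error(find_neighbors(co, k = 200), class = "avt_config_error")
  # no row is ever its own neighbor
  expect_true(all(got$indices != row(got$indices)))
})

test_that("avatars are convex combinations of their neighbors", {
  ds <- generate_mixed(n = 300, seed = 31)
  av <- generate_avatars(ds, avatar_config(k = 10, seed = 99))
  expect_true(all(av$weights >= 0))
  expect_equal(rowSums(av$weights), rep(1, ds$n), tolerance = 1e-12)
  # continuous avatar values stay inside the neighbors' value range
  oc <- as.data.frame(ds)
  pre_shuffle <- ds_pre_shuffle(av)
  for (nm in c("x1", "x2", "x3")) {
    vals <- oc[[nm]]
    lo <- apply(av$neighbors, 1L, function(ix) min(vals[ix]))
    hi <- apply(av$neighbors, 1L, function(ix) max(vals[ix]))
    expect_true(all(pre_shuffle[[nm]] >= lo - 1e-8 & pre_shuffle[[nm]] <= hi + 1e-8))
  }
})

test_that("k = 1 degenerates to the nearest neighbor's record", {
  ds <- generate_mixed(n = 80, seed = 41)
  av <- generate_avatars(ds, avatar_config(k = 1, seed = 13))
  pre <- ds_pre_shuffle(av)
  nn <- av$neighbors[, 1]
  src <- as.data.frame(ds)
  for (nm in c("x1", "x2", "x3"))
    expect_equal(pre[[nm]], src[[nm]][nn], tolerance = 1e-6)
  expect_identical(as.character(pre$cluster), as.character(src$cluster[nn]))
})

test_that("generation is seed-deterministic and seed-sensitive", {
  ds <- generate_mixed(n = 120, seed = 51)
  a1 <- generate_avatars(ds, avatar_config(k = 5, seed = 7))
  a2 <- generate_avatars(ds, avatar_config(k = 5, seed = 7))
  a3 <- generate_avatars(ds, avatar_config(k = 5, seed = 8))
  expect_identical(a1$data$data, a2$data$data)
  expect_identical(a1$permutation, a2$permutation)
  expect_false(identical(a1$data$data, a3$data$data))
})

test_that("avatar output keeps schema and shape and hides the linkage", {
  ds <- generate_mixed(n = 150, seed = 61, duplicate_frac = 0.1)
  cfg <- avatar_config(k = 20, seed = 3)
  out_csv <- tempfile(fileext = ".csv")
  rep_json <- tempfile(fileext = ".json")
  man_json <- tempfile(fileext = ".json")
  avatarize(ds, cfg, output = out_csv, report_path = rep_json,
            manifest_path = man_json)
  back <- read_dataset(out_csv, schema = ds$schema)
  expect_equal(back$n, ds$n)
  expect_equal(back$p, ds$p)
  expect_true(validate_against(back, ds$schema)$valid)
  blob <- paste(readLines(rep_json, warn = FALSE), collapse = "")
  expect_false(grepl("linkage|permutation", blob))
  manifest <- jsonlite::read_json(man_json)
  expect_equal(manifest$k, 20L)
  expect_equal(manifest$seed, 3L)
})

test_that("duplicate records are handled through the distance floor", {
  df <- data.frame(x = c(rep(1, 4), 5, 6, 7), y = c(rep(2, 4), 1, 3, 2))
  ds <- tabular_dataset(df)
  av <- generate_avatars(ds, avatar_config(k = 2, seed = 5))
  expect_equal(av$data$n, 7L)
  expect_true(all(is.finite(as.matrix(av$data$data))))
})
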