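test_that("regression targets are monotone: better decoys get more negative y", {
  rec <- data.frame(fnat = c(0, 0.2, 0.7), lrmsd = c(30, 8, 1),
                    irmsd = c(1, 2, 10), stars = c(0L, 1L, 3L))
  class(rec) <- c("quality_records", class(rec))
  expect_equal(regression_targets(rec, "negative", "stars"), c(0, -1, -3))
  expect_equal(regression_targets(rec, "negative-reciprocal", "irmsd"),
               c(-1, -0.5, -0.1))
  # reciprocal floor keeps a perfect decoy the most negative
  rec2 <- data.frame(irmsd = c(0, 0.5, 5))
  y <- regression_targets(rec2, "negative-reciprocal", "irmsd")
  expect_true(all(diff(y) > 0))
  expect_equal(y[1], -1000)
  # monotone in quality for both schemes
  y_st <- regression_targets(rec, "negative", "stars")
  expect_true(all(diff(y_st) < 0))
  y_lr <- regression_targets(rec, "negative-reciprocal", "lrmsd")
  expect_true(all(diff(y_lr) < 0))
})

test_that("fraction normalization turns rows into fractions and flags zero rows", {
  g <- structure(list(features = rbind(c(2, 2, 4), c(0, 0, 0), c(1, 0, 3)),
                      form = potential_form("step", bin_edges = c(0, 4)),
                      n_types = 2L, table_hash = "x",
                      layout = data.frame(column = 1:3),
                      decoy_ids = c("a", "b", "c"), native = rep(FALSE, 3),
                      complex_id = "c1"),
                 class = "feature_grid")
  ng <- fraction_normalize(g)
  expect_equal(ng$features[1, ], c(0.25, 0.25, 0.5))
  expect_equal(ng$features[2, ], c(0, 0, 0))
  expect_equal(rowSums(ng$features[c(1, 3), ]), c(1, 1))
  expect_identical(attr(ng, "zero_rows"), 2L)
})

test_that("OLS recovers exact solutions; NNLS equals OLS when unconstrained optimum is non-negative", {
  set.seed(53)
  # full-rank square system
  X <- matrix(rnorm(64), 8, 8)
  w <- rnorm(8)
  expect_equal(fit_linear(X, X %*% w, "ols"), w, tolerance = 1e-8)
  # non-negative truth: KKT says NNLS = OLS
  X2 <- matrix(runif(200), 40, 5)
  w2 <- runif(5, 0.5, 2)
  y2 <- as.numeric(X2 %*% w2)
  expect_equal(fit_linear(X2, y2, "nnls"), fit_linear(X2, y2, "ols"),
               tolerance = 1e-6)
  # NNLS never returns negative entries
  y3 <- as.numeric(X2 %*% c(-3, 1, 1, -2, 0.5)) + rnorm(40, 0, 0.1)
  expect_true(all(fit_linear(X2, y3, "nnls") >= 0))
  # OLS residual orthogonal to the column space
  Xr <- matrix(rnorm(120), 30, 4)
  yr <- rnorm(30)
  res <- yr - Xr %*% fit_linear(Xr, yr, "ols")
  expect_lt(max(abs(crossprod(Xr, res))), 1e-8)
  expect_error(fit_linear(matrix(0, 4, 2), rnorm(4)), "degenerate")
})

test_that("noiseless planted potentials are recovered by OLS on raw features", {
  bm <- make_planted_benchmark(n_complexes = 4,
                               spec = fixture_spec(n_atoms = 25,
                                                   n_decoys = 150),
                               noise_sd = 0, seed = 59)
  X <- do.call(rbind, lapply(bm$grids, `[[`, "features"))
  expect_equal(qr(X)$rank, ncol(X)) # generic full rank at this size
  fit <- train_lr(bm$grids, bm$energies, mode = "ols", normalize = FALSE)
  expect_equal(fit$values, bm$planted$values, tolerance = 1e-8)
})

test_that("fraction normalization makes fits invariant to duplicated interfaces", {
  bm <- make_planted_benchmark(n_complexes = 3,
                               spec = fixture_spec(n_atoms = 15,
                                                   n_decoys = 60),
                               seed = 61)
  targets <- lapply(bm$energies, function(e) -rank_decoys(e) / length(e))
  f1 <- train_lr(bm$grids, targets, mode = "ols", normalize = TRUE)
  doubled <- lapply(bm$grids, function(g) { g$features <- 2 * g$features; g })
  f2 <- train_lr(doubled, targets, mode = "ols", normalize = TRUE)
  expect_equal(f1$values, f2$values, tolerance = 1e-8)
})

test_that("cross-validation scales parameter sets by their own spread before averaging", {
  form <- potential_form("step", bin_edges = c(0, 4))
  v <- c(1, -2, 0.5)
  mk <- function(vals) parameter_vector(form, values = vals, n_types = 2)
  grids <- replicate(4, structure(list(
    features = matrix(runif(9), 3, 3), form = form, n_types = 2L,
    table_hash = "x", layout = data.frame(column = 1:3),
    decoy_ids = letters[1:3], native = rep(FALSE, 3), complex_id = "c"),
    class = "feature_grid"), simplify = FALSE)
  # identical sets across folds: combined equals any single scaled set
  cv <- crossval_average(grids, as.list(1:4), k = 2,
                         trainer = function(g, a) mk(v))
  expect_equal(cv$params$values, v / sd(v), tolerance = 1e-12)
  # v and 2v scale to the same set
  flip <- local({
    i <- 0
    function(g, a) { i <<- i + 1; mk(if (i == 1) v else 2 * v) }
  })
  cv2 <- crossval_average(grids, as.list(1:4), k = 2, trainer = flip)
  expect_equal(cv2$params$values, v / sd(v), tolerance = 1e-12)
  expect_error(crossval_average(grids, as.list(1:4), k = 9,
                                trainer = function(g, a) mk(v)),
               "split error")
})

test_that("best-set selection picks the fold with the highest validation score", {
  bm <- make_planted_benchmark(n_complexes = 6,
                               spec = fixture_spec(n_atoms = 15,
                                                   n_decoys = 50),
                               seed = 67)
  aux <- lapply(seq_along(bm$grids), function(i)
    list(good = bm$good[[i]], energies = bm$energies[[i]]))
  # one corrupted fold trains an anti-potential; validation must avoid it
  trainer <- function(grids, aux) {
    p <- train_lr(grids, lapply(aux, `[[`, "energies"), mode = "ols",
                  normalize = FALSE)
    p
  }
  corrupting <- local({
    call <- 0
    function(grids, aux) {
      call <<- call + 1
      p <- trainer(grids, aux)
      if (call == 2) p$values <- -p$values # corrupted fold
      p
    }
  })
  validate <- function(p, grids, aux)
    mean(vapply(seq_along(grids), function(i)
      enrichment_fraction(rank_decoys(score_decoys(grids[[i]], p)),
                          aux[[i]]$good, 0.2), 0))
  cv <- crossval_average(bm$grids, aux, k = 3, trainer = corrupting,
                         combine = "best", validate = validate)
  expect_true(which.max(cv$validation) != 2)
  expect_equal(cv$params$values, cv$fold_params[[which.max(cv$validation)]]$values)
})

test_that("LR and MC trained on the same planted fixture both beat random enrichment", {
  bm <- make_planted_benchmark(n_complexes = 5,
                               spec = fixture_spec(n_atoms = 18,
                                                   n_decoys = 80),
                               seed = 71)
  lr <- train_lr(bm$grids[1:3], lapply(bm$energies[1:3], function(e) e),
                 mode = "ols", normalize = FALSE)
  mc <- anneal(bm$grids[1:3], bm$weights[1:3],
               anneal_config(steps = 4000, conv_window = 4000,
                             scheme = "quadratic", seed = 73))
  enr <- function(p) mean(vapply(4:5, function(i)
    enrichment_fraction(rank_decoys(score_decoys(bm$grids[[i]], p)),
                        bm$good[[i]], 0.10), 0))
  rb <- random_baseline(vapply(bm$grids[4:5], function(g) nrow(g$features), 0L),
                        bm$good[4:5], n_shuffles = 50, seed = 79,
                        percentiles = 0.10)
  expect_gt(enr(lr), rb$enrichment[["top10pct"]])
  expect_gt(enr(mc$params), rb$enrichment[["top10pct"]])
})
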