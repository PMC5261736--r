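test_that("ranking weights rise from 1/n (or 1/n^2) at the bottom to 1 at rank 1", {
  n <- 37
  expect_equal(ranking_weight(1, n, "linear"), 1)
  expect_equal(ranking_weight(1, n, "quadratic"), 1)
  expect_equal(ranking_weight(n, n, "linear"), 1 / n)
  expect_equal(ranking_weight(n, n, "quadratic"), 1 / n^2)
  wl <- ranking_weight(1:n, n, "linear")
  wq <- ranking_weight(1:n, n, "quadratic")
  expect_true(all(diff(wl) < 0))
  expect_true(all(wq <= wl))
})

test_that("the target function matches exhaustive recomputation and is weight-scale invariant", {
  # all quality weight on the rank-1 decoy
  expect_equal(target_function(list(c(-5, 1, 2)), list(c(1, 0, 0)), "linear"), 1)
  # all-zero weights give t = 0
  expect_equal(target_function(list(rnorm(6)), list(numeric(6))), 0)
  # 4-decoy brute-force oracle
  sc <- c(0.3, -1.2, 0.8, -0.1)
  wq <- c(0.5, 0.5, 0, 0)
  # hand enumeration: ranks of sc are (3, 1, 4, 2)
  ranks <- c(3L, 1L, 4L, 2L)
  oracle <- sum(wq * ((4 - ranks + 1) / 4))
  expect_equal(target_function(list(sc), list(wq), "linear"), oracle)
  oracle_q <- sum(wq * ((4 - ranks + 1) / 4)^2)
  expect_equal(target_function(list(sc), list(wq), "quadratic"), oracle_q)
  # normalization invariance: scaling raw weights before normalization
  raw <- c(2, 1, 0, 1)
  t1 <- target_function(list(sc), list(raw / sum(raw)))
  t2 <- target_function(list(sc), list((7 * raw) / sum(7 * raw)))
  expect_equal(t1, t2)
})

test_that("Metropolis acceptance follows min(1, exp(dt/T)) empirically", {
  expect_true(metropolis_accept(1, 0.5, 2, 0.999999)) # uphill: always
  expect_identical(metropolis_accept(0.5, 1.5, 1, exp(-1) - 1e-9), TRUE)
  expect_identical(metropolis_accept(0.5, 1.5, 1, exp(-1) + 1e-9), FALSE)
  set.seed(43)
  dt <- -0.7; temp <- 1.3; n <- 1e5
  u <- runif(n)
  acc <- mean(vapply(u, function(ui)
    metropolis_accept(dt, 0, temp, ui), TRUE))
  p <- exp(dt / temp)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the ziczac schedule hits its endpoints inside the exponential envelope", {
  S <- 1000
  expect_equal(ziczac_temperature(0, S), 50)
  expect_equal(ziczac_temperature(S, S), 0.05) # default oscillations even
  s <- 0:S
  temp <- ziczac_temperature(s, S)
  t_hi <- 50 * (0.05 / 50)^(s / S)
  expect_true(all(temp <= t_hi + 1e-12))
  expect_true(all(temp >= t_hi / 3 - 1e-12))
})

test_that("moves are clamped, vanish at d = 0, and d adapts to the acceptance rate", {
  set.seed(47)
  lo <- c(1.5, 0); hi <- c(6, 50)
  state <- c(1.6, 0.5)
  for (i in 1:200) {
    state <- propose_move(state, d = 10, lo, hi)$state
    expect_true(all(state >= lo & state <= hi))
  }
  st0 <- c(0.2, 0.4, 0.6)
  mv <- propose_move(st0, d = 0, rep(-1, 3), rep(1, 3))
  expect_equal(mv$state, st0)
  # adaptation: in an annealing trace, the move size changes only at window
  # boundaries, by x1.1 when trailing acceptance > 0.3 and x0.9 otherwise
  bm <- make_planted_benchmark(n_complexes = 2,
                               spec = fixture_spec(n_atoms = 10,
                                                   n_decoys = 30),
                               noise_sd = 0, seed = 3)
  res <- anneal(bm$grids, bm$weights,
                anneal_config(steps = 600, conv_window = 600, seed = 5))
  tr <- res$trace
  for (w in 1:(nrow(tr) %/% 100 - 1)) {
    idx <- (w * 100 + 1):min((w + 1) * 100, nrow(tr))
    rate <- mean(tr$accepted[((w - 1) * 100 + 1):(w * 100)])
    factor <- tr$move_size[idx[1]] / tr$move_size[w * 100]
    expect_equal(factor, if (rate > 0.3) 1.1 else 0.9, tolerance = 1e-12)
    expect_equal(length(unique(tr$move_size[idx])), 1L)
  }
})

test_that("annealing is seed-reproducible with a non-decreasing best target", {
  bm <- make_planted_benchmark(n_complexes = 3,
                               spec = fixture_spec(n_atoms = 12,
                                                   n_decoys = 40),
                               seed = 9)
  cfg <- anneal_config(steps = 1500, seed = 11)
  r1 <- anneal(bm$grids, bm$weights, cfg)
  r2 <- anneal(bm$grids, bm$weights, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$params$values, r2$params$values)
  expect_true(all(diff(r1$best_t_trace) >= 0))
  expect_equal(max(r1$best_t_trace), r1$best_t)
  # all-zero weights everywhere is untrainable
  zero_w <- lapply(bm$weights, function(w) w * 0)
  expect_error(anneal(bm$grids, zero_w, cfg), "untrainable")
})

test_that("annealing recovers a planted step potential well enough to enrich good decoys", {
  bm <- make_planted_benchmark(n_complexes = 6,
                               spec = fixture_spec(n_atoms = 20,
                                                   n_decoys = 120),
                               seed = 13)
  res <- anneal(bm$grids[1:4], bm$weights[1:4],
                anneal_config(steps = 6000, scheme = "quadratic", seed = 17))
  enr <- vapply(5:6, function(i)
    enrichment_fraction(rank_decoys(score_decoys(bm$grids[[i]], res$params)),
                        bm$good[[i]], 0.10), 0)
  rb <- random_baseline(vapply(bm$grids[5:6], function(g) nrow(g$features), 0L),
                        bm$good[5:6], n_shuffles = 50, seed = 19,
                        percentiles = 0.10)
  expect_gt(mean(enr), rb$enrichment[["top10pct"]] + 0.2)
})

test_that("vdw annealing keeps sigma and epsilon inside their clamps", {
  bm <- make_planted_benchmark(n_complexes = 2,
                               spec = fixture_spec(n_atoms = 12,
                                                   n_decoys = 30),
                               form = potential_form("vdw"), seed = 23)
  res <- anneal(bm$grids, bm$weights,
                anneal_config(steps = 800, conv_window = 800, seed = 29))
  view <- vdw_sigma_eps(res$params)
  ok <- !is.na(view$sigma)
  expect_true(all(view$sigma[ok] >= 1.5 & view$sigma[ok] <= 6))
  expect_true(all(view$epsilon[ok] >= 0 & view$epsilon[ok] <= 50 + 1e-9))
})
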