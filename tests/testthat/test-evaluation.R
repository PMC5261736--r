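test_that("top-N success and enrichment behave on hand cases", {
  ranks <- c(1L, 11L, 5L, 2L, 3L, 4L, 6L, 7L, 8L, 9L, 10L, 12L)
  native_first <- c(TRUE, rep(FALSE, 11))
  expect_true(topn_success(ranks, native_first, 1))
  only11 <- ranks == 11L
  expect_false(topn_success(ranks, only11, 10))
  expect_true(topn_success(ranks, only11, 100))
  # all m near-natives on top: enrichment 1 once the slice covers them
  good <- ranks <= 3
  expect_equal(enrichment_fraction(ranks, good, 3 / 12), 1.0)
  expect_equal(enrichment_fraction(ranks, only11, 0.5), 0.0)
  expect_true(is.na(enrichment_fraction(ranks, rep(FALSE, 12), 0.1)))
})

test_that("random scoring matches the hypergeometric success and q-proportional enrichment", {
  set.seed(83)
  n <- 400; m <- 25; N <- 20
  good <- c(rep(TRUE, m), rep(FALSE, n - m))
  B <- 1e4
  succ <- 0; enr <- numeric(B)
  for (b in seq_len(B)) {
    r <- sample.int(n)
    if (topn_success(r, good, N)) succ <- succ + 1
    enr[b] <- enrichment_fraction(r, good, 0.05)
  }
  p_hyper <- 1 - choose(n - m, N) / choose(n, N)
  se <- sqrt(p_hyper * (1 - p_hyper) / B)
  expect_lt(abs(succ / B - p_hyper), 3 * se)
  q <- 0.05
  se_enr <- sd(enr) / sqrt(B)
  expect_lt(abs(mean(enr) - q), 3 * se_enr + 1e-3)
})

test_that("random_baseline is seed-reproducible and close to closed forms", {
  good <- list(c(rep(TRUE, 10), rep(FALSE, 190)),
               c(rep(TRUE, 5), rep(FALSE, 195)))
  b1 <- random_baseline(c(200L, 200L), good, n_shuffles = 400, seed = 89,
                        top_ns = c(1, 10), percentiles = c(0.01, 0.1))
  b2 <- random_baseline(c(200L, 200L), good, n_shuffles = 400, seed = 89,
                        top_ns = c(1, 10), percentiles = c(0.01, 0.1))
  expect_identical(b1, b2)
  hyper <- function(n, m, N) 1 - choose(n - m, N) / choose(n, N)
  expect_equal(b1$success[["top10"]],
               mean(c(hyper(200, 10, 10), hyper(200, 5, 10))),
               tolerance = 0.05)
  expect_lt(abs(b1$enrichment[["top10pct"]] - 0.1), 0.025)
})

test_that("insert_native appends the native's own feature row and can be excluded", {
  set.seed(97)
  spec <- fixture_spec(n_atoms = 12, n_decoys = 8)
  nat <- make_toy_complex(spec)
  ds <- make_decoy_set(nat, spec, ensure_classes = FALSE)
  form <- potential_form("step", bin_edges = c(0, 4, 6))
  g <- build_feature_grid(ds$decoys, form)
  ga <- insert_native(g, nat)
  expect_equal(nrow(ga$features), nrow(g$features) + 1)
  expect_true(ga$native[nrow(ga$features)])
  expect_equal(ga$features[nrow(ga$features), ],
               step_features(nat, c(0, 4, 6)))
  # excluding the native row reproduces pre-insertion assessments
  p <- parameter_vector(form, values = rnorm(ncol(g$features)), n_types = 4,
                        table_hash = g$table_hash)
  sc_all <- score_decoys(ga, p)
  expect_equal(unname(sc_all[!ga$native]), unname(score_decoys(g, p)))
  # a foreign typing table is rejected
  other <- assign_atom_types(typed_structure(nat$receptor, nat$ligand),
                             toy_typing_table(5))
  expect_error(insert_native(g, other), "compatibility")
})

test_that("class and discriminating contributions match hand arithmetic", {
  expect_equal(class_contribution(0, 5, 10), 0)
  expect_equal(class_contribution(-2.5, 10, 10), -2.5)
  expect_equal(class_contribution(3, 1, 0), 0)
  # 3-decoy worked fixture: features f = (4, 2, 0), classes (nn, inc, inc)
  sigma <- -1.5
  nc_nn <- 4; nc_inc <- 1; nc_tot <- 2
  dp <- discriminating_contribution(sigma, nc_nn, nc_inc, nc_tot)
  expect_equal(dp$dp_abs, sigma * abs(4 - 1) / 2)
  expect_equal(dp$dp_signed,
               sigma * 1 / 2 - sigma * 4 / 2)
  expect_false(dp$false_negative) # negative param, counts higher in nn: fine
  expect_false(dp$false_positive)
  # sign-contradiction flags
  fn <- discriminating_contribution(-1, nc_nearnat = 1, nc_incorrect = 3,
                                    nc_tot = 2)
  expect_true(fn$false_negative)
  fp <- discriminating_contribution(1, nc_nearnat = 3, nc_incorrect = 1,
                                    nc_tot = 2)
  expect_true(fp$false_positive)
  # rescaling features by k and sigma by 1/k leaves the underlying score
  # contributions sigma * nc invariant, so dp and p scale together by 1/k
  k <- 10
  dp2 <- discriminating_contribution(sigma / k, k * nc_nn, k * nc_inc,
                                     k * nc_tot)
  expect_equal((sigma / k) * (k * nc_nn), sigma * nc_nn, tolerance = 1e-12)
  expect_equal(dp2$dp_abs * k, dp$dp_abs, tolerance = 1e-12)
  expect_equal(dp2$dp_signed * k, dp$dp_signed, tolerance = 1e-12)
})

test_that("contribution reports aggregate class means across complexes", {
  set.seed(101)
  spec <- fixture_spec(n_atoms = 12, n_decoys = 15)
  nat <- make_toy_complex(spec)
  ds <- make_decoy_set(nat, spec)
  form <- potential_form("step", bin_edges = c(0, 4, 6))
  g <- build_feature_grid(ds$decoys, form)
  p <- parameter_vector(form, values = rnorm(ncol(g$features)), n_types = 4,
                        table_hash = g$table_hash)
  rep <- contribution_report(list(g), list(ds$records$stars), p)
  expect_equal(nrow(rep), ncol(g$features))
  expect_equal(rep$nc_tot, colMeans(g$features))
  nn <- ds$records$stars >= 1
  expect_equal(rep$nc_nearnat, colMeans(g$features[nn, , drop = FALSE]))
  expect_equal(rep$p_nearnat + rep$dp_signed, rep$p_incorrect,
               tolerance = 1e-12)
})

test_that("evaluation reports are monotone in N and percentile", {
  set.seed(103)
  ranks <- lapply(c(120, 200), sample.int)
  good <- lapply(ranks, function(r) r %in% sample(seq_along(r), 12))
  rep <- evaluation_report(ranks, good, top_ns = c(1, 10, 50, 100),
                           percentiles = c(0.01, 0.05, 0.2))
  expect_true(all(diff(rep$success) >= 0))
  expect_true(all(diff(rep$enrichment) >= 0))
  expect_equal(rep$best_rank,
               vapply(1:2, function(i) min(ranks[[i]][good[[i]]]), 0))
})
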