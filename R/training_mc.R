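#' Rank weights for the annealing target function
#'
#' The weight of a decoy at `rank` among `n` rises from the last position to
#' 1 at rank 1: linearly, `(n - rank + 1)/n`, or quadratically, its square.
#' The quadratic scheme concentrates the objective on the very top of the
#' ranking.
#'
#' @param rank integer rank(s) in `1..n`.
#' @param n decoy count.
#' @param scheme `"linear"` or `"quadratic"`.
#' @return Numeric weights in `(0, 1]`.
#' @export
ranking_weight <- function(rank, n, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  stopifnot(all(rank >= 1L & rank <= n))
  w <- (n - rank + 1) / n
  if (scheme == "quadratic") w^2 else w
}

#' Rank-based training target
#'
#' `t = sum over complexes c, decoys i of wq[i,c] * wr(rank of i under the
#' current scores)`, where `wq` are per-complex normalized quality weights
#' and `wr` the [ranking_weight()]. Higher `t` is better; `t` attains its
#' maximum when all quality weight sits at rank 1.
#'
#' @param scores list of numeric score vectors, one per complex.
#' @param weights list of per-complex normalized quality weights.
#' @param scheme ranking-weight scheme.
#' @return Scalar target value.
#' @export
target_function <- function(scores, weights, scheme = "linear") {
  stopifnot(length(scores) == length(weights))
  tot <- 0
  for (c in seq_along(scores)) {
    wq <- weights[[c]]
    if (all(wq == 0)) next
    n <- length(scores[[c]])
    tot <- tot + sum(wq * ranking_weight(rank_decoys(scores[[c]]), n, scheme))
  }
  tot
}

#' Metropolis acceptance for a maximized target
#'
#' Accept iff `u < min(1, exp((t_new - t_old)/T))`: uphill moves always,
#' downhill moves with Boltzmann probability.
#'
#' @param t_new,t_old target values.
#' @param temperature pseudo-temperature, > 0.
#' @param u a uniform(0,1) draw.
#' @return Logical.
#' @export
metropolis_accept <- function(t_new, t_old, temperature, u) {
  stopifnot(temperature > 0)
  u < min(1, exp((t_new - t_old) / temperature))
}

#' Ziczac annealing temperature schedule
#'
#' The temperature oscillates between two decaying exponential envelopes:
#' `T(s) = T_hi(s) * (1/ratio + (1 - 1/ratio) * sin^2(pi*k*s/S + pi/2))`
#' with `T_hi(s) = T0 * (Tend/T0)^(s/S)`. So `T(0) = T0`, `T(S) = Tend`
#' for even oscillation counts `k`, and `T_hi/ratio <= T <= T_hi`
#' throughout.
#'
#' @param s step (0-based), `0 <= s <= S`.
#' @param S total steps.
#' @param T0,Tend start and end temperatures (defaults 50 and 0.05, i.e.
#'   cooling to 0.1 percent of the start).
#' @param ratio envelope ratio (> 1).
#' @param oscillations number of sin^2 oscillations over the run.
#' @return Temperature(s).
#' @export
ziczac_temperature <- function(s, S, T0 = 50, Tend = 0.05, ratio = 3,
                               oscillations = 10) {
  stopifnot(all(s >= 0 & s <= S), ratio > 1, T0 > 0, Tend > 0)
  t_hi <- T0 * (Tend / T0)^(s / S)
  t_hi * (1 / ratio + (1 - 1 / ratio) * sin(pi * oscillations * s / S + pi / 2)^2)
}

#' Annealing configuration
#'
#' @param steps annealing steps; defaults to 300000 for step/bsa forms and
#'   100000 for vdw (pass explicitly for desk-scale runs).
#' @param T0,Tend,ratio,oscillations see [ziczac_temperature()]; `Tend`
#'   defaults to `T0/1000`.
#' @param scheme ranking-weight scheme ("linear" or "quadratic").
#' @param d0 starting adaptive move size.
#' @param adapt_window,adapt_target move-size adaptation: every
#'   `adapt_window` steps `d` is multiplied by 1.1 (0.9) if the trailing
#'   acceptance rate exceeds (falls below) `adapt_target`.
#' @param bounds per-parameter clamps; for vdw fixed to sigma in `[1.5, 6]`
#'   and epsilon in `[0, 50]`, for step/bsa a symmetric `c(lo, hi)` box.
#' @param conv_window,conv_tol stop early when the best target improved by
#'   less than `conv_tol` (relative) over the trailing `conv_window` steps.
#' @param seed RNG seed (annealing is bit-reproducible given the seed).
#' @return List of class `anneal_config`.
#' @export
anneal_config <- function(steps = NULL, T0 = 50, Tend = T0 / 1000,
                          ratio = 3, oscillations = 10,
                          scheme = c("linear", "quadratic"), d0 = 1,
                          adapt_window = 100L, adapt_target = 0.3,
                          bounds = c(-50, 50),
                          conv_window = 2000L, conv_tol = 1e-6,
                          seed = 1L) {
  structure(list(steps = steps, T0 = T0, Tend = Tend, ratio = ratio,
                 oscillations = oscillations, scheme = match.arg(scheme),
                 d0 = d0, adapt_window = as.integer(adapt_window),
                 adapt_target = adapt_target, bounds = bounds,
                 conv_window = as.integer(conv_window), conv_tol = conv_tol,
                 seed = as.integer(seed)),
            class = "anneal_config")
}

# vdw state lives in (sigma, epsilon) space: c(sigma_1..P, eps_1..P)
vdw_state_bounds <- function(P) {
  list(lo = c(rep(1.5, P), rep(0, P)), hi = c(rep(6, P), rep(50, P)))
}

vdw_state_to_weights <- function(state) {
  P <- length(state) / 2L
  sigma <- state[seq_len(P)]; eps <- state[P + seq_len(P)]
  c(eps * sigma^8, -(eps * sigma^6)) # matches score = F %*% w layout
}

#' Propose an adaptive annealing move
#'
#' One uniformly chosen parameter is perturbed additively by a draw from
#' `Uniform(-d, d)` in its natural space (potential values for step/bsa,
#' sigma/epsilon for vdw) and clamped to its bounds.
#'
#' @param state numeric parameter state.
#' @param d current move size.
#' @param lo,hi per-parameter bounds.
#' @return List with the new `state` and the `index` moved. Consumes two
#'   uniform RNG draws.
#' @export
propose_move <- function(state, d, lo, hi) {
  j <- floor(runif(1) * length(state)) + 1L
  if (j > length(state)) j <- length(state) # guard against runif(1) == 1
  val <- state[j] + runif(1, -d, d)
  state[j] <- min(max(val, lo[j]), hi[j])
  list(state = state, index = j)
}

#' Train a potential by Monte-Carlo simulated annealing
#'
#' Directly optimizes the rank-based [target_function()] over parameter
#' space: each step perturbs one randomly chosen parameter
#' ([propose_move()]), re-scores every training complex from its
#' precomputed feature grid (a rank-one score update; no structure access
#' inside the loop), re-ranks, and accepts by the Metropolis criterion at
#' the [ziczac_temperature()]. The best-so-far parameters are returned.
#'
#' @param grids list of compatible `feature_grid`s (one per training
#'   complex).
#' @param weights list of per-complex normalized quality weights (see
#'   [make_quality_weights()]); at least one complex must have nonzero
#'   weights.
#' @param config an [anneal_config()].
#' @return List of class `anneal_result`: `params` (best
#'   [parameter_vector()]), `best_t`, `trace` (data.frame with per-step
#'   `t`, `temperature`, `accepted`, `move_size`), `steps_run`,
#'   `converged`.
#' @export
anneal <- function(grids, weights, config = anneal_config()) {
  stopifnot(length(grids) >= 1L, length(grids) == length(weights))
  for (g in grids[-1]) {
    if (!grids_compatible(grids[[1L]], g))
      stop("grid compatibility error: training grids differ in form/table")
  }
  usable <- vapply(weights, function(w) any(w > 0), TRUE)
  if (!any(usable)) stop("untrainable: all complexes have zero quality weights")
  grids <- grids[usable]; weights <- weights[usable]

  form <- grids[[1L]]$form
  lambda <- grids[[1L]]$n_types
  P <- n_pair_types(lambda)
  S <- config$steps %||% if (form$kind == "vdw") 100000L else 300000L

  X <- lapply(grids, `[[`, "features")
  n_feat <- ncol(X[[1L]])
  if (form$kind == "vdw") {
    b <- vdw_state_bounds(P)
    lo <- b$lo; hi <- b$hi
    n_par <- 2L * P
    to_w <- vdw_state_to_weights
  } else {
    lo <- rep(config$bounds[1], n_feat); hi <- rep(config$bounds[2], n_feat)
    n_par <- n_feat
    to_w <- identity
  }

  set.seed(config$seed)
  state <- numeric(n_par)
  if (form$kind == "vdw") state[seq_len(P)] <- 3 # mid-range sigma, eps 0
  w <- to_w(state)
  scores <- lapply(X, function(x) as.numeric(x %*% w))
  t_cur <- target_function(scores, weights, config$scheme)
  best_t <- t_cur; best_state <- state

  d <- config$d0
  trace_t <- numeric(S); trace_T <- numeric(S)
  trace_acc <- logical(S); trace_d <- numeric(S)
  best_hist <- numeric(S)
  acc_window <- 0L
  converged <- FALSE
  # plateaus of best-t during the hot phase are stochastic, not converged:
  # only watch the convergence window over the cooler second half
  min_check <- max(config$conv_window, S %/% 2L)
  steps_run <- S

  for (s in seq_len(S)) {
    temp <- ziczac_temperature(s - 1, S, config$T0, config$Tend,
                               config$ratio, config$oscillations)
    mv <- propose_move(state, d, lo, hi)
    j <- mv$index
    if (form$kind == "vdw") {
      w_new <- to_w(mv$state)
      # a sigma/epsilon change touches the alpha and beta column of one pair
      p_idx <- if (j <= P) j else j - P
      cols <- c(p_idx, P + p_idx)
      dw <- w_new[cols] - w[cols]
      scores_new <- vector("list", length(X))
      for (ci in seq_along(X))
        scores_new[[ci]] <- scores[[ci]] +
          as.numeric(X[[ci]][, cols, drop = FALSE] %*% dw)
    } else {
      delta <- mv$state[j] - state[j]
      scores_new <- vector("list", length(X))
      for (ci in seq_along(X))
        scores_new[[ci]] <- scores[[ci]] + delta * X[[ci]][, j]
    }
    t_new <- target_function(scores_new, weights, config$scheme)
    acc <- metropolis_accept(t_new, t_cur, temp, runif(1))
    if (acc) {
      state <- mv$state
      if (form$kind == "vdw") w <- to_w(state)
      scores <- scores_new
      t_cur <- t_new
      acc_window <- acc_window + 1L
      if (t_cur > best_t) { best_t <- t_cur; best_state <- state }
    }
    trace_t[s] <- t_cur; trace_T[s] <- temp
    trace_acc[s] <- acc; trace_d[s] <- d
    best_hist[s] <- best_t
    if (s %% config$adapt_window == 0L) {
      rate <- acc_window / config$adapt_window
      d <- d * if (rate > config$adapt_target) 1.1 else 0.9
      acc_window <- 0L
    }
    if (s >= min_check) {
      prev <- best_hist[s - config$conv_window + 1L]
      if (best_t - prev < config$conv_tol * max(abs(best_t), 1e-12)) {
        converged <- TRUE; steps_run <- s
        break
      }
    }
  }

  keep <- seq_len(steps_run)
  params <- if (form$kind == "vdw") {
    sigma <- best_state[seq_len(P)]; eps <- best_state[P + seq_len(P)]
    vdw_from_sigma_eps(form, sigma, eps, lambda, grids[[1L]]$table_hash)
  } else {
    parameter_vector(form, values = best_state, n_types = lambda,
                     table_hash = grids[[1L]]$table_hash)
  }
  structure(list(params = params, best_t = best_t,
                 trace = data.frame(step = keep, t = trace_t[keep],
                                    temperature = trace_T[keep],
                                    accepted = trace_acc[keep],
                                    move_size = trace_d[keep]),
                 best_t_trace = best_hist[keep],
                 steps_run = steps_run, converged = converged,
                 config = config),
            class = "anneal_result")
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf("anneal_result: %d steps%s, best target %.6g (%s form)\n",
              x$steps_run, if (x$converged) " (converged)" else "",
              x$best_t, x$params$form$kind))
  invisible(x)
}
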