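# Discovery and production dynamics in assembly space.
#
# Discovery cascade: dN_{a+1}/dt = k_d * (N_a)^alpha over assembly levels
# a = 1..a_max (level 1 = the elementary basis, held constant). alpha = 1 is
# undirected, history-dependent expansion (the boundary of assembly
# possible); alpha < 1 restricts reuse to a sublinear subset of each level -
# selection. Production adds copies of discovered objects at homogeneous
# rate k_p per object under a total mass budget, and the ensemble assembly
# A(t) follows from the assembly equation.

#' Selection/kinetics parameter set
#'
#' @param alpha Selectivity in `[0, 1]`: exponent of `P_a \propto (N_a)^alpha`.
#' @param k_d Discovery (expansion) rate, 1/time; `tau_d = 1/k_d`.
#' @param k_p Per-object copy-production rate, 1/time; `tau_p = 1/k_p`
#'   (`k_p = 0` disables production and `tau_p` is infinite).
#' @return A `selection_params` list with rates and timescales.
#' @export
selection_params <- function(alpha = 1, k_d = 1, k_p = 0) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (!is.finite(k_d) || k_d <= 0) stop("k_d must be positive and finite")
  if (!is.finite(k_p) || k_p < 0) stop("k_p must be non-negative and finite")
  structure(list(alpha = alpha, k_d = k_d, k_p = k_p,
                 tau_d = 1 / k_d, tau_p = if (k_p > 0) 1 / k_p else Inf),
            class = "selection_params")
}

#' Deterministic growth cascade across assembly levels
#'
#' Integrates `dN_{a+1}/dt = k_d (N_a)^alpha` for levels `a = 1..a_max` with
#' `N_1` constant. The rate out of an empty level is zero (nothing can be
#' built on objects that do not exist); `activation` optionally raises that
#' cutoff, e.g. `activation = 1` requires one whole object before a level
#' feeds the next, which makes the alpha = 0 front advance one level per
#' `1/k_d`. For alpha = 1 the cascade has the closed form
#' `N_a(t) = N_1 (k_d t)^(a-1) / (a-1)!`.
#'
#' @param params A [selection_params()] set.
#' @param N1 Initial (constant) count at level 1.
#' @param t_grid Increasing numeric time grid starting at 0.
#' @param a_max Deepest level integrated.
#' @param activation Threshold below which a level's feed rate is zero
#'   (default 0: any positive mass feeds the next level).
#' @param rtol,atol Solver tolerances. The defaults are extreme (deep levels
#'   hold values around 1e-10 early on and are still resolved relatively);
#'   with a positive `activation` threshold the right-hand side is
#'   discontinuous and looser tolerances (around 1e-8) are appropriate.
#' @return A `growth_trajectory`: list with `t`, matrix `N` (rows = times,
#'   columns = levels) and `params`.
#' @export
integrate_growth <- function(params, N1, t_grid, a_max = 10L, activation = 0,
                             rtol = 1e-12, atol = 1e-22) {
  stopifnot(inherits(params, "selection_params"))
  if (!is.finite(N1) || N1 <= 0) stop("N1 must be positive and finite")
  if (any(!is.finite(t_grid))) stop("non-finite time grid")
  a_max <- as.integer(a_max)
  rhs <- function(t, y, p) {
    feed <- ifelse(y > activation, p$k_d * pmax(y, 0)^p$alpha, 0)
    dy <- c(0, feed[-length(y)])
    list(dy)
  }
  y0 <- c(N1, rep(0, a_max - 1L))
  sol <- deSolve::lsoda(y0, t_grid, rhs, params, rtol = rtol, atol = atol)
  N <- unname(as.matrix(sol[, -1, drop = FALSE]))
  structure(list(t = t_grid, N = N, params = params),
            class = "growth_trajectory")
}

#' Closed-form alpha = 1 cascade (Poisson form)
#' @param params,N1,t_grid,a_max As in [integrate_growth()].
#' @return Matrix of `N_a(t) = N1 (k_d t)^(a-1)/(a-1)!`.
#' @export
growth_closed_form <- function(params, N1, t_grid, a_max = 10L) {
  outer(t_grid, seq_len(a_max), function(t, a)
    N1 * (params$k_d * t)^(a - 1) / factorial(a - 1))
}

# ---- stochastic engine -----------------------------------------------------

# Object bookkeeping: per level, a count of objects in discovery order; the
# "available" subset of level a is its first ceiling(N_a^alpha) objects, so
# the probability of a level being used is proportional to (N_a)^alpha.
# A discovery event picks a parent u from the chosen level's available
# subset and a partner v from all available objects; the product (u, v) is
# new only if that pair has not combined before (combinatorial identity), so
# strong selection (small available subsets) repeatedly rediscovers the same
# objects and unique-object growth slows below exponential.

#' Stochastic discovery dynamics
#'
#' Continuous-time realization of the discovery cascade: events occur at
#' total rate `k_d * sum_a ceil(N_a^alpha)`; each event combines a selected
#' object at level `a` with a partner from the available pool and, if the
#' pair is novel, adds one object at level `a + 1`.
#'
#' @param params A [selection_params()] set (only `alpha`, `k_d` used).
#' @param seed Integer seed (recorded in the result).
#' @param N1 Objects in the elementary basis (level 1).
#' @param max_events Stop after this many events (Inf to disable).
#' @param t_end Stop at this simulated time (Inf to disable); at least one
#'   of `max_events`, `t_end` must be finite.
#' @param t_grid Optional time grid on which to record `N_a(t)`.
#' @param a_max Deepest level tracked.
#' @return A `growth_trajectory` with fields `t`, `N` (levels over the grid
#'   or at event times), `events`, `novel`, `seed`.
#' @export
stochastic_growth <- function(params, seed, N1 = 100L, max_events = Inf,
                              t_end = Inf, t_grid = NULL, a_max = 12L) {
  stopifnot(inherits(params, "selection_params"))
  if (!is.finite(max_events) && !is.finite(t_end))
    stop("one of max_events or t_end must be finite")
  set.seed(as.integer(seed))
  alpha <- params$alpha; k_d <- params$k_d
  N <- c(N1, rep(0L, a_max - 1L))
  pair_seen <- new.env(parent = emptyenv())
  t_now <- 0; events <- 0L; novel <- 0L
  rec_t <- if (is.null(t_grid)) numeric(0) else t_grid
  rec_N <- matrix(0, nrow = length(rec_t), ncol = a_max)
  rec_i <- 1L
  flush_grid <- function(upto) {
    while (rec_i <= length(rec_t) && rec_t[rec_i] <= upto) {
      rec_N[rec_i, ] <<- N
      rec_i <<- rec_i + 1L
    }
  }
  repeat {
    avail <- ceiling(pmax(N, 0)^alpha)
    avail[N == 0L] <- 0
    rate <- k_d * sum(avail)
    if (rate <= 0 || events >= max_events) break
    dt <- rexp(1L, rate)
    if (t_now + dt > t_end) { t_now <- t_end; break }
    t_now <- t_now + dt
    flush_grid(t_now)
    lv <- sample.int(a_max, 1L, prob = avail)
    if (lv < a_max) {
      u <- sample.int(avail[lv], 1L)
      # partner: uniform over all available objects across levels
      cum <- cumsum(avail)
      vglob <- sample.int(cum[a_max], 1L)
      vlv <- findInterval(vglob - 1L, c(0, cum))  # level of partner
      key <- paste(lv, u, vlv, vglob - c(0, cum)[vlv], sep = "_")
      if (is.null(pair_seen[[key]])) {
        pair_seen[[key]] <- TRUE
        N[lv + 1L] <- N[lv + 1L] + 1L
        novel <- novel + 1L
      }
    }
    events <- events + 1L
  }
  flush_grid(Inf)
  if (is.null(t_grid)) { rec_t <- t_now; rec_N <- matrix(N, nrow = 1L) }
  structure(list(t = rec_t, N = rec_N, final_N = N, t_final = t_now,
                 events = events, novel = novel, params = params,
                 seed = as.integer(seed)), class = "growth_trajectory")
}

#' Coupled discovery and production kinetics with a mass budget
#'
#' Discovery events (as in [stochastic_growth()]) compete with copy
#' production: every discovered object (levels >= 2) gains copies at the
#' homogeneous rate `k_p` per object. Every discovery and every produced
#' copy consumes one unit of a total mass budget `M`; the simulation ends
#' cleanly when the budget is exhausted or `t_end` is reached. The ensemble
#' assembly A(t) is evaluated over discovered objects via the assembly
#' equation, with the assembly index of a level-`a` object equal to `a - 1`.
#'
#' @param params A [selection_params()] set.
#' @param seed Integer seed.
#' @param t_end End time.
#' @param N1 Basis objects at level 1.
#' @param M Total mass budget (copies, including first copies on discovery).
#' @param a_max Deepest level tracked.
#' @param n_record Number of time points at which A(t) is recorded.
#' @return List with `objects` (data frame: `level`, `a` = level - 1,
#'   `copies`), `A_final`, `trajectory` (data frame `t`, `A`, `unique`,
#'   `copies`), `mass_used`, `t_final`, `seed`.
#' @export
discovery_production_sim <- function(params, seed, t_end, N1 = 100L, M = 100L,
                                     a_max = 12L, n_record = 50L) {
  stopifnot(inherits(params, "selection_params"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive and finite")
  set.seed(as.integer(seed))
  alpha <- params$alpha; k_d <- params$k_d; k_p <- params$k_p
  N <- c(N1, rep(0L, a_max - 1L))
  obj_level <- integer(0)   # level of each discovered object (>= 2)
  obj_copies <- integer(0)
  pair_seen <- new.env(parent = emptyenv())
  mass <- 0L; t_now <- 0
  rec <- data.frame(t = numeric(0), A = numeric(0), unique = integer(0),
                    copies = numeric(0))
  grid <- seq(0, t_end, length.out = n_record)
  gi <- 1L
  snapshot <- function(tp) {
    A <- if (length(obj_copies)) {
      NT <- sum(obj_copies)
      sum(exp(obj_level - 1) * (obj_copies - 1)) / NT
    } else 0
    rec[nrow(rec) + 1L, ] <<- list(tp, A, length(obj_copies), sum(obj_copies))
  }
  repeat {
    avail <- ceiling(pmax(N, 0)^alpha); avail[N == 0L] <- 0
    r_disc <- k_d * sum(avail)
    r_prod <- k_p * length(obj_level)
    rate <- r_disc + r_prod
    if (rate <= 0 || mass >= M) break
    dt <- rexp(1L, rate)
    if (t_now + dt > t_end) { t_now <- t_end; break }
    t_now <- t_now + dt
    while (gi <= length(grid) && grid[gi] <= t_now) { snapshot(grid[gi]); gi <- gi + 1L }
    if (runif(1L) < r_disc / rate) {
      lv <- sample.int(a_max, 1L, prob = avail)
      if (lv < a_max) {
        u <- sample.int(avail[lv], 1L)
        cum <- cumsum(avail)
        vglob <- sample.int(cum[a_max], 1L)
        vlv <- findInterval(vglob - 1L, c(0, cum))
        key <- paste(lv, u, vlv, vglob - c(0, cum)[vlv], sep = "_")
        if (is.null(pair_seen[[key]])) {
          pair_seen[[key]] <- TRUE
          N[lv + 1L] <- N[lv + 1L] + 1L
          obj_level <- c(obj_level, lv + 1L)
          obj_copies <- c(obj_copies, 1L)
          mass <- mass + 1L
        }
      }
    } else {
      i <- sample.int(length(obj_level), 1L)
      obj_copies[i] <- obj_copies[i] + 1L
      mass <- mass + 1L
    }
  }
  while (gi <= length(grid)) { snapshot(grid[gi]); gi <- gi + 1L }
  A_final <- if (length(obj_copies))
    sum(exp(obj_level - 1) * (obj_copies - 1)) / sum(obj_copies) else 0
  list(objects = data.frame(level = obj_level, a = obj_level - 1L,
                            copies = obj_copies),
       A_final = A_final, trajectory = rec, mass_used = mass,
       t_final = t_now, N = N, params = params, seed = as.integer(seed))
}

#' Classify the discovery/production timescale regime
#'
#' Regime 1: discovery much faster than production (`tau_d/tau_p < r_low`) -
#' combinatorial explosion of singletons, selection unlikely. Regime 2:
#' production much faster (`tau_d/tau_p > r_high`) - high copy numbers of
#' low-assembly objects, selection unlikely. Regime 3: comparable timescales
#' - selection possible.
#'
#' @param tau_d,tau_p Positive discovery and production timescales.
#' @param r_low,r_high Regime thresholds (defaults 0.1 and 10).
#' @return Integer 1, 2 or 3.
#' @export
regime_classify <- function(tau_d, tau_p, r_low = 0.1, r_high = 10) {
  if (!is.finite(tau_d) || !is.finite(tau_p) || tau_d <= 0 || tau_p <= 0)
    stop("timescales must be positive and finite")
  r <- tau_d / tau_p
  if (r < r_low) 1L else if (r > r_high) 2L else 3L
}

#' Estimate selection parameters from observed discovery time series
#'
#' Interface stub for fitting `alpha` and `k_d` to experimentally observed
#' counts of unique objects per assembly index over time (e.g. from
#' time-resolved mass spectrometry). Estimation on real data is out of
#' scope for this package version; the function documents the expected
#' input contract and fails explicitly.
#'
#' @param counts Data frame with columns `t`, `a`, `N` (unique objects with
#'   assembly index `a` observed by time `t`).
#' @return Never returns; signals a not-implemented error.
#' @export
estimate_selection_params <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("t", "a", "N") %in% names(counts)))
  stop("estimation of (alpha, k_d) from observed time series is not implemented; ",
       "see the methods vignette for the forward models this would invert")
}
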