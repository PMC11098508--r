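#' Expected days until a mosquito is trapped, per origin site
#'
#' Solves the standard absorbing-Markov-chain expectation: with transient
#' block Q (site-to-site movement after trap renormalization), the expected
#' number of steps to absorption from each origin is
#' \eqn{t = (I - Q)^{-1} \mathbf{1}}, computed as a linear solve of
#' \eqn{(I - Q) t = \mathbf{1}} rather than an explicit inverse. Because the
#' movement matrix holds daily probabilities, steps are days.
#'
#' Origins from which absorption is not certain (no path to any trap, or a
#' reachable sink that itself cannot reach a trap) receive an `Inf` sentinel
#' instead of raising, so optimizers can rank and discard such
#' configurations. The same sentinel is used when the transient system is
#' numerically singular (reciprocal condition number below 1e-12).
#'
#' @param chain a [augment_chain()] result.
#' @return numeric vector of expected days per origin site (`Inf` where
#'   absorption is not certain).
#' @examples
#' ls <- landscape(data.frame(x = 0, y = 0), dispersal_kernel("exponential"))
#' ch <- augment_chain(ls, list(trap(trap_kernel("exponential", A = 0.5), node = 0)))
#' expected_absorption_time(ch)  # geometric mean 1/p = 3 days
#' @export
expected_absorption_time <- function(chain) {
  stopifnot(inherits(chain, "trap_chain"))
  Q <- chain$Q
  n <- nrow(Q)
  fin <- certain_absorption_sites(Q, chain$R)
  t <- rep(Inf, n)
  if (any(fin)) {
    A <- diag(1, sum(fin)) - Q[fin, fin, drop = FALSE]
    ok <- TRUE
    rc <- tryCatch(rcond(A), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-12) ok <- FALSE
    if (ok) {
      sol <- tryCatch(solve(A, rep(1, sum(fin))), error = function(e) NULL)
      if (!is.null(sol)) t[fin] <- sol else ok <- FALSE
    }
  }
  t
}

# Logical vector: origins for which absorption is certain. An origin has a
# finite expectation iff it cannot reach any state that is unable to reach a
# trap.
certain_absorption_sites <- function(Q, R) {
  n <- nrow(Q)
  adj <- Q > 0
  diag(adj) <- FALSE
  can_trap <- backward_reach(adj, rowSums(R) > 0)
  if (all(can_trap)) return(rep(TRUE, n))
  hits_bad <- backward_reach(adj, !can_trap)
  !hits_bad
}

# States from which some state in `seed` is reachable (including seed
# states), over directed adjacency `adj`.
backward_reach <- function(adj, seed) {
  reach <- seed
  repeat {
    nxt <- reach | (adj %*% reach > 0)
    if (all(nxt == reach)) return(as.vector(reach))
    reach <- nxt
  }
}

#' Mean expected trapping time over origin sites (days)
#'
#' The mean-time objective: the arithmetic mean of [expected_absorption_time()]
#' over all origin sites, i.e. the expected days-to-trapping of a mosquito
#' whose origin is uniform over the landscape. `Inf` if any origin cannot be
#' absorbed, so unreachable configurations rank strictly worst.
#'
#' @param t numeric vector of per-origin expected days.
#' @return scalar days.
#' @export
fitness_mean <- function(t) {
  if (length(t) < 1L) stop("empty absorption profile")
  if (any(is.infinite(t))) return(Inf)
  mean(t)
}

#' Maximum expected trapping time over origin sites (days)
#'
#' The worst-case objective: the expected days-to-trapping starting from the
#' origin for which this time is longest. Useful when confinement matters
#' more than average detection speed.
#'
#' @param t numeric vector of per-origin expected days.
#' @return scalar days.
#' @export
fitness_max <- function(t) {
  if (length(t) < 1L) stop("empty absorption profile")
  max(t)
}

#' Monte-Carlo random-walk oracle for absorption times
#'
#' Simulates independent mosquito random walks on the full transition matrix
#' and records the step at which each walker is absorbed by a trap. Serves
#' as an independent empirical check of the fundamental-matrix solve.
#'
#' @param chain a [augment_chain()] result.
#' @param n_walkers walkers per origin site.
#' @param max_steps cap on walk length; walkers still transient at the cap
#'   are censored and excluded from the mean.
#' @param seed optional RNG seed.
#' @return data frame with one row per origin site: `site` (0-based id),
#'   `mean` and `se` of days-to-trapping among absorbed walkers,
#'   `n_absorbed`, `n_censored`.
#' @export
simulate_walkers <- function(chain, n_walkers = 1000, max_steps = 100000,
                             seed = NULL) {
  stopifnot(inherits(chain, "trap_chain"))
  if (n_walkers < 1) stop("n_walkers must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(chain$Q)
  m <- ncol(chain$P)
  cum <- t(apply(chain$P[seq_len(n), , drop = FALSE], 1L, cumsum))
  out <- data.frame(site = seq_len(n) - 1L, mean = NA_real_, se = NA_real_,
                    n_absorbed = 0L, n_censored = 0L)
  for (i in seq_len(n)) {
    state <- rep.int(i, n_walkers)
    time_abs <- rep(NA_real_, n_walkers)
    active <- seq_len(n_walkers)
    step <- 0L
    while (length(active) > 0L && step < max_steps) {
      step <- step + 1L
      u <- stats::runif(length(active))
      nxt <- rowSums(cum[state[active], , drop = FALSE] < u) + 1L
      state[active] <- nxt
      done <- nxt > n
      if (any(done)) {
        time_abs[active[done]] <- step
        active <- active[!done]
      }
    }
    ta <- time_abs[!is.na(time_abs)]
    out$n_absorbed[i] <- length(ta)
    out$n_censored[i] <- n_walkers - length(ta)
    if (length(ta) > 0L) {
      out$mean[i] <- mean(ta)
      out$se[i] <- stats::sd(ta) / sqrt(length(ta))
    }
  }
  out
}

#' Simulate walker absorption times from a trap chain
#'
#' `simulate()` method wrapping [simulate_walkers()].
#'
#' @param object a `trap_chain`.
#' @param nsim walkers per origin site.
#' @param seed optional RNG seed.
#' @param max_steps walk-length cap.
#' @param ... ignored.
#' @export
simulate.trap_chain <- function(object, nsim = 1000, seed = NULL,
                                max_steps = 100000, ...) {
  simulate_walkers(object, n_walkers = nsim, max_steps = max_steps, seed = seed)
}

#' Export an absorption profile as CSV
#'
#' Writes `site_id,expected_days` (0-based site ids).
#'
#' @param t vector of per-origin expected days.
#' @param path output file.
#' @export
write_absorption_profile <- function(t, path) {
  utils::write.csv(data.frame(site_id = seq_along(t) - 1L, expected_days = t),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
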