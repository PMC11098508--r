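#' @export
print.trap_opt <- function(x, ...) {
  L <- length(x$movable_kernels)
  cat(sprintf("Optimized trap placement (%s mode, %s objective)\n",
              x$mode, x$objective))
  cat(sprintf("  %d movable trap%s, %d fixed; %d site%s\n",
              L, if (L == 1) "" else "s", length(x$fixed_traps),
              nrow(x$landscape$sites),
              if (nrow(x$landscape$sites) == 1) "" else "s"))
  cat(sprintf("  best expected trapping time: %.4f days\n", x$best_fitness))
  cat(sprintf("  %d repetition(s) x %d generations, population %d, seed %d\n",
              x$control$repetitions, x$control$generations,
              x$control$pop_size, x$seed))
  invisible(x)
}

#' Placements of the optimized traps
#'
#' In discrete mode, 0-based node indices of the movable traps; in
#' continuous mode, their coordinate matrix.
#'
#' @param object a `trap_opt`.
#' @param ... ignored.
#' @export
coef.trap_opt <- function(object, ...) object$best_genes

#' @export
summary.trap_opt <- function(object, ...) {
  chain <- augment_chain(object$landscape, object$best_traps)
  t <- expected_absorption_time(chain)
  last <- object$trace[object$trace$generation == max(object$trace$generation), ]
  out <- list(objective = object$objective, mode = object$mode,
              best_fitness = object$best_fitness,
              profile = t,
              per_rep_final = last$best,
              placements = object$best_genes,
              n_fixed = length(object$fixed_traps))
  class(out) <- "summary.trap_opt"
  out
}

#' @export
print.summary.trap_opt <- function(x, ...) {
  cat(sprintf("Trap placement summary (%s mode, %s objective)\n", x$mode, x$objective))
  cat(sprintf("  best fitness: %.4f days; per-repetition finals: %s\n",
              x$best_fitness, paste(sprintf("%.2f", x$per_rep_final), collapse = ", ")))
  cat("  expected days to trapping by origin site:\n")
  print(summary(x$profile))
  invisible(x)
}

#' Expected days to trapping per origin under the optimal placement
#'
#' @param object a `trap_opt`.
#' @param ... ignored.
#' @export
fitted.trap_opt <- function(object, ...) {
  expected_absorption_time(augment_chain(object$landscape, object$best_traps))
}

#' Simulate walkers on the optimized chain
#'
#' @param object a `trap_opt`.
#' @param nsim walkers per origin site.
#' @param seed optional RNG seed.
#' @param ... passed to [simulate_walkers()].
#' @export
simulate.trap_opt <- function(object, nsim = 1000, seed = NULL, ...) {
  simulate_walkers(augment_chain(object$landscape, object$best_traps),
                   n_walkers = nsim, seed = seed, ...)
}

#' Plot an optimization result
#'
#' `which = "trace"` draws the per-generation best fitness of each
#' repetition (log-scaled y when the spread warrants it); `which = "map"`
#' draws the landscape with the optimal trap positions.
#'
#' @param x a `trap_opt`.
#' @param which `"trace"` or `"map"`.
#' @param ... passed through to the underlying plot.
#' @export
plot.trap_opt <- function(x, which = c("trace", "map"), ...) {
  which <- match.arg(which)
  if (which == "map") {
    plot.landscape(x$landscape, traps = x$best_traps, ...)
  } else {
    tr <- x$trace
    finite <- tr$best[is.finite(tr$best)]
    ylim <- range(finite)
    graphics::plot(NA, xlim = range(tr$generation), ylim = ylim,
                   xlab = "generation", ylab = "best fitness (days)", ...)
    for (r in unique(tr$repetition)) {
      sub <- tr[tr$repetition == r, ]
      graphics::lines(sub$generation, sub$best, col = r)
    }
  }
  invisible(x)
}
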