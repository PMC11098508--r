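#' Genetic-algorithm control parameters
#'
#' Conventional evolutionary-toolbox defaults, all exposed. A chromosome is
#' the ordered list of movable-trap placements: node indices in discrete
#' mode, `(x, y)` pairs in continuous mode. Fixed (immovable) traps live
#' outside the genome, which guarantees they are never perturbed by
#' crossover or mutation.
#'
#' @param pop_size population size.
#' @param generations number of generations per repetition.
#' @param cx_prob probability a selected pair undergoes two-point crossover.
#' @param mut_prob probability an offspring undergoes mutation.
#' @param gene_mut_rate per-gene mutation rate within a mutated chromosome.
#' @param tournament_size tournament size for selection (minimization).
#' @param sigma_frac continuous-mode Gaussian mutation scale as a fraction of
#'   the bounding-box diagonal.
#' @param elite size of the elite archive carried across generations
#'   (1 preserves the best-so-far solution and makes the best-fitness trace
#'   non-increasing).
#' @param repetitions independent seeded restarts; the reported result is the
#'   best across repetitions and every trace is retained.
#' @param seed integer seed; repetition r uses `seed + r - 1`.
#' @return a list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 128, generations = 500, cx_prob = 0.7,
                       mut_prob = 0.3, gene_mut_rate = 0.5,
                       tournament_size = 3, sigma_frac = 0.05, elite = 1,
                       repetitions = 1, seed = 1) {
  probs <- c(cx_prob, mut_prob, gene_mut_rate)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(pop_size, generations, tournament_size, repetitions)
  if (any(counts < 1)) stop("counts must be >= 1")
  if (sigma_frac < 0) stop("sigma_frac must be non-negative")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 cx_prob = cx_prob, mut_prob = mut_prob,
                 gene_mut_rate = gene_mut_rate,
                 tournament_size = as.integer(tournament_size),
                 sigma_frac = sigma_frac, elite = as.integer(elite),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "ga_control")
}

# Build the trap list for a chromosome: fixed traps first, then movable
# traps at the chromosome's placements.
chromosome_traps <- function(genes, fixed_traps, movable_kernels, mode) {
  mov <- if (mode == "discrete") {
    lapply(seq_along(movable_kernels), function(j)
      trap(movable_kernels[[j]], node = genes[j]))
  } else {
    lapply(seq_along(movable_kernels), function(j)
      trap(movable_kernels[[j]], x = genes[j, 1], y = genes[j, 2]))
  }
  c(fixed_traps, mov)
}

#' Evaluate a trap placement's fitness (expected days to trapping)
#'
#' Composes the pipeline: build the trap set (fixed + movable at the
#' chromosome's placements), augment the movement matrix into the absorbing
#' chain, solve for per-origin expected absorption times, and reduce with
#' the mean or max objective. Duplicate placements are allowed — co-located
#' traps simply compete through the shared renormalization.
#'
#' @param genes integer vector of 0-based node indices (discrete mode) or a
#'   two-column coordinate matrix (continuous mode), one gene per movable
#'   trap.
#' @param ls a [landscape()].
#' @param fixed_traps list of immovable [trap()]s (may be empty).
#' @param movable_kernels list of [trap_kernel()]s, one per movable trap.
#' @param objective `"mean"` or `"max"`.
#' @param mode `"discrete"` or `"continuous"`.
#' @return scalar days (`Inf` when some origin cannot reach any trap).
#' @export
evaluate_placement <- function(genes, ls, fixed_traps, movable_kernels,
                               objective = c("mean", "max"),
                               mode = c("discrete", "continuous")) {
  objective <- match.arg(objective)
  mode <- match.arg(mode)
  traps <- chromosome_traps(genes, fixed_traps, movable_kernels, mode)
  t <- expected_absorption_time(augment_chain(ls, traps))
  if (objective == "mean") fitness_mean(t) else fitness_max(t)
}

#' Discrete mutation: resample node indices
#'
#' Each gene is independently resampled uniformly over the `n_sites` node
#' indices with probability `rate`.
#'
#' @param genes integer vector of 0-based node indices.
#' @param rate per-gene mutation rate.
#' @param n_sites number of landscape sites.
#' @return mutated gene vector.
#' @export
mutate_discrete <- function(genes, rate, n_sites) {
  hit <- stats::runif(length(genes)) < rate
  if (any(hit)) genes[hit] <- sample.int(n_sites, sum(hit), replace = TRUE) - 1L
  genes
}

#' Continuous mutation: Gaussian coordinate perturbation
#'
#' Each gene (coordinate pair) is perturbed with probability `rate` by
#' independent `N(0, sigma)` noise on both axes, then clipped to the
#' bounding box.
#'
#' @param genes two-column coordinate matrix.
#' @param rate per-gene mutation rate.
#' @param sigma Gaussian standard deviation (coordinate units).
#' @param bounds `c(xmin, xmax, ymin, ymax)` bounding box.
#' @return mutated coordinate matrix.
#' @export
mutate_continuous <- function(genes, rate, sigma, bounds) {
  hit <- stats::runif(nrow(genes)) < rate
  if (any(hit)) {
    k <- sum(hit)
    genes[hit, 1] <- genes[hit, 1] + stats::rnorm(k, 0, sigma)
    genes[hit, 2] <- genes[hit, 2] + stats::rnorm(k, 0, sigma)
    genes[, 1] <- pmin(pmax(genes[, 1], bounds[1]), bounds[2])
    genes[, 2] <- pmin(pmax(genes[, 2], bounds[3]), bounds[4])
  }
  genes
}

#' Two-point crossover on the gene list
#'
#' Genes are whole placements (a node index or a coordinate pair — pairs are
#' never split). The two children jointly conserve the multiset of parental
#' genes. Chromosomes of fewer than two genes are returned unchanged.
#'
#' @param a,b parent chromosomes (vectors or coordinate matrices of equal
#'   length).
#' @return list of two children.
#' @export
crossover_twopoint <- function(a, b) {
  L <- if (is.matrix(a)) nrow(a) else length(a)
  if (L < 2L) return(list(a, b))
  cut <- sort(sample.int(L + 1L, 2L) - 1L)   # 0 <= cut1 <= cut2 <= L
  if (cut[1] == cut[2]) return(list(a, b))
  seg <- (cut[1] + 1L):cut[2]
  if (is.matrix(a)) {
    tmp <- a[seg, , drop = FALSE]; a[seg, ] <- b[seg, , drop = FALSE]; b[seg, ] <- tmp
  } else {
    tmp <- a[seg]; a[seg] <- b[seg]; b[seg] <- tmp
  }
  list(a, b)
}

#' Tournament selection (minimization)
#'
#' Draws `k` winners; each winner is the minimum-fitness member of a
#' uniformly drawn (without replacement) tournament, ties broken by lowest
#' population index, so a tournament as large as the population always
#' returns the global best. `Inf` fitnesses compare as worst.
#'
#' @param fitnesses numeric vector of fitnesses for the population.
#' @param k number of winners to draw.
#' @param tournament_size members per tournament.
#' @return integer vector of selected population indices.
#' @export
select_tournament <- function(fitnesses, k, tournament_size) {
  n <- length(fitnesses)
  tournament_size <- min(tournament_size, n)
  vapply(seq_len(k), function(i) {
    idx <- sort(sample.int(n, tournament_size))
    idx[which.min(fitnesses[idx])]
  }, integer(1))
}

# Bounding box of the sites, padded by 5% per side (continuous mode).
site_bounds <- function(sites, pad = 0.05) {
  rx <- range(sites$x); ry <- range(sites$y)
  px <- max(diff(rx), .Machine$double.eps) * pad
  py <- max(diff(ry), .Machine$double.eps) * pad
  c(rx[1] - px, rx[2] + px, ry[1] - py, ry[2] + py)
}

#' Optimize trap placement with a genetic algorithm
#'
#' The package's central fitting function: searches for the trap
#' configuration minimizing the expected days until a mosquito is trapped
#' (mean or worst-case over origin sites). Candidate configurations are
#' chromosomes of movable-trap placements; immovable traps are supplied via
#' `fixed_traps` and never move. Each generation evaluates the population,
#' selects parents by tournament, recombines with two-point crossover,
#' mutates, and re-injects the best-so-far solution (elitism), so the
#' best-fitness trace is non-increasing. Runs are fully reproducible given
#' the control seed; `repetitions > 1` performs independent seeded restarts
#' and reports the best.
#'
#' @param ls a [landscape()].
#' @param movable_kernels list of [trap_kernel()]s, one per movable trap
#'   (a single kernel is recycled via `n_traps`).
#' @param fixed_traps list of immovable [trap()]s (default none).
#' @param n_traps convenience: replicate a single movable kernel this many
#'   times.
#' @param objective `"mean"` or `"max"` expected trapping time.
#' @param mode `"discrete"` (placements restricted to sites) or
#'   `"continuous"` (free coordinates within the padded site bounding box).
#' @param control a [ga_control()].
#' @param init optional list of chromosomes seeded into the initial
#'   population (e.g. warm starts from a smaller trap count).
#' @return object of class `trap_opt`: best placement and fitness, the
#'   per-generation trace of every repetition, the optimal trap list, and a
#'   configuration echo. Methods: `print`, `summary`, `coef` (placements),
#'   `plot`, `simulate` (Monte-Carlo walkers on the optimal chain),
#'   `fitted` (per-origin expected days).
#' @examples
#' ls <- landscape(make_landscape("grid", n_sites = 9),
#'                 dispersal_kernel("exponential", m = 1))
#' fit <- optimize_traps(ls, trap_kernel("exponential", A = 0.5, radius = 1),
#'                       control = ga_control(pop_size = 16, generations = 20))
#' coef(fit)
#' @export
optimize_traps <- function(ls, movable_kernels, fixed_traps = list(),
                           n_traps = NULL,
                           objective = c("mean", "max"),
                           mode = c("discrete", "continuous"),
                           control = ga_control(), init = list()) {
  objective <- match.arg(objective)
  mode <- match.arg(mode)
  stopifnot(inherits(ls, "landscape"), inherits(control, "ga_control"))
  if (inherits(movable_kernels, "trap_kernel")) {
    movable_kernels <- rep(list(movable_kernels), if (is.null(n_traps)) 1L else n_traps)
  }
  L <- length(movable_kernels)
  if (L < 1L) stop("at least one movable trap is required")
  n_sites <- nrow(ls$sites)
  bounds <- site_bounds(ls$sites)
  sigma <- control$sigma_frac *
    sqrt((bounds[2] - bounds[1])^2 + (bounds[4] - bounds[3])^2)

  eval_cache <- new.env(parent = emptyenv())
  eval_one <- function(genes) {
    if (mode == "discrete") {
      key <- paste(genes, collapse = ",")
      hit <- eval_cache[[key]]
      if (!is.null(hit)) return(hit)
      f <- evaluate_placement(genes, ls, fixed_traps, movable_kernels,
                              objective, mode)
      eval_cache[[key]] <- f
      f
    } else {
      evaluate_placement(genes, ls, fixed_traps, movable_kernels,
                         objective, mode)
    }
  }
  rand_chrom <- function() {
    if (mode == "discrete") sample.int(n_sites, L, replace = TRUE) - 1L
    else cbind(stats::runif(L, bounds[1], bounds[2]),
               stats::runif(L, bounds[3], bounds[4]))
  }

  best_overall <- NULL
  best_fit_overall <- Inf
  traces <- vector("list", control$repetitions)
  warn_unreachable <- FALSE

  for (rep_i in seq_len(control$repetitions)) {
    set.seed(control$seed + rep_i - 1L)
    pop <- c(init, replicate(control$pop_size - length(init), rand_chrom(),
                             simplify = FALSE))
    pop <- pop[seq_len(control$pop_size)]
    fit <- vapply(pop, eval_one, numeric(1))
    if (all(is.infinite(fit))) warn_unreachable <- TRUE
    elite_i <- which.min(fit)
    elite <- pop[[elite_i]]; elite_fit <- fit[elite_i]
    trace <- matrix(NA_real_, control$generations, 2,
                    dimnames = list(NULL, c("best", "mean")))
    for (gen in seq_len(control$generations)) {
      sel <- select_tournament(fit, control$pop_size, control$tournament_size)
      off <- pop[sel]
      i <- 1L
      while (i + 1L <= length(off)) {
        if (stats::runif(1) < control$cx_prob) {
          ch <- crossover_twopoint(off[[i]], off[[i + 1L]])
          off[[i]] <- ch[[1]]; off[[i + 1L]] <- ch[[2]]
        }
        i <- i + 2L
      }
      for (j in seq_along(off)) {
        if (stats::runif(1) < control$mut_prob) {
          off[[j]] <- if (mode == "discrete")
            mutate_discrete(off[[j]], control$gene_mut_rate, n_sites)
          else
            mutate_continuous(off[[j]], control$gene_mut_rate, sigma, bounds)
        }
      }
      pop <- off
      fit <- vapply(pop, eval_one, numeric(1))
      # elitism: re-insert the best-so-far over the current worst
      if (control$elite > 0L && elite_fit < min(fit)) {
        worst <- which.max(fit)
        pop[[worst]] <- elite; fit[worst] <- elite_fit
      }
      gi <- which.min(fit)
      if (fit[gi] < elite_fit) { elite <- pop[[gi]]; elite_fit <- fit[gi] }
      trace[gen, ] <- c(elite_fit, mean(fit))
    }
    traces[[rep_i]] <- data.frame(repetition = rep_i,
                                  generation = seq_len(control$generations),
                                  best = trace[, "best"], mean = trace[, "mean"])
    if (elite_fit < best_fit_overall) {
      best_fit_overall <- elite_fit
      best_overall <- elite
    }
  }

  best_traps <- chromosome_traps(best_overall, fixed_traps, movable_kernels, mode)
  res <- structure(list(best_genes = best_overall,
                        best_fitness = best_fit_overall,
                        best_traps = best_traps,
                        trace = do.call(rbind, traces),
                        objective = objective, mode = mode,
                        fixed_traps = fixed_traps,
                        movable_kernels = movable_kernels,
                        landscape = ls, control = control,
                        seed = control$seed,
                        warn_unreachable = warn_unreachable),
                   class = "trap_opt")
  if (warn_unreachable)
    warning("an initial population contained only configurations from which some origin could not be trapped")
  res
}

#' Exhaustive discrete optimum by multiset enumeration
#'
#' Enumerates every multiset of node placements for the movable traps
#' (order is irrelevant because trap kernels of the same index are
#' interchangeable only when identical; enumeration uses ordered tuples when
#' kernels differ) and returns the exact global optimum. Serves as the
#' correctness oracle for the genetic algorithm on small instances.
#'
#' @inheritParams optimize_traps
#' @param cap refuse when the number of candidate placements exceeds this.
#' @return list with `best_genes` (0-based node indices), `best_fitness`
#'   (days) and `n_evaluated`.
#' @export
brute_force_traps <- function(ls, movable_kernels, fixed_traps = list(),
                              n_traps = NULL,
                              objective = c("mean", "max"),
                              cap = 200000) {
  objective <- match.arg(objective)
  if (inherits(movable_kernels, "trap_kernel")) {
    movable_kernels <- rep(list(movable_kernels), if (is.null(n_traps)) 1L else n_traps)
  }
  L <- length(movable_kernels)
  n <- nrow(ls$sites)
  identical_kernels <- L == 1L ||
    all(vapply(movable_kernels[-1], identical, logical(1), movable_kernels[[1]]))
  n_comb <- if (identical_kernels) choose(n + L - 1, L) else n^L
  if (n_comb > cap)
    stop(sprintf("brute force would need %.0f evaluations (cap %d)", n_comb, cap))
  combos <- if (identical_kernels) multisets(n, L) else
    as.matrix(expand.grid(rep(list(seq_len(n)), L)))  # ordered tuples
  best_fit <- Inf; best <- NULL
  for (r in seq_len(nrow(combos))) {
    genes <- combos[r, ] - 1L
    f <- evaluate_placement(genes, ls, fixed_traps, movable_kernels,
                            objective, "discrete")
    if (f < best_fit) { best_fit <- f; best <- genes }
  }
  list(best_genes = best, best_fitness = best_fit, n_evaluated = nrow(combos))
}

# All multisets of size L from 1..n, as rows (non-decreasing tuples).
multisets <- function(n, L) {
  if (L == 1L) return(matrix(seq_len(n), ncol = 1))
  cmb <- utils::combn(n + L - 1L, L)
  t(cmb - (seq_len(L) - 1L))
}

#' Optimize over an increasing number of traps (diminishing returns sweep)
#'
#' Runs [optimize_traps()] for each trap count in `counts`, warm-starting
#' each run with the previous optimum extended by a random extra placement.
#' With elitism this makes the optimized fitness non-increasing in the trap
#' count, exposing the cost-effectiveness trade-off of adding traps.
#'
#' @inheritParams optimize_traps
#' @param kernel single movable [trap_kernel()], replicated per count.
#' @param counts increasing vector of movable-trap counts.
#' @return data frame `n_traps`, `fitness_days`, plus attribute `fits`
#'   (the `trap_opt` objects).
#' @export
sweep_trap_count <- function(ls, kernel, counts, fixed_traps = list(),
                             objective = c("mean", "max"),
                             mode = "discrete", control = ga_control()) {
  objective <- match.arg(objective)
  fits <- vector("list", length(counts))
  prev <- NULL
  n_sites <- nrow(ls$sites)
  for (i in seq_along(counts)) {
    init <- list()
    if (!is.null(prev)) {
      extra <- counts[i] - length(prev)
      set.seed(control$seed + 7919L * i)
      init <- list(c(prev, sample.int(n_sites, extra, replace = TRUE) - 1L))
    }
    fits[[i]] <- optimize_traps(ls, kernel, fixed_traps = fixed_traps,
                                n_traps = counts[i], objective = objective,
                                mode = mode, control = control, init = init)
    prev <- fits[[i]]$best_genes
  }
  out <- data.frame(n_traps = counts,
                    fitness_days = vapply(fits, function(f) f$best_fitness,
                                          numeric(1)))
  attr(out, "fits") <- fits
  out
}
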