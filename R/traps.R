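#' Trap attractiveness kernel constructor
#'
#' Maps the distance between a site and a trap to the raw odds weight of a
#' mosquito at that site entering the trap in one day. `A` is the maximum
#' attractiveness: with a trap co-located with a site, the daily ratio of
#' mosquitoes entering the trap to those that do not is `A : 1`, i.e. a
#' capture probability of `A / (1 + A)`.
#'
#' Families:
#' * `"exponential"`: \eqn{A \exp(-d / radius)}, `radius` the mean radius of
#'   attractiveness.
#' * `"sigmoidal"`: \eqn{A / (1 + \exp(shape (d - radius)))}, `radius` the
#'   inflection radius and `shape` the steepness. Note the value at `d = 0`
#'   is \eqn{A / (1 + e^{-shape \cdot radius})}, slightly below `A`: the
#'   maximum attractiveness is the supremum parameter, not the attained
#'   value.
#' * `"custom"`: any non-increasing non-negative function via `fun`
#'   (values are clipped to `A`).
#'
#' @param family `"exponential"`, `"sigmoidal"` or `"custom"`.
#' @param A maximum attractiveness in `[0, 1]` (dimensionless odds weight).
#' @param radius mean radius (exponential) or inflection radius (sigmoidal),
#'   in coordinate units (metres under haversine distances). Must be positive.
#' @param shape sigmoid steepness, `> 0` (sigmoidal only).
#' @param fun custom weight function of distance (custom only).
#' @param type_weights optional per-source-resource-type multiplier vector
#'   (e.g. an ovitrap mostly attracts females currently at a food node);
#'   defaults to all ones.
#' @return object of class `trap_kernel`.
#' @examples
#' trap_kernel("exponential", A = 0.5, radius = 15.88)
#' trap_kernel("sigmoidal", A = 0.5, radius = 16, shape = 0.25)
#' @export
trap_kernel <- function(family = c("exponential", "sigmoidal", "custom"),
                        A = 0.5, radius = 1, shape = NULL, fun = NULL,
                        type_weights = NULL) {
  family <- match.arg(family)
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A < 0 || A > 1)
    stop("maximum attractiveness 'A' must lie in [0, 1]")
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("'radius' must be a positive finite number")
  if (family == "sigmoidal") {
    if (is.null(shape) || !is.numeric(shape) || length(shape) != 1L ||
        !is.finite(shape) || shape <= 0)
      stop("sigmoidal kernels need a positive 'shape'")
  }
  if (family == "custom" && !is.function(fun)) stop("custom kernels require 'fun'")
  if (!is.null(type_weights) && (any(!is.finite(type_weights)) || any(type_weights < 0)))
    stop("'type_weights' must be finite and non-negative")
  structure(list(family = family, A = A, radius = radius, shape = shape,
                 fun = fun, type_weights = type_weights),
            class = "trap_kernel")
}

#' Raw trap attractiveness weight at a distance
#'
#' @param d vector of non-negative site-to-trap distances.
#' @param kernel a [trap_kernel()].
#' @return weights in `[0, A]`.
#' @examples
#' trap_attractiveness(0, trap_kernel("exponential", A = 0.5, radius = 24))
#' @export
trap_attractiveness <- function(d, kernel) {
  stopifnot(inherits(kernel, "trap_kernel"))
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and non-negative")
  w <- switch(kernel$family,
    exponential = kernel$A * exp(-d / kernel$radius),
    sigmoidal = kernel$A / (1 + exp(kernel$shape * (d - kernel$radius))),
    custom = kernel$fun(d))
  pmin(pmax(w, 0), kernel$A)
}

#' A single trap
#'
#' A trap is either node-bound (`node`, a 0-based site index: discrete
#' placement) or free (`x`, `y` coordinates: continuous placement), carries
#' an attractiveness kernel, and may be flagged immovable so the optimizer
#' leaves it in place.
#'
#' @param kernel a [trap_kernel()].
#' @param node 0-based site index for discrete placement.
#' @param x,y coordinates for continuous placement.
#' @param immovable logical; immovable traps are never moved by the
#'   optimizer.
#' @return object of class `trap`.
#' @export
trap <- function(kernel, node = NULL, x = NULL, y = NULL, immovable = FALSE) {
  stopifnot(inherits(kernel, "trap_kernel"))
  if (is.null(node) == is.null(x)) stop("give exactly one of 'node' or 'x'/'y'")
  if (!is.null(node)) {
    node <- as.integer(node)
    if (length(node) != 1L || is.na(node) || node < 0) stop("'node' must be a single index >= 0")
  } else {
    if (is.null(y) || !is.finite(x) || !is.finite(y)) stop("trap coordinates must be finite")
  }
  structure(list(kernel = kernel, node = node, x = x, y = y,
                 immovable = isTRUE(immovable)),
            class = "trap")
}

#' Resolve trap positions to coordinates
#'
#' Node-bound traps inherit their host site's coordinates; free traps pass
#' through unchanged. Order and flags are preserved.
#'
#' @param traps list of [trap()] objects.
#' @param sites site data frame (columns `x`, `y`).
#' @return numeric matrix with one `(x, y)` row per trap.
#' @export
resolve_trap_coordinates <- function(traps, sites) {
  if (length(traps) < 1L) stop("at least one trap is required")
  xy <- t(vapply(traps, function(tr) {
    if (!is.null(tr$node)) {
      if (tr$node + 1L > nrow(sites)) stop("trap node index out of range")
      c(sites$x[tr$node + 1L], sites$y[tr$node + 1L])
    } else c(tr$x, tr$y)
  }, numeric(2)))
  if (any(!is.finite(xy))) stop("trap coordinates must be finite")
  colnames(xy) <- c("x", "y")
  xy
}

# Site-to-trap distance matrix under the landscape's distance mode.
site_trap_distances <- function(ls, trap_xy) {
  s <- as.matrix(ls$sites[, c("x", "y")])
  if (ls$distance_mode == "haversine") {
    geosphere::distm(s, trap_xy, fun = function(p1, p2)
      geosphere::distHaversine(p1, p2, r = 6371008.8))
  } else {
    n <- nrow(s); k <- nrow(trap_xy)
    d <- matrix(0, n, k)
    for (j in seq_len(k))
      d[, j] <- sqrt((s[, 1] - trap_xy[j, 1])^2 + (s[, 2] - trap_xy[j, 2])^2)
    d
  }
}

#' Augment a landscape's movement matrix with absorbing traps
#'
#' Builds the absorbing Markov chain over sites and traps. For each site i
#' and trap k the raw attractiveness weight \eqn{\nu_{ik}} is the trap
#' kernel evaluated at their distance (times the kernel's per-source-type
#' multiplier, if any). Trap weights are odds relative to the unit mass of
#' the movement row: site row i of the full matrix is
#' \deqn{[\tau_i, \nu_i] / (1 + \sum_k \nu_{ik}),}
#' so a trap of weight 0.5 co-located with a site captures with daily
#' probability 0.5/1.5 = 1/3. Multiple traps share the denominator and
#' therefore compete for the same mosquitoes. Trap rows are absorbing
#' (identity pattern).
#'
#' @param ls a [landscape()].
#' @param traps list of [trap()] objects.
#' @return object of class `trap_chain` with elements `Q` (renormalized
#'   site-to-site block), `R` (site-to-trap block), `P` (full transition
#'   matrix `[[Q, R], [0, I]]`), `trap_xy`, `traps` and `landscape`.
#' @examples
#' ls <- landscape(data.frame(x = 0, y = 0), dispersal_kernel("exponential"))
#' ch <- augment_chain(ls, list(trap(trap_kernel("exponential", A = 0.5), node = 0)))
#' ch$P
#' @export
augment_chain <- function(ls, traps) {
  stopifnot(inherits(ls, "landscape"))
  if (!is.list(traps) || length(traps) < 1L) stop("at least one trap is required")
  if (inherits(traps, "trap")) traps <- list(traps)
  xy <- resolve_trap_coordinates(traps, ls$sites)
  d <- site_trap_distances(ls, xy)
  n <- nrow(ls$tau); k <- length(traps)
  nu <- matrix(0, n, k)
  types <- site_types(ls$sites)
  for (j in seq_len(k)) {
    w <- trap_attractiveness(d[, j], traps[[j]]$kernel)
    tw <- traps[[j]]$kernel$type_weights
    if (!is.null(tw)) {
      if (max(types) + 1L > length(tw)) stop("type_weights shorter than number of resource types")
      w <- w * tw[types + 1L]
    }
    nu[, j] <- w
  }
  denom <- 1 + rowSums(nu)
  Q <- ls$tau / denom
  R <- nu / denom
  P <- rbind(cbind(Q, R),
             cbind(matrix(0, k, n), diag(1, k)))
  structure(list(Q = Q, R = R, P = P, trap_xy = xy, traps = traps,
                 landscape = ls),
            class = "trap_chain")
}

#' @export
print.trap_chain <- function(x, ...) {
  n <- nrow(x$Q); k <- ncol(x$R)
  cat(sprintf("Absorbing trap chain: %d transient site%s, %d absorbing trap%s\n",
              n, if (n == 1) "" else "s", k, if (k == 1) "" else "s"))
  cat(sprintf("  daily capture probability per site: min %.4g, max %.4g\n",
              min(rowSums(x$R)), max(rowSums(x$R))))
  invisible(x)
}
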