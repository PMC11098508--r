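#' Dispersal kernel constructor
#'
#' A dispersal kernel maps the distance between two sites to a non-negative
#' relative movement weight. Three built-in families cover the common
#' short-range mosquito flight behaviours:
#'
#' * `"exponential"`: \eqn{w(d) = \exp(-d/m)}, mean dispersal distance `m`.
#' * `"zero_inflated_exponential"`: an explicit staying probability `z` at the
#'   current site; conditional on moving, destinations receive weight
#'   \eqn{\propto \exp(-d/m)}. Typical of *Aedes*, which dwell locally and
#'   make short flights.
#' * `"long_tailed"`: a Lomax (shifted power-law) form
#'   \eqn{w(d) = (1 + d/(m(b-1)))^{-b}} with shape `b > 1` and mean `m`,
#'   heavier-tailed than the exponential and converging to it as
#'   `b` grows. Suits longer-ranging dispersers such as *Anopheles*.
#' * `"custom"`: any non-negative vectorized function of distance supplied
#'   via `fun`.
#'
#' @param family one of `"exponential"`, `"zero_inflated_exponential"`,
#'   `"long_tailed"`, `"custom"`.
#' @param m mean dispersal distance (coordinate units; metres under haversine
#'   distances). Must be positive. For the zero-inflated family this is the
#'   mean conditional upon movement.
#' @param z staying probability in `[0, 1]`; zero-inflated family only.
#' @param b tail shape, `> 1`; long-tailed family only.
#' @param fun custom weight function of a distance vector; custom family only.
#' @return an object of class `dispersal_kernel`.
#' @examples
#' dispersal_kernel("zero_inflated_exponential", m = 54, z = 0.72)
#' @export
dispersal_kernel <- function(family = c("exponential", "zero_inflated_exponential",
                                        "long_tailed", "custom"),
                             m = 1, z = NULL, b = NULL, fun = NULL) {
  family <- match.arg(family)
  if (family != "custom" && (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0))
    stop("mean dispersal distance 'm' must be a positive finite number")
  if (family == "zero_inflated_exponential") {
    if (is.null(z) || !is.numeric(z) || length(z) != 1L || !is.finite(z) || z < 0 || z > 1)
      stop("staying probability 'z' must lie in [0, 1]")
  }
  if (family == "long_tailed") {
    if (is.null(b) || !is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 1)
      stop("tail shape 'b' must be > 1 for the long-tailed (Lomax) kernel")
  }
  if (family == "custom" && !is.function(fun))
    stop("custom kernels require 'fun'")
  structure(list(family = family, m = m, z = z, b = b, fun = fun),
            class = "dispersal_kernel")
}

#' Evaluate a dispersal kernel's raw weight at given distances
#'
#' For the zero-inflated family this returns the conditional-on-movement
#' weight \eqn{\exp(-d/m)}; the point mass at the current site is handled by
#' [build_movement_matrix()].
#'
#' @param kernel a [dispersal_kernel()].
#' @param d vector of non-negative distances.
#' @return non-negative weights, same length as `d`.
#' @export
kernel_eval <- function(kernel, d) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and non-negative")
  switch(kernel$family,
    exponential = exp(-d / kernel$m),
    zero_inflated_exponential = exp(-d / kernel$m),
    long_tailed = (1 + d / (kernel$m * (kernel$b - 1)))^(-kernel$b),
    custom = {
      w <- kernel$fun(d)
      if (any(!is.finite(w)) || any(w < 0)) stop("custom kernel returned invalid weights")
      w
    })
}

#' Pairwise distance matrix between sites
#'
#' @param sites data frame with numeric columns `x` and `y`. Under
#'   `mode = "haversine"` these are interpreted as longitude and latitude in
#'   decimal degrees and distances are great-circle metres on a sphere of
#'   radius 6,371,008.8 m; under `"euclidean"` they are planar coordinates
#'   and distances are in the same units.
#' @param mode `"euclidean"` or `"haversine"`.
#' @return symmetric matrix with zero diagonal.
#' @examples
#' distance_matrix(data.frame(x = c(0, 3), y = c(0, 4)))
#' @export
distance_matrix <- function(sites, mode = c("euclidean", "haversine")) {
  mode <- match.arg(mode)
  xy <- as.matrix(sites[, c("x", "y")])
  storage.mode(xy) <- "double"
  if (nrow(xy) < 1L) stop("at least one site is required")
  if (any(!is.finite(xy))) stop("site coordinates must be finite")
  if (mode == "euclidean") {
    d <- as.matrix(stats::dist(xy))
  } else {
    if (any(abs(xy[, 2]) > 90)) stop("haversine mode requires latitudes in [-90, 90]")
    if (any(abs(xy[, 1]) > 360)) stop("haversine mode requires longitudes in degrees")
    d <- geosphere::distm(xy, fun = function(p1, p2)
      geosphere::distHaversine(p1, p2, r = 6371008.8))
  }
  dimnames(d) <- NULL
  diag(d) <- 0
  d
}

#' Apply a dispersal kernel to a distance matrix
#'
#' Entry-wise kernel weights. The diagonal is `kernel(0)` for the exponential,
#' long-tailed and custom families (the whole row is later normalized
#' together); for the zero-inflated family the diagonal is set to 0 here —
#' the staying mass `z` is imposed exactly during row normalization.
#'
#' @param dist square distance matrix from [distance_matrix()].
#' @param kernel a [dispersal_kernel()].
#' @return non-negative weight matrix of the same dimension.
#' @export
kernel_weights <- function(dist, kernel) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  w <- matrix(kernel_eval(kernel, as.vector(dist)), nrow(dist), ncol(dist))
  if (kernel$family == "zero_inflated_exponential") diag(w) <- 0
  w
}

#' Apply a resource-type masking matrix to movement weights
#'
#' The mask modulates movement by the mosquito's current need: entry
#' `mask[s, t]` multiplies the weight of moving from a site of resource type
#' `s` to a site of type `t` (e.g. a recently blood-fed female down-weights
#' further blood-feeding sites and seeks water for egg-laying). Types are
#' 0-based integers indexing mask rows/columns in order. No normalization is
#' performed here.
#'
#' @param weights square weight matrix.
#' @param types integer vector of 0-based resource types, one per site.
#' @param mask square non-negative matrix, one row/column per resource type.
#' @return masked weight matrix.
#' @export
apply_mask <- function(weights, types, mask) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  mask <- as.matrix(mask)
  if (any(!is.finite(mask)) || any(mask < 0)) stop("mask entries must be finite and non-negative")
  if (any(rowSums(mask) <= 0)) stop("every mask row needs at least one positive entry")
  types <- as.integer(types)
  if (length(types) != nrow(weights)) stop("one resource type per site is required")
  if (any(types < 0) || any(types + 1L > nrow(mask)) || any(types + 1L > ncol(mask)))
    stop("resource type absent from mask")
  weights * mask[types + 1L, types + 1L, drop = FALSE]
}

#' Build the row-stochastic site-to-site movement matrix
#'
#' Converts kernel weights (optionally masked by resource type) into the
#' daily per-capita movement matrix \eqn{\tau}: each entry is the probability
#' that a mosquito at site i is at site j one day later, and every row sums
#' to one. For the zero-inflated family the diagonal equals the staying
#' probability `z` exactly and the off-diagonal mass `1 - z` is distributed
#' proportionally to the masked kernel weights; a site with no reachable
#' destination keeps all its mass (self-probability 1).
#'
#' @param sites data frame with columns `x`, `y` and optionally `t`
#'   (0-based integer resource type; defaults to a single universal type).
#' @param kernel a [dispersal_kernel()].
#' @param mask optional square masking matrix (see [apply_mask()]).
#' @param distance_mode `"euclidean"` or `"haversine"`.
#' @param dist optional precomputed distance matrix.
#' @return row-stochastic square matrix.
#' @export
build_movement_matrix <- function(sites, kernel, mask = NULL,
                                  distance_mode = c("euclidean", "haversine"),
                                  dist = NULL) {
  distance_mode <- match.arg(distance_mode)
  if (is.null(dist)) dist <- distance_matrix(sites, distance_mode)
  n <- nrow(dist)
  types <- site_types(sites, n)
  w <- kernel_weights(dist, kernel)
  if (!is.null(mask)) w <- apply_mask(w, types, mask)
  tau <- matrix(0, n, n)
  if (kernel$family == "zero_inflated_exponential") {
    z <- kernel$z
    off <- rowSums(w)
    for (i in seq_len(n)) {
      if (off[i] <= 0) {          # isolated site: nowhere to go
        tau[i, i] <- 1
      } else {
        tau[i, ] <- (1 - z) * w[i, ] / off[i]
        tau[i, i] <- z
      }
    }
  } else {
    rs <- rowSums(w)
    if (any(rs <= 0)) stop("degenerate landscape: a site has an all-zero movement row")
    tau <- w / rs
  }
  tau
}

# Resource types of a site table, defaulting to one universal type.
site_types <- function(sites, n = nrow(sites)) {
  if (!is.null(sites$t)) as.integer(sites$t) else integer(n)
}

#' Landscape: sites, dispersal kernel and derived movement matrix
#'
#' The central container for the movement model. A landscape is a
#' metapopulation of discrete mosquito population nodes; movement between
#' them is Markovian with daily transition probabilities \eqn{\tau} derived
#' from a dispersal kernel of inter-site distance and, optionally, a
#' resource-type masking matrix.
#'
#' @param sites data frame with numeric `x`, `y` and optional 0-based integer
#'   resource type `t`.
#' @param kernel a [dispersal_kernel()].
#' @param mask optional masking matrix.
#' @param distance_mode `"euclidean"` (planar, default) or `"haversine"`
#'   (lon/lat degrees, distances in metres).
#' @return object of class `landscape` with elements `sites`, `kernel`,
#'   `mask`, `distance_mode`, `dist` (distance matrix) and `tau`
#'   (row-stochastic movement matrix).
#' @examples
#' ls <- landscape(make_landscape("grid", n_sites = 9),
#'                 dispersal_kernel("exponential", m = 1))
#' rowSums(ls$tau)
#' @export
landscape <- function(sites, kernel, mask = NULL,
                      distance_mode = c("euclidean", "haversine")) {
  distance_mode <- match.arg(distance_mode)
  sites <- as.data.frame(sites)
  if (!all(c("x", "y") %in% names(sites))) stop("sites need 'x' and 'y' columns")
  if (nrow(sites) < 1L) stop("at least one site is required")
  d <- distance_matrix(sites, distance_mode)
  tau <- build_movement_matrix(sites, kernel, mask, distance_mode, dist = d)
  structure(list(sites = sites, kernel = kernel, mask = mask,
                 distance_mode = distance_mode, dist = d, tau = tau),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  n <- nrow(x$sites)
  cat(sprintf("Landscape: %d site%s, %s kernel, %s distances\n",
              n, if (n == 1) "" else "s", x$kernel$family, x$distance_mode))
  nt <- length(unique(site_types(x$sites)))
  if (nt > 1) cat(sprintf("  %d resource types%s\n", nt,
                          if (is.null(x$mask)) "" else " with masking matrix"))
  cat(sprintf("  movement matrix: %d x %d, min row sum %.12f\n",
              n, n, min(rowSums(x$tau))))
  invisible(x)
}

#' @export
summary.landscape <- function(object, ...) {
  tau <- object$tau
  out <- list(n_sites = nrow(object$sites),
              kernel = object$kernel$family,
              distance_mode = object$distance_mode,
              staying = diag(tau),
              mean_offdiag_distance = mean(object$dist[upper.tri(object$dist)]))
  class(out) <- "summary.landscape"
  out
}

#' @export
print.summary.landscape <- function(x, ...) {
  cat(sprintf("Landscape of %d sites (%s kernel, %s distances)\n",
              x$n_sites, x$kernel, x$distance_mode))
  cat(sprintf("  mean inter-site distance: %.4g\n", x$mean_offdiag_distance))
  cat("  staying probabilities (diag of tau):\n")
  print(summary(x$staying))
  invisible(x)
}

#' Plot a landscape and, optionally, traps
#'
#' Sites are drawn at their coordinates (plotting symbol by resource type);
#' traps, if given, as crosses with a dashed circle at the kernel's
#' characteristic radius (immovable traps filled).
#'
#' @param x a `landscape`.
#' @param traps optional list of [trap()] objects.
#' @param ... passed to [graphics::plot()].
#' @export
plot.landscape <- function(x, traps = NULL, ...) {
  s <- x$sites
  types <- site_types(s)
  graphics::plot(s$x, s$y, pch = c(17, 19, 15, 18)[(types %% 4) + 1],
                 col = "grey30", xlab = "x", ylab = "y", asp = 1, ...)
  if (!is.null(traps)) {
    xy <- resolve_trap_coordinates(traps, s)
    imm <- vapply(traps, function(tr) isTRUE(tr$immovable), logical(1))
    graphics::points(xy[, 1], xy[, 2], pch = ifelse(imm, 10, 4),
                     col = "firebrick", cex = 1.6, lwd = 2)
    theta <- seq(0, 2 * pi, length.out = 64)
    for (k in seq_along(traps)) {
      r <- traps[[k]]$kernel$radius
      graphics::lines(xy[k, 1] + r * cos(theta), xy[k, 2] + r * sin(theta),
                      col = "firebrick", lty = 2)
    }
  }
  invisible(x)
}
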