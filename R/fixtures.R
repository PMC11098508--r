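#' Generate a synthetic site table
#'
#' Deterministic (given `seed`) generators for the landscape layouts used
#' throughout the package's tests and examples:
#'
#' * `"grid"`: a near-square unit-spaced lattice of `n_sites` points.
#' * `"uniform_random"`: uniform points in the extent.
#' * `"clustered"`: `cluster_count` Gaussian clusters of spread `spread`,
#'   cluster centres uniform in the extent; resource types cycle through
#'   clusters when `n_types > 1`.
#' * `"two_clusters"`: two well-separated Gaussian clusters.
#' * `"hexad"`: a fixed six-node demonstration metapopulation on a
#'   hexagon, with alternating resource types (three blood-feeding, three
#'   water/egg-laying sites).
#'
#' @param layout one of `"grid"`, `"uniform_random"`, `"clustered"`,
#'   `"two_clusters"`, `"hexad"`.
#' @param n_sites number of sites (ignored for `"hexad"`, which always
#'   has 6).
#' @param n_types number of resource types, assigned cyclically.
#' @param extent bounding box `c(xmin, xmax, ymin, ymax)`.
#' @param cluster_count,spread clustered layouts only.
#' @param seed RNG seed for the stochastic layouts.
#' @return data frame with columns `x`, `y`, `t` (0-based resource type).
#' @examples
#' make_landscape("hexad")
#' @export
make_landscape <- function(layout = c("grid", "uniform_random", "clustered",
                                      "two_clusters", "hexad"),
                           n_sites = 9, n_types = 1,
                           extent = c(0, 10, 0, 10),
                           cluster_count = 3, spread = 0.5, seed = 1) {
  layout <- match.arg(layout)
  if (layout != "hexad" && n_sites < 1) stop("n_sites must be >= 1")
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be a nondegenerate bounding box")
  sites <- switch(layout,
    grid = {
      nx <- ceiling(sqrt(n_sites))
      g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ceiling(n_sites / nx)) - 1)
      data.frame(x = g$x[seq_len(n_sites)], y = g$y[seq_len(n_sites)])
    },
    uniform_random = {
      set.seed(seed)
      data.frame(x = stats::runif(n_sites, extent[1], extent[2]),
                 y = stats::runif(n_sites, extent[3], extent[4]))
    },
    clustered = {
      set.seed(seed)
      cx <- stats::runif(cluster_count, extent[1], extent[2])
      cy <- stats::runif(cluster_count, extent[3], extent[4])
      k <- rep(seq_len(cluster_count), length.out = n_sites)
      data.frame(x = stats::rnorm(n_sites, cx[k], spread),
                 y = stats::rnorm(n_sites, cy[k], spread))
    },
    two_clusters = {
      set.seed(seed)
      w <- diff(extent[1:2])
      cx <- c(extent[1] + 0.2 * w, extent[1] + 0.8 * w)
      cy <- rep(mean(extent[3:4]), 2)
      k <- rep(1:2, length.out = n_sites)
      data.frame(x = stats::rnorm(n_sites, cx[k], spread),
                 y = stats::rnorm(n_sites, cy[k], spread))
    },
    hexad = {
      theta <- (seq_len(6) - 1) * pi / 3
      data.frame(x = round(1.5 * cos(theta), 6), y = round(1.5 * sin(theta), 6))
    })
  n <- nrow(sites)
  sites$t <- if (layout == "hexad") rep(c(0L, 1L), 3L)
             else (seq_len(n) - 1L) %% max(1L, as.integer(n_types))
  rownames(sites) <- NULL
  sites
}

#' Scaled-down study scenarios
#'
#' Bundled parameterizations of the two kinds of surveillance problems the
#' package targets, at sizes where exhaustive and Monte-Carlo cross-checks
#' remain fast:
#'
#' * `"suburb_small"`: 60 household-like sites uniform in a 1 km x 1 km box,
#'   a local-dispersing species (zero-inflated exponential kernel, daily
#'   staying probability 0.72, mean dispersal distance conditional upon
#'   movement 54 m), and two trap types — an exponential attractiveness
#'   kernel (A = 0.5, mean radius 15.88 m) and a sigmoidal one (A = 0.5,
#'   inflection radius 16 m, shape 0.25). Default 8 traps, half of each
#'   type.
#' * `"island_small"`: 30 village-like sites in 5 clusters on an elongated
#'   2 km x 4 km island-shaped extent, an exponential movement kernel
#'   (m = 300 m), a single trap type (exponential, A = 0.5, mean radius
#'   24 m), and two immovable traps pre-placed at the northernmost and
#'   southernmost sites.
#'
#' @param name `"suburb_small"` or `"island_small"`.
#' @param seed RNG seed for site generation.
#' @return list with elements `landscape` (a [landscape()]),
#'   `trap_kernels` (list, one per movable trap in the default design),
#'   `fixed_traps` (list of immovable [trap()]s, possibly empty), and
#'   `name`.
#' @export
make_scenario <- function(name = c("suburb_small", "island_small"), seed = 1) {
  name <- match.arg(name)
  if (name == "suburb_small") {
    sites <- make_landscape("uniform_random", n_sites = 60,
                            extent = c(0, 1000, 0, 1000), seed = seed)
    ls <- landscape(sites,
                    dispersal_kernel("zero_inflated_exponential", m = 54, z = 0.72))
    kexp <- trap_kernel("exponential", A = 0.5, radius = 15.88)
    ksig <- trap_kernel("sigmoidal", A = 0.5, radius = 16, shape = 0.25)
    list(name = name, landscape = ls,
         trap_kernels = c(rep(list(kexp), 4), rep(list(ksig), 4)),
         fixed_traps = list())
  } else {
    sites <- make_landscape("clustered", n_sites = 30,
                            extent = c(0, 2000, 0, 4000),
                            cluster_count = 5, spread = 100, seed = seed)
    ls <- landscape(sites, dispersal_kernel("exponential", m = 300))
    ktrap <- trap_kernel("exponential", A = 0.5, radius = 24)
    north <- which.max(sites$y) - 1L
    south <- which.min(sites$y) - 1L
    list(name = name, landscape = ls,
         trap_kernels = list(ktrap),
         fixed_traps = list(trap(ktrap, node = north, immovable = TRUE),
                            trap(ktrap, node = south, immovable = TRUE)))
  }
}
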