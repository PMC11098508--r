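# Seeded random instances used across tests. Landscapes live in the unit
# box with dispersal and trap ranges sized so absorption is fast enough for
# Monte-Carlo cross-checks.

random_sites <- function(seed, n_sites = NULL, n_types = 1) {
  set.seed(seed)
  if (is.null(n_sites)) n_sites <- sample(3:12, 1)
  data.frame(x = runif(n_sites), y = runif(n_sites),
             t = (seq_len(n_sites) - 1L) %% n_types)
}

random_landscape <- function(seed, n_sites = NULL, kernel = NULL, ...) {
  sites <- random_sites(seed, n_sites, ...)
  if (is.null(kernel)) {
    set.seed(seed + 1000L)
    kernel <- switch(sample(3, 1),
      dispersal_kernel("exponential", m = runif(1, 0.2, 0.6)),
      dispersal_kernel("zero_inflated_exponential", m = runif(1, 0.2, 0.6),
                       z = runif(1, 0.2, 0.8)),
      dispersal_kernel("long_tailed", m = runif(1, 0.2, 0.6),
                       b = runif(1, 1.5, 5)))
  }
  landscape(sites, kernel)
}

random_traps <- function(ls, seed, n_traps = NULL) {
  set.seed(seed)
  n <- nrow(ls$sites)
  if (is.null(n_traps)) n_traps <- sample(1:3, 1)
  lapply(seq_len(n_traps), function(i)
    trap(trap_kernel("exponential", A = runif(1, 0.3, 0.9),
                     radius = runif(1, 0.3, 0.8)),
         node = sample(n, 1) - 1L))
}

# One-transient-state chain with a given daily capture probability.
single_site_chain <- function(p) {
  structure(list(Q = matrix(1 - p, 1, 1), R = matrix(p, 1, 1),
                 P = rbind(c(1 - p, p), c(0, 1))),
            class = "trap_chain")
}

cli_path <- function() system.file("cli", "trapscape.R", package = "trapscape")

run_cli <- function(...) {
  out <- suppressWarnings(
    system2(file.path(R.home("bin"), "Rscript"), c(cli_path(), ...),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
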