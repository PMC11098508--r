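test_that("placement evaluation composes the augment-solve-reduce pipeline", {
  ls1 <- landscape(data.frame(x = 0, y = 0), dispersal_kernel("exponential"))
  k05 <- trap_kernel("exponential", A = 0.5)
  expect_equal(evaluate_placement(0L, ls1, list(), list(k05), "mean", "discrete"), 3)

  ls <- random_landscape(51, n_sites = 5)
  ks <- list(trap_kernel("exponential", A = 0.6, radius = 0.4),
             trap_kernel("sigmoidal", A = 0.4, radius = 0.3, shape = 4))
  genes <- c(1L, 3L)
  manual <- fitness_mean(expected_absorption_time(augment_chain(ls,
    list(trap(ks[[1]], node = 1), trap(ks[[2]], node = 3)))))
  expect_equal(evaluate_placement(genes, ls, list(), ks, "mean", "discrete"), manual)

  # duplicate genes: two traps on one node is a valid competing configuration
  dup <- evaluate_placement(c(2L, 2L), ls, list(), ks, "mean", "discrete")
  expect_true(is.finite(dup) && dup > 0)
})

test_that("discrete mutation resamples genes at the configured rate", {
  set.seed(1)
  g <- c(0L, 1L, 2L, 3L)
  expect_identical(mutate_discrete(g, 0, 10), g)
  expect_identical(mutate_discrete(c(5L, 7L), 1, 1), c(0L, 0L))
  set.seed(2)
  hits <- replicate(10000, sum(mutate_discrete(rep(1L, 4), 0.3, 1000) != 1L))
  # resampling may redraw the same site; correct for the 1/1000 collision rate
  rate <- mean(hits) / 4 / (1 - 1 / 1000)
  expect_equal(rate, 0.3, tolerance = 0.05)
})

test_that("continuous mutation is bounded with half-normal displacements", {
  g <- cbind(runif(5), runif(5))
  expect_identical(mutate_continuous(g, 0.5, 0, c(0, 1, 0, 1)), g)
  set.seed(3)
  sigma <- 0.1
  disp <- replicate(10000, {
    out <- mutate_continuous(cbind(0.5, 0.5), 1, sigma, c(-10, 10, -10, 10))
    abs(out[1, 1] - 0.5)
  })
  expect_equal(mean(disp), sigma * sqrt(2 / pi), tolerance = 0.05)
  set.seed(4)
  for (i in 1:200) {
    out <- mutate_continuous(cbind(runif(3), runif(3)), 1, 5, c(0, 1, 0, 1))
    expect_true(all(out[, 1] >= 0 & out[, 1] <= 1))
    expect_true(all(out[, 2] >= 0 & out[, 2] <= 1))
  }
})

test_that("two-point crossover conserves the parental gene multiset", {
  set.seed(5)
  a <- sample(0:9); b <- sample(0:9)
  ch <- crossover_twopoint(a, b)
  expect_equal(length(ch[[1]]), 10)
  expect_equal(sort(c(ch[[1]], ch[[2]])), sort(c(a, b)))
  expect_identical(crossover_twopoint(a, a), list(a, a))
  expect_identical(crossover_twopoint(3L, 8L), list(3L, 8L))  # single gene
  # coordinate pairs are exchanged whole
  ma <- cbind(1:4, 101:104); mb <- cbind(11:14, 111:114)
  cm <- crossover_twopoint(ma, mb)
  both <- rbind(cm[[1]], cm[[2]])
  expect_true(all(both[, 2] - both[, 1] == 100))
})

test_that("tournament selection minimizes with the documented pressure", {
  fit <- c(5, 1, 3, 9)
  set.seed(6)
  expect_true(all(select_tournament(fit, 20, 4) == 2L))
  set.seed(7)
  sel1 <- select_tournament(fit, 20000, 1)
  expect_equal(as.numeric(table(sel1)) / 20000, rep(0.25, 4), tolerance = 0.05)
  set.seed(8)
  sel3 <- select_tournament(fit, 20000, 3)
  expect_gt(mean(sel3 == 2L), 1.5 / 4)  # best picked far above uniform rate
})

test_that("the GA finds the exhaustive optimum on a small fixture", {
  ls <- landscape(make_landscape("hexad"),
                  dispersal_kernel("zero_inflated_exponential", m = 1, z = 0.75))
  k <- trap_kernel("exponential", A = 0.5, radius = 1)
  bf <- brute_force_traps(ls, k, n_traps = 1)
  fit <- optimize_traps(ls, k, n_traps = 1,
                        control = ga_control(pop_size = 32, generations = 200,
                                             seed = 9))
  expect_equal(fit$best_fitness, bf$best_fitness, tolerance = 1e-12)
})

test_that("two traps split across two symmetric clusters", {
  ls <- landscape(make_landscape("two_clusters", n_sites = 10,
                                 extent = c(0, 10, 0, 10), spread = 0.3,
                                 seed = 12),
                  dispersal_kernel("exponential", m = 1.5))
  k <- trap_kernel("exponential", A = 0.5, radius = 1.5)
  fit <- optimize_traps(ls, k, n_traps = 2,
                        control = ga_control(pop_size = 64, generations = 200,
                                             seed = 10))
  left <- ls$sites$x < 5
  placed_left <- left[coef(fit) + 1L]
  expect_equal(sort(placed_left), c(FALSE, TRUE))  # one trap per cluster
  # and strictly better than the best both-in-one-cluster configuration
  one_cluster <- evaluate_placement(c(which(left)[1] - 1L, which(left)[2] - 1L),
                                    ls, list(), rep(list(k), 2), "mean", "discrete")
  expect_lt(fit$best_fitness, one_cluster)
})

test_that("identical seeds give bit-identical runs and elitist traces", {
  ls <- random_landscape(61, n_sites = 7)
  k <- trap_kernel("exponential", A = 0.5, radius = 0.5)
  ctrl <- ga_control(pop_size = 24, generations = 60, seed = 11, repetitions = 2)
  f1 <- optimize_traps(ls, k, n_traps = 2, control = ctrl)
  f2 <- optimize_traps(ls, k, n_traps = 2, control = ctrl)
  expect_identical(f1$trace, f2$trace)
  expect_identical(coef(f1), coef(f2))
  for (r in 1:2) {
    tr <- f1$trace$best[f1$trace$repetition == r]
    expect_true(all(diff(tr) <= 0))
  }
  f3 <- optimize_traps(ls, k, n_traps = 2,
                       control = ga_control(pop_size = 24, generations = 60,
                                            seed = 99))
  expect_false(identical(f1$trace$mean, f3$trace$mean))
})

test_that("immovable traps keep their positions through optimization", {
  ls <- random_landscape(71, n_sites = 8)
  k <- trap_kernel("exponential", A = 0.5, radius = 0.5)
  fixed <- list(trap(k, node = 0, immovable = TRUE),
                trap(k, x = 0.5, y = 0.5, immovable = TRUE))
  fit <- optimize_traps(ls, k, fixed_traps = fixed, n_traps = 1,
                        control = ga_control(pop_size = 16, generations = 30,
                                             seed = 12))
  expect_identical(fit$best_traps[[1]]$node, 0L)
  expect_identical(c(fit$best_traps[[2]]$x, fit$best_traps[[2]]$y), c(0.5, 0.5))
  expect_true(fit$best_traps[[1]]$immovable)
})

test_that("brute force enumerates multisets and refuses oversized problems", {
  ls1 <- landscape(data.frame(x = 0, y = 0), dispersal_kernel("exponential"))
  k <- trap_kernel("exponential", A = 0.5)
  bf1 <- brute_force_traps(ls1, k, n_traps = 1)
  expect_identical(bf1$best_genes, 0L)
  expect_equal(bf1$best_fitness, 3)

  ls <- random_landscape(81, n_sites = 6)
  bf <- brute_force_traps(ls, k, n_traps = 1)
  expect_equal(bf$n_evaluated, 6)
  all_f <- vapply(0:5, function(g)
    evaluate_placement(g, ls, list(), list(k), "mean", "discrete"), numeric(1))
  expect_equal(bf$best_fitness, min(all_f))
  expect_equal(bf$best_genes, which.min(all_f) - 1L)

  bf2 <- brute_force_traps(ls, k, n_traps = 2)
  expect_equal(bf2$n_evaluated, choose(6 + 1, 2))
  expect_error(brute_force_traps(ls, k, n_traps = 2, cap = 10), "cap")
})

test_that("a trap-count sweep has non-increasing optimized fitness", {
  ls <- random_landscape(91, n_sites = 10)
  k <- trap_kernel("exponential", A = 0.5, radius = 0.3)
  sw <- sweep_trap_count(ls, k, counts = c(1, 2, 3),
                         control = ga_control(pop_size = 24, generations = 40,
                                              seed = 13))
  expect_true(all(diff(sw$fitness_days) <= 1e-9))
})

test_that("optimization results expose modelling-style methods", {
  ls <- random_landscape(95, n_sites = 6)
  k <- trap_kernel("exponential", A = 0.5, radius = 0.5)
  fit <- optimize_traps(ls, k, n_traps = 1,
                        control = ga_control(pop_size = 16, generations = 20,
                                             seed = 14))
  expect_output(print(fit), "best expected trapping time")
  s <- summary(fit)
  expect_output(print(s), "days")
  expect_equal(length(fitted(fit)), 6)
  expect_equal(min(fitted(fit)) <= fit$best_fitness, TRUE)
  sim <- simulate(fit, nsim = 200, seed = 15)
  expect_equal(nrow(sim), 6)
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit, which = "trace"); plot(fit, which = "map")
  grDevices::dev.off(); unlink(tf)
})
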