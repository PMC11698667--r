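# The exact mixed-integer route and its certification oracles.

test_that("build_exact_model lays out variables and refuses oversize input", {
  model <- build_exact_model(trivial_partition(c(1, 2, 3)))
  expect_equal(model$n, 3)
  expect_equal(length(model$idx$z), 3)
  expect_equal(length(model$idx$y[[1]]), 3)
  expect_equal(dim(model$idx$X[[1]]), c(3, 3))
  expect_equal(sum(model$integrality), 9)
  # a singleton segment needs no binaries
  part <- lpdp_prepare(c(1, 2, 3), c(1, 2))
  m2 <- build_exact_model(part)
  expect_null(m2$idx$X[[2]])
  expect_error(build_exact_model(trivial_partition(sort(apply_Q(1:16))), n_limit = 15),
               "exceeds")
})

test_that("separation_cut certifies or cuts as the objective dictates", {
  obj <- exact_objective("rel_linf")
  segs <- list(c(1, 2, 3))
  cut <- separation_cut(obj, list(c(0.2, 0, 0)), t_value = 0.1, segments = segs)
  expect_equal(cut$kind, "ratio")
  expect_equal(cut$segment, 1L)
  expect_equal(cut$rank, 1L)
  expect_equal(cut$value, 0.2, tolerance = 1e-12)
  expect_null(separation_cut(obj, list(c(0, 0, 0)), t_value = 0, segments = segs))
  # worst additivity triple on assigned distances (1, 2, 3.5)
  dmat <- matrix(NA_real_, 3, 3)
  dmat[1, 2] <- 1; dmat[2, 3] <- 2; dmat[1, 3] <- 3.5
  tri <- separation_cut(exact_objective("part_linf"), list(numeric(3)),
                        t_value = 0.1, assigned = dmat)
  expect_equal(tri$kind, "triple")
  expect_equal(tri$value, 0.5, tolerance = 1e-12)
  expect_equal(tri$triple, c(1, 2, 3))
  mm <- separation_cut(exact_objective("mm_support"), list(c(0.3, 0.4, 0)),
                       t_value = 0)
  expect_equal(mm$kind, "support")
  expect_equal(unlist(mm$x), c(0.3, 0.4, 0) / 0.5, tolerance = 1e-12)
})

test_that("noiseless instances are certified at objective zero", {
  ex <- solve_exact(trivial_partition(c(1, 2, 3)))
  expect_true(ex$optimal)
  expect_equal(ex$objective, 0, tolerance = 1e-8)
  want <- c(-4, -1, 5) / sqrt(42) # either mirror is a valid reconstruction
  expect_equal(canonicalize(ex$z / sqrt(sum(ex$z^2)), want), want, tolerance = 1e-6)
  for (kind in c("mm_support", "rel_linf")) {
    z <- sample_points("uniform", 6, seed = 21)
    D <- sort(apply_Q(z))
    ex6 <- solve_exact(trivial_partition(D), exact_objective(kind))
    expect_true(ex6$optimal)
    expect_lt(ex6$objective, 1e-7)
  }
})

test_that("solve_exact agrees with enumeration on noisy instances", {
  set.seed(5)
  for (trial in 1:3) {
    z <- sort(rnorm(4)); z <- z - mean(z)
    D <- sort(pmax(apply_Q(z) + rnorm(6, 0, 0.04), 0))
    ex <- solve_exact(trivial_partition(D), exact_objective("mm_support"),
                      max_cuts = 10)
    bf <- brute_force_solve(D, 4)
    expect_equal(ex$objective, bf$objective, tolerance = 1e-6)
    rl_ex <- solve_exact(trivial_partition(D), exact_objective("rel_linf"))
    rl_bf <- brute_force_solve(D, 4, exact_objective("rel_linf"))
    expect_equal(rl_ex$objective, rl_bf$objective, tolerance = 1e-6)
    expect_true(rl_ex$optimal)
  }
})

test_that("the exact optimum dominates the alternating solvers", {
  set.seed(9)
  z <- sort(runif(5)); z <- z - mean(z)
  D <- sort(pmax(apply_Q(z) + rnorm(10, 0, 0.03), 0))
  ex <- solve_exact(trivial_partition(D), exact_objective("mm_support"),
                    max_cuts = 8)
  fit <- mmdq_solve(rescale_distances(D, 5), greedy_init(D))
  # score the alternating solution under the same pinned-scale residual norm
  lens <- apply_Q(fit$z)
  z_data <- fit$z * sum(D) / sum(lens)
  sigma_fit <- sqrt(sum((D - sort(apply_Q(z_data)))^2))
  expect_lte(ex$objective, sigma_fit + 1e-9)
})

test_that("brute_force_solve matches its closed-form geometry and refuses big n", {
  bf <- brute_force_solve(c(1, 2, 3), 3)
  expect_equal(bf$objective, 0, tolerance = 1e-10)
  expect_equal(sort(apply_Q(bf$z)), c(1, 2, 3), tolerance = 1e-9)
  # n = 2: single assignment, perfect fit
  bf2 <- brute_force_solve(4, 2)
  expect_equal(bf2$objective, 0, tolerance = 1e-12)
  expect_equal(diff(bf2$z), 4, tolerance = 1e-12)
  expect_error(brute_force_solve(sort(apply_Q(1:6)), 6), "n > 5")
  expect_error(brute_force_solve(sort(apply_Q(1:5)), 5, exact_objective("rel_linf")),
               "n > 4")
})

test_that("backtracking reconstructs noiseless multisets or reports failure", {
  bt <- backtracking_solve(c(1, 2, 3))
  expect_true(isTRUE(all.equal(bt, c(0, 1, 3))) || isTRUE(all.equal(bt, c(0, 2, 3))))
  bt2 <- backtracking_solve(sort(c(2, 1, 3)))
  expect_equal(sort(apply_Q(bt2)), c(1, 2, 3))
  expect_null(backtracking_solve(c(1, 1, 5)))
  for (seed in 1:5) {
    z <- sample_points("normal", 9, seed = seed + 800)
    D <- sort(apply_Q(z))
    bt3 <- backtracking_solve(D, tol = 1e-8)
    expect_false(is.null(bt3))
    expect_equal(sort(apply_Q(bt3)), D, tolerance = 1e-7)
  }
})
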