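# The alternating MM solver, divide-and-conquer refinement, and block solver.

test_that("mm_solve recovers the 3-point instance and honors fixed points", {
  D <- rescale_distances(c(1, 2, 3), 3)
  fit <- mm_solve(D, c(-1, 0, 1) / sqrt(2))
  expect_s3_class(fit, "turnpike_fit")
  expect_true(fit$converged)
  expect_lte(fit$iterations, 3)
  expect_equal(fit$z, c(-4, -1, 5) / sqrt(42), tolerance = 1e-9)
  expect_equal(sort(apply_Q(fit$z)), D, tolerance = 1e-9)
  # ground truth is a one-iteration fixed point on noiseless instances
  for (n in 4:8) {
    z <- sample_points("normal", n, seed = n)
    Dn <- sort(apply_Q(z))
    f <- mm_solve(Dn, z)
    expect_equal(f$iterations, 1L)
    expect_equal(f$z, z, tolerance = 1e-10)
  }
  # n = 2 collapses to the unit pair
  f2 <- mm_solve(0.7, c(-3, 5))
  expect_equal(f2$z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_error(mm_solve(c(1, 2, 3), c(1, 0, 2)), "sorted")
})

test_that("returned configurations satisfy the symmetry-breaking conventions", {
  for (seed in 1:5) {
    inst <- rand_instance(12, noise_sd = 0.05, seed = seed)
    fit <- mm_solve(inst$D, gaussian_init(12, seed))
    expect_silent(check_points(fit$z))
  }
})

test_that("the matching objective is nondecreasing across iterations", {
  set.seed(21)
  for (trial in 1:50) {
    n <- sample(5:40, 1)
    inst <- rand_instance(n, noise_sd = 10^runif(1, -6, -1), seed = trial + 900)
    fit <- mm_solve(inst$D, gaussian_init(n, trial))
    expect_true(all(diff(fit$objective_trace) >= -1e-9))
    expect_lte(fit$iterations, solver_config()$max_iters)
  }
})

test_that("segment_distances routes by the matched endpoints", {
  z <- c(0, 1, 3, 7)
  D <- sort(apply_Q(z))
  m <- sorted_match_apply(D, z)$matching
  segs <- segment_distances(D, m, split = 2)
  expect_equal(segs$ll, 1)
  expect_equal(segs$rr, 4)
  expect_equal(segs$lr, c(2, 3, 6, 7))
  expect_equal(lengths(segs), c(ll = 1L, rr = 1L, lr = 4L))
  segs3 <- segment_distances(sort(apply_Q(c(0, 1, 3))),
                             sorted_match_apply(sort(apply_Q(c(0, 1, 3))), c(0, 1, 3))$matching,
                             split = 1)
  expect_equal(lengths(segs3), c(ll = 0L, rr = 1L, lr = 2L))
})

test_that("refit_subset closed form and conjugate gradient agree", {
  expect_equal(refit_subset(c(1, 2, 3), c(-1, 0, 1)), c(-4, -1, 5) / 3,
               tolerance = 1e-10)
  expect_equal(refit_subset(2, c(-1, 1)), c(-1, 1), tolerance = 1e-12)
  for (seed in 1:5) {
    z <- sort(rnorm(10))
    z <- z - mean(z)
    D <- sort(apply_Q(z))
    a <- refit_subset(D, z, method = "closed_form")
    b <- refit_subset(D, z, method = "cg")
    expect_equal(a, b, tolerance = 1e-8)
    expect_equal(a, z, tolerance = 1e-8) # noiseless refit reproduces truth
  }
})

test_that("mmdq never scores below plain MM from the same start", {
  set.seed(4)
  for (trial in 1:20) {
    z <- sample_points("uniform", 20, seed = trial + 60)
    D <- sort(apply_Q(z))
    z0 <- greedy_init(D, seed = trial, flip_prob = if (trial %% 2) 0.2 else 0)
    mm <- mm_solve(D, z0)
    dq <- mmdq_solve(D, z0)
    expect_gte(dq$objective, mm$objective - 1e-10)
  }
})

test_that("mmdq leaves an attained optimum unchanged", {
  D <- rescale_distances(c(1, 2, 3), 3)
  f_mm <- mm_solve(D, c(-1, 0, 1) / sqrt(2))
  f_dq <- mmdq_solve(D, c(-1, 0, 1) / sqrt(2))
  expect_equal(f_dq$z, f_mm$z, tolerance = 1e-10)
  z <- sample_points("normal", 16, seed = 3)
  Dn <- sort(apply_Q(z))
  f <- mmdq_solve(Dn, z)
  expect_equal(f$z, z, tolerance = 1e-8)
})

test_that("block_mm_solve with the trivial partition is bit-identical to mm_solve", {
  inst <- rand_instance(10, noise_sd = 0.01, seed = 17)
  z0 <- gaussian_init(10, 5)
  a <- mm_solve(inst$D, z0)
  b <- block_mm_solve(trivial_partition(inst$D), z0)
  expect_identical(a$z, b$z)
  expect_identical(a$iterations, b$iterations)
  expect_equal(a$objective, b$objective)
})

test_that("an all-missing partition converges immediately to its start", {
  n <- 6
  m <- n * (n - 1) / 2
  part <- distance_partition(n, list(numeric(0)), kind = "custom",
                             labels = rep(0L, m))
  z0 <- gaussian_init(n, 2)
  fit <- block_mm_solve(part, z0)
  expect_equal(fit$z, z0, tolerance = 1e-12)
  expect_equal(fit$iterations, 1L)
})

test_that("solver_config validates its inputs", {
  expect_error(solver_config(tol = 0), "tol")
  expect_error(solver_config(min_subset = 2), "min_subset")
  expect_s3_class(solver_config(), "solver_config")
})
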