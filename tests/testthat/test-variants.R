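# Beltway lift/solve and the two partial-digest labelings.

test_that("beltway slot accounting holds for the lifted instance", {
  for (n in c(2, 3, 5, 10, 40, 100)) {
    expect_equal(2 * n * (n - 1) + n, n * (2 * n - 1))
  }
  for (n in c(2, 3, 6)) {
    inst <- make_beltway_instance(n, seed = n)
    part <- beltway_lift(inst$arcs, n)
    counts <- turnpike:::partition_label_counts(part)
    expect_equal(sum(counts$observed), n * (n - 1) + n)
    expect_equal(counts$missing, 2 * choose(n, 2))
    expect_equal(sum(counts$observed) + counts$missing, n * (2 * n - 1))
  }
  expect_error(beltway_lift(rep(1, 5), 3), "n\\(n-1\\)")
})

test_that("the lifted ground truth is an exact fixed point of the sweep", {
  for (n in c(3, 5, 8)) {
    inst <- make_beltway_instance(n, seed = 2 * n)
    theta <- inst$angles - inst$angles[1]
    part <- beltway_lift(arcs_from_angles(theta), n)
    z <- c(theta - 2 * pi, theta)
    zr <- partitioned_match_apply(part, z)$z / (2 * n)
    expect_equal(zr, z - mean(z), tolerance = 1e-10)
  }
})

test_that("beltway_solve recovers known configurations", {
  arcs <- sort(rep(c(2 * pi / 3, 4 * pi / 3), each = 3))
  th <- beltway_solve(arcs, 3, solver_config(seed = 1))
  expect_equal(as.numeric(th), c(0, 2 * pi / 3, 4 * pi / 3), tolerance = 1e-8)
  expect_lt(mean(abs(arcs_from_angles(as.numeric(th)) - arcs)), 1e-8)
  th2 <- beltway_solve(c(pi, pi), 2, solver_config(seed = 1))
  expect_equal(as.numeric(th2), c(0, pi), tolerance = 1e-8)
})

test_that("beltway_solve round-trips random noiseless instances", {
  for (n in c(4, 6)) {
    inst <- make_beltway_instance(n, seed = 70 + n)
    th <- beltway_solve(inst$arcs, n, solver_config(seed = 2))
    expect_lt(mean(abs(arcs_from_angles(as.numeric(th)) - inst$arcs)), 1e-6)
  }
})

test_that("beltway_solve rescales non-unit circumferences", {
  inst <- make_beltway_instance(5, seed = 31)
  scaled <- sort(inst$arcs * 7.5)
  th <- beltway_solve(scaled, 5, solver_config(seed = 3))
  expect_equal(attr(th, "circumference"), 2 * pi * 7.5, tolerance = 1e-9)
  expect_lt(mean(abs(arcs_from_angles(as.numeric(th)) - inst$arcs)), 1e-6)
})

test_that("l1_monotone_subtract equals brute-force enumeration", {
  expect_equal(l1_monotone_subtract(c(1, 2, 3), c(1, 2)),
               list(indices = c(1L, 2L), cost = 0))
  expect_equal(l1_monotone_subtract(c(1, 2, 3), 2.1)$cost, 0.1, tolerance = 1e-12)
  expect_equal(l1_monotone_subtract(c(1, 10), c(4, 6))$cost, 7)
  set.seed(12)
  for (trial in 1:30) {
    m <- sample(2:8, 1)
    k <- sample(seq_len(m), 1)
    D <- sort(runif(m, 0, 5))
    E <- sort(runif(k, 0, 5))
    got <- l1_monotone_subtract(D, E)
    expect_equal(got$cost, brute_monotone_cost(D, E), tolerance = 1e-10)
    expect_true(!is.unsorted(got$indices, strictly = TRUE))
  }
  expect_error(l1_monotone_subtract(c(1, 2), c(1, 2, 3)), "exceed")
})

test_that("lpdp_prepare builds the two-segment endpoint partition", {
  # n = 3: endpoint slots are (1,2) and (2,3); the span (1,3) stays unlabeled
  part <- lpdp_prepare(c(1, 2, 3), c(1, 2))
  expect_equal(part$kind, "lpdp")
  expect_equal(part$segments[[1]], c(1, 2))
  expect_equal(part$segments[[2]], 3)
  # noiseless removal is free
  z <- sort(c(0, 4, 9, 17, 26, 40, 55, 71))
  lab <- make_labeled_instance(z, "lpdp")
  expect_equal(l1_monotone_subtract(lab$D, lab$E)$cost, 0)
  # a perturbed endpoint value costs exactly its perturbation
  delta <- 0.25
  E_pert <- sort(lab$E + c(delta, rep(0, length(lab$E) - 1)))
  expect_equal(l1_monotone_subtract(lab$D, E_pert)$cost, delta, tolerance = 1e-9)
  expect_error(lpdp_prepare(c(1, 2, 3), c(1, 2, 3, 4)), "2\\(n-2\\)")
})

test_that("spdp_prepare trims the overlap and labels interior slots missing", {
  lab <- make_labeled_instance(c(0, 1, 3, 7), "spdp")
  expect_equal(lab$A, c(1, 2, 4))
  expect_equal(lab$E, c(1, 3, 4, 6))
  part <- spdp_prepare(lab$A, lab$E, 4)
  expect_equal(part$segments[[1]], c(1, 2, 4))
  expect_equal(part$segments[[2]], c(3, 6)) # E minus the copies of 1 and 4
  counts <- turnpike:::partition_label_counts(part)
  expect_equal(counts$missing, 1L) # the span (1,4)
  # n = 3: everything is adjacent; (1,3) is missing
  p3 <- spdp_prepare(c(1, 2), c(1, 2), 3)
  expect_equal(lengths(p3$segments), c(2L, 0L))
  expect_equal(turnpike:::partition_label_counts(p3)$missing, 1L)
  # n = 2: a single adjacency
  p2 <- spdp_prepare(5, numeric(0), 2)
  expect_equal(p2$segments[[1]], 5)
})

test_that("labeled solves recover noiseless digests", {
  z <- sort(c(0, 4, 9, 17, 26, 40))
  zu <- normalize_points(z)
  lab <- make_labeled_instance(z, "lpdp")
  part <- lpdp_prepare(lab$D, lab$E)
  # best of a few greedy-family restarts, selected by input residual
  best <- NULL
  for (z0 in turnpike:::restart_inits(lab$D, 5, seed = 2)) {
    fit <- block_mm_solve(part, z0)
    resid <- sqrt(sum((estimated_distances(fit$z, lab$D) - lab$D)^2))
    if (is.null(best) || resid < best$resid) best <- list(fit = fit, resid = resid)
  }
  fit <- best$fit
  expect_lt(mean(abs(canonicalize(fit$z, zu) - zu)), 1e-8)
  # and the recovered multiset matches the input
  expect_lt(max(abs(estimated_distances(fit$z, lab$D) - lab$D)), 1e-7)
})
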