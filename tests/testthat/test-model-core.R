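# Canonical types, normalization, and the matrix-free incidence operators.

test_that("normalize_points sorts, centers, scales, and rejects degenerates", {
  z <- normalize_points(c(0, 1, 3))
  expect_equal(z, c(-4, -1, 5) / sqrt(42), tolerance = 1e-12)
  expect_equal(sum(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(z^2)), 1, tolerance = 1e-12)
  # idempotence on an already-normalized configuration
  expect_equal(normalize_points(z), z, tolerance = 1e-14)
  # one global scale factor relates input and output distance multisets
  raw <- c(2.5, -1, 7, 0.3)
  zz <- normalize_points(raw)
  ratio <- sort(apply_Q(zz)) / sort(apply_Q(sort(raw)))
  expect_lt(diff(range(ratio)), 1e-12)
  expect_error(normalize_points(c(5, 5, 5)), "degenerate")
  expect_error(normalize_points(3), "two points")
})

test_that("rescale_distances matches the unit-norm convention", {
  D <- rescale_distances(c(1, 2, 3), 3)
  expect_equal(D, sqrt(3) / sqrt(14) * c(1, 2, 3), tolerance = 1e-12)
  # the distances of the normalized generator reproduce the rescaled multiset
  expect_equal(sort(apply_Q(normalize_points(c(0, 1, 3)))), D, tolerance = 1e-12)
  expect_equal(rescale_distances(D, 3), D, tolerance = 1e-12)
  expect_error(rescale_distances(c(0, 0, 0), 3), "zero")
})

test_that("the norm identity ||D||^2 = n ||z||^2 holds for centered points", {
  for (n in c(2, 3, 7, 20, 50)) {
    z <- sample_points("normal", n, seed = n)
    expect_equal(sum(apply_Q(z)^2), n * sum(z^2), tolerance = 1e-9)
  }
})

test_that("apply_Q enumerates slots width-major", {
  expect_equal(apply_Q(c(0, 1, 3)), c(1, 2, 3))
  expect_equal(apply_Q(c(-1, 0, 1)), c(1, 1, 2))
  expect_equal(apply_Q(c(-2, 2)), 4)
  expect_error(apply_Q(c(1, 0)), "sorted")
})

test_that("apply_Qt is the adjoint: examples, zero-sum, round trip", {
  expect_equal(apply_Qt(c(1, 1, 2), 3), c(-3, 0, 3))
  expect_equal(apply_Qt(c(1, 2, 3), 3), c(-4, -1, 5))
  expect_equal(apply_Qt(rep(0, 6), 4), rep(0, 4))
  expect_error(apply_Qt(c(1, 2), 3), "length")
  for (n in c(2, 5, 13, 31)) {
    z <- sample_points("uniform", n, seed = n + 100)
    # Q^T Q = n I - 1 1^T, so centered z comes back scaled by n
    expect_equal(apply_Qt(apply_Q(z), n), n * z, tolerance = 1e-9)
    d <- rnorm(n * (n - 1) / 2)
    expect_equal(sum(apply_Qt(d, n)), 0, tolerance = 1e-9)
    # agreement with the dense-matrix oracle
    expect_equal(apply_Qt(d, n), as.vector(t(dense_Q(n)) %*% d), tolerance = 1e-10)
    expect_equal(apply_Q(z), as.vector(dense_Q(n) %*% z), tolerance = 1e-12)
  }
})

test_that("interval_slot is a bijection with a working inverse", {
  expect_equal(interval_slot(1, 2, 3), 1)
  expect_equal(interval_slot(1, 3, 3), 3)
  for (n in c(4, 7, 12)) expect_equal(interval_slot(n - 1, n, n), n - 1)
  n <- 7
  sp <- expand_pairs(n)
  slots <- interval_slot(sp$i, sp$j, n)
  expect_setequal(slots, seq_len(n * (n - 1) / 2))
  for (k in seq_len(n * (n - 1) / 2)) {
    ij <- slot_interval(k, n)
    expect_equal(interval_slot(ij[1], ij[2], n), k)
  }
  expect_error(interval_slot(3, 2, 5), "i < j")
  expect_error(slot_interval(11, 4), "range")
})

test_that("objective_value evaluates the matching inner product", {
  z <- normalize_points(c(0, 1, 3))
  D <- rescale_distances(c(1, 2, 3), 3)
  m <- sorted_match_apply(D, z)$matching
  # noiseless fixed point: <D-bar, D-bar> = n
  expect_equal(objective_value(z, D, m), 3, tolerance = 1e-9)
  expect_equal(objective_value(z, rep(0, 3), m), 0)
  expect_error(objective_value(z, c(1, 2), m), "size")
})

test_that("the sorted matching maximizes the objective (rearrangement)", {
  set.seed(42)
  n <- 6
  z <- sample_points("normal", n, seed = 9)
  D <- make_noisy_instance(z, noise_spec("gaussian", 0.05, seed = 10))
  best <- objective_value(z, D, sorted_match_apply(D, z)$matching)
  sp <- expand_pairs(n)
  for (trial in seq_len(1000)) {
    perm <- sample.int(nrow(sp))
    rand_match <- list(i = sp$i[perm], j = sp$j[perm])
    expect_lte(objective_value(z, D, rand_match), best + 1e-12)
  }
  # reversing the sorted matching on strictly sorted intervals is strictly worse
  m <- sorted_match_apply(D, z)$matching
  rev_match <- list(i = rev(m$i), j = rev(m$j))
  expect_lt(objective_value(z, D, rev_match), best)
})

test_that("distance files round-trip and ignore comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "3.5", " 1.25", "", "2 # trailing"), path)
  expect_equal(read_distances(path), c(1.25, 2, 3.5))
  write_distances(c(0.1, 0.25), path)
  expect_equal(read_distances(path), c(0.1, 0.25))
})
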