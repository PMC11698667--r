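# Synthetic-instance generators.

test_that("generators are deterministic under fixed seeds", {
  expect_identical(sample_points("cauchy", 30, seed = 5),
                   sample_points("cauchy", 30, seed = 5))
  z <- sample_points("uniform", 8, seed = 1)
  ns <- noise_spec("gaussian", 0.01, seed = 9)
  expect_identical(make_noisy_instance(z, ns), make_noisy_instance(z, ns))
  expect_identical(make_beltway_instance(6, seed = 3),
                   make_beltway_instance(6, seed = 3))
  expect_identical(make_labeled_instance(c(0, 2, 5, 9), "lpdp",
                                         noise_spec("relative_uniform", 0.05, 2)),
                   make_labeled_instance(c(0, 2, 5, 9), "lpdp",
                                         noise_spec("relative_uniform", 0.05, 2)))
})

test_that("sampled configurations are valid and cauchy is heavy-tailed", {
  for (d in c("uniform", "normal", "cauchy")) {
    expect_silent(check_points(sample_points(d, 50, seed = 7)))
  }
  expect_equal(sample_points("uniform", 2, seed = 1), c(-1, 1) / sqrt(2),
               tolerance = 1e-12)
  zc <- sample_points("cauchy", 100, seed = 11)
  expect_gt(max(abs(zc)) / median(abs(zc)), 10)
  expect_error(sample_points("exponential", 5), "arg")
})

test_that("noise models behave as specified, including the zero clamp", {
  z <- sample_points("uniform", 10, seed = 3)
  expect_equal(make_noisy_instance(z, noise_spec("none")), sort(apply_Q(z)))
  # massive gaussian noise never yields negative distances
  big <- make_noisy_instance(z, noise_spec("gaussian", 10, seed = 4))
  expect_true(all(big >= 0))
  expect_true(any(big == 0)) # some measurements drown and clamp to zero
  # relative noise with r = 0 keeps integer distances unchanged
  zi <- c(0, 3, 7, 15)
  expect_equal(make_noisy_instance(zi, noise_spec("relative_uniform", 0, seed = 1)),
               sort(apply_Q(zi)))
  # relative noise stays inside the band
  r <- 0.05
  d0 <- apply_Q(zi * 100)
  dn <- make_noisy_instance(zi * 100, noise_spec("relative_uniform", r, seed = 2))
  expect_true(all(dn >= floor((1 - r) * sort(d0)) - 1e-9))
  expect_true(all(dn <= ceiling((1 + r) * sort(d0)) + 1e-9))
  expect_true(all(dn == round(dn)))
  # signed poisson with lambda 0 is noiseless
  expect_equal(make_noisy_instance(zi, noise_spec("signed_poisson", 0, seed = 5)),
               sort(apply_Q(zi)))
})

test_that("digest_genome cuts at planted motifs", {
  motif <- "ACGTACGTACGTAGG"
  set.seed(99)
  bases <- sample(c("A", "C", "G", "T"), 1200, replace = TRUE)
  for (pos in c(101, 351, 901)) {
    bases[pos:(pos + 14)] <- strsplit(motif, "")[[1]]
  }
  seqn <- paste(bases, collapse = "")
  dig <- digest_genome(seqn, motif_length = 15, min_occurrences = 3,
                       max_occurrences = 10, seed = 6, max_attempts = 5000)
  expect_equal(dig$motif, motif)
  expect_equal(dig$cuts, c(0, 100, 350, 900, 1200))
  expect_equal(length(dig$distances), choose(5, 2))
  expect_equal(dig$distances, sort(apply_Q(as.numeric(dig$cuts))))
  # noise: lambda = 0 keeps distances exact
  dig0 <- digest_genome(seqn, motif_length = 15, min_occurrences = 3,
                        max_occurrences = 10,
                        noise = noise_spec("signed_poisson", 0), seed = 6,
                        max_attempts = 5000)
  expect_equal(dig0$distances, dig$distances)
})

test_that("digest_genome rejects motifs outside the occurrence band", {
  seqn <- paste(rep("ACGT", 500), collapse = "")
  expect_error(
    digest_genome(seqn, motif_length = 4, min_occurrences = 2,
                  max_occurrences = 100, seed = 1, max_attempts = 40),
    "no motif"
  )
})

test_that("labeled instances match their definitions", {
  lab <- make_labeled_instance(c(0, 1, 3), "lpdp")
  expect_equal(lab$D, c(1, 2, 3))
  expect_equal(lab$E, c(1, 2))
  lab2 <- make_labeled_instance(c(0, 1, 3, 7), "spdp")
  expect_equal(lab2$A, c(1, 2, 4))
  expect_equal(lab2$E, c(1, 3, 4, 6))
  expect_error(make_labeled_instance(c(0, 1), "lpdp"), "n >= 3")
})

test_that("beltway instances pair arcs to the full circumference", {
  inst <- make_beltway_instance(7, seed = 2)
  arcs <- inst$arcs
  expect_equal(length(arcs), 7 * 6)
  expect_equal(sort(arcs + rev(arcs)), rep(2 * pi, length(arcs)), tolerance = 1e-9)
  inst2 <- make_beltway_instance(2, seed = 4)
  expect_equal(sum(inst2$arcs), 2 * pi, tolerance = 1e-12)
})
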