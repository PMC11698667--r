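# Initialization schemes for the alternating solvers. The landscape of the
# matching objective is riddled with local maxima, so the starting
# configuration matters; the greedy placement is the strongest of the three
# and is the default throughout the package.

#' Gaussian initializer
#'
#' Draws a standard-normal vector, sorts, centers, and unit-normalizes it.
#'
#' @param n Point count.
#' @param seed Integer seed (the draw is deterministic given the seed).
#' @return A valid point configuration.
#' @export
gaussian_init <- function(n, seed = 1L) {
  stopifnot(n >= 2)
  raw <- withr::with_seed(seed, stats::rnorm(n))
  normalize_points(raw)
}

#' Random-permutation initializer
#'
#' Assigns the distances to interval slots uniformly at random and returns
#' the sorted unit normalization of the closed-form point update
#' `Q^T P0 D` for that assignment.
#'
#' @param D Sorted complete distance multiset.
#' @param seed Integer seed.
#' @return A valid point configuration.
#' @export
permutation_init <- function(D, seed = 1L) {
  check_distances(D)
  n <- n_from_m(length(D))
  perm <- withr::with_seed(seed, sample.int(length(D)))
  unit(sort(center(apply_Qt(D[perm], n))))
}

#' Greedy largest-first initializer
#'
#' Anchors points at 0 and max(D), then repeatedly takes the largest unused
#' distance and places a new point at that distance from either the left or
#' the right anchor, choosing the side whose implied distances to the points
#' placed so far have the smaller total l1 discrepancy to the nearest unused
#' input values (which are then consumed). Unlike the classical backtracking
#' reconstruction this never revisits a choice, so it runs in polynomial time
#' and serves as a strong starting point for the MM solvers rather than as a
#' solver itself. With `flip_prob > 0` the placement choice is randomly
#' inverted with that probability, which turns the deterministic scheme into
#' a family of restart candidates.
#'
#' @param D Sorted complete distance multiset.
#' @param seed Integer seed (only used when `flip_prob > 0`).
#' @param flip_prob Probability of inverting a placement choice.
#' @return A valid point configuration.
#' @export
greedy_init <- function(D, seed = 1L, flip_prob = 0) {
  check_distances(D)
  if (length(D) == 0) stop("empty distance multiset", call. = FALSE)
  n <- n_from_m(length(D))
  flips <- if (flip_prob > 0) {
    withr::with_seed(seed, stats::runif(n) < flip_prob)
  } else {
    rep.int(FALSE, n)
  }
  normalize_points(cpp_greedy_place(as.numeric(D), flips))
}

#' Best-of-k initializer selection
#'
#' Draws `samples` candidates from the named scheme, scores each by the
#' matching objective (the inner product of the candidate's sorted intervals
#' with the sorted distances), and returns the maximizer. The greedy scheme
#' is deterministic and contributes a single candidate.
#'
#' @param D Sorted complete distance multiset.
#' @param scheme One of `"gaussian"`, `"permutation"`, `"greedy"`.
#' @param samples Number of candidates; defaults to n.
#' @param seed Integer master seed.
#' @return The highest-scoring candidate configuration, with the score in
#'   attribute `score`.
#' @export
best_of <- function(D, scheme = c("greedy", "gaussian", "permutation"),
                    samples = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  check_distances(D)
  n <- n_from_m(length(D))
  if (is.null(samples)) samples <- n
  stopifnot(samples >= 1)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, samples))
  cands <- switch(scheme,
    gaussian = lapply(seeds, function(s) gaussian_init(n, s)),
    permutation = lapply(seeds, function(s) permutation_init(D, s)),
    greedy = list(greedy_init(D))
  )
  scores <- vapply(cands, function(z) {
    r <- sorted_match_apply(D, z)
    objective_value(z, D, r$matching)
  }, numeric(1))
  best <- which.max(scores)
  structure(cands[[best]], score = scores[best])
}

# Restart candidates for the evaluation protocol: the pure greedy placement
# first, then greedy placements with randomized side choices.
restart_inits <- function(D, restarts, seed, flip_prob = 0.15) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, restarts))
  lapply(seq_len(restarts), function(r) {
    if (r == 1) greedy_init(D) else greedy_init(D, seed = seeds[r], flip_prob = flip_prob)
  })
}
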