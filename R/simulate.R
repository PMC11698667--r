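# Synthetic instance generation: distributional point sets with additive
# Gaussian noise, simulated restriction digests with signed-Poisson cut
# noise, relative integer noise, and generators for the circular and labeled
# variants. All generators are deterministic under a fixed seed.

#' Noise specification
#'
#' @param kind One of `"none"`, `"gaussian"` (additive N(0, magnitude^2),
#'   i.e. `magnitude` is the standard deviation of the measurement
#'   uncertainty), `"signed_poisson"` (additive s * Poisson(magnitude) with
#'   an independent uniform sign s, modeling an enzyme cutting a few bases
#'   too early or too late), or `"relative_uniform"` (each distance d is
#'   replaced by a uniform integer in \[(1-magnitude) d, (1+magnitude) d\];
#'   distances should be in integer base-pair units).
#' @param magnitude Noise magnitude (epsilon, lambda, or r respectively).
#' @param seed Integer seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "gaussian", "signed_poisson", "relative_uniform"),
                       magnitude = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(magnitude >= 0)
  if (kind == "relative_uniform") stopifnot(magnitude <= 1)
  structure(list(kind = kind, magnitude = magnitude, seed = as.integer(seed)),
            class = "noise_spec")
}

apply_noise <- function(d, noise) {
  out <- switch(noise$kind,
    none = d,
    gaussian = d + stats::rnorm(length(d), 0, noise$magnitude),
    signed_poisson = d + sample(c(-1, 1), length(d), replace = TRUE) *
      stats::rpois(length(d), noise$magnitude),
    relative_uniform = {
      lo <- ceiling((1 - noise$magnitude) * d - 1e-9)
      hi <- floor((1 + noise$magnitude) * d + 1e-9)
      bad <- lo > hi
      x <- floor(stats::runif(length(d), lo, hi + 1))
      x <- pmin(pmax(x, lo), hi)
      x[bad] <- round(d[bad])
      x
    }
  )
  # a measurement whose uncertainty exceeds it is reported as a zero distance
  sort(pmax(out, 0))
}

#' Sample a point configuration from a named distribution
#'
#' @param distribution `"uniform"` (on \[0, 1\]), `"normal"` (standard), or
#'   `"cauchy"` (standard; heavy tails stress the l2 machinery).
#' @param n Point count.
#' @param seed Integer seed.
#' @return A valid (sorted, centered, unit-norm) point configuration.
#' @export
sample_points <- function(distribution = c("uniform", "normal", "cauchy"),
                          n, seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 2)
  raw <- withr::with_seed(seed, switch(distribution,
    uniform = stats::runif(n),
    normal = stats::rnorm(n),
    cauchy = stats::rcauchy(n)
  ))
  normalize_points(raw)
}

#' Noisy complete distance multiset of a point configuration
#'
#' Computes all pairwise distances of `z`, perturbs each independently
#' according to the noise specification, clamps non-positive results to zero
#' (a measurement drowned by its own uncertainty reads as a missing/zero
#' fragment), and returns the sorted multiset.
#'
#' @param z Sorted point configuration (any scale).
#' @param noise A [noise_spec()].
#' @return Sorted noisy distance multiset.
#' @export
make_noisy_instance <- function(z, noise = noise_spec("none")) {
  stopifnot(inherits(noise, "noise_spec"))
  d <- apply_Q(z)
  withr::with_seed(noise$seed, apply_noise(d, noise))
}

#' Simulate a partial restriction digest of a DNA sequence
#'
#' Draws candidate recognition motifs (substrings of the sequence at uniform
#' random offsets) until one occurs between `min_occurrences` and
#' `max_occurrences` times, cuts the sequence at every (possibly
#' overlapping) occurrence, and returns all pairwise distances between cut
#' positions (occurrence start offsets plus both sequence ends) with
#' signed-Poisson noise applied per distance.
#'
#' @param sequence A DNA string, or a path to a FASTA file (first record
#'   used; requires the Biostrings package).
#' @param motif_length Recognition-site length in bases.
#' @param min_occurrences,max_occurrences Acceptance band for the motif's
#'   occurrence count.
#' @param noise A [noise_spec()] (typically `"signed_poisson"`).
#' @param seed Integer seed for motif sampling.
#' @param max_attempts Candidate draws before giving up.
#' @return A list of class `digest_instance` with `sequence_length`, `motif`,
#'   `cuts` (0-based offsets), `n_sites`, and the sorted noisy `distances`.
#' @export
digest_genome <- function(sequence, motif_length = 15L, min_occurrences = 10L,
                          max_occurrences = 500L, noise = noise_spec("none"),
                          seed = 1L, max_attempts = 1000L) {
  if (length(sequence) == 1 && file.exists(sequence) && !grepl("^[ACGTNacgtn]+$", sequence)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA input requires the Biostrings package", call. = FALSE)
    }
    sequence <- as.character(Biostrings::readDNAStringSet(sequence)[[1]])
  }
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L <= motif_length) stop("sequence shorter than the motif length", call. = FALSE)
  found <- withr::with_seed(seed, {
    res <- NULL
    for (attempt in seq_len(max_attempts)) {
      pos <- sample.int(L - motif_length + 1L, 1L)
      motif <- substr(sequence, pos, pos + motif_length - 1L)
      # lookahead regex finds overlapping occurrences
      hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
      starts <- if (hits[1] == -1) integer(0) else as.integer(hits)
      if (length(starts) >= min_occurrences && length(starts) <= max_occurrences) {
        res <- list(motif = motif, starts = starts)
        break
      }
    }
    res
  })
  if (is.null(found)) {
    stop("no motif of length ", motif_length, " occurring between ",
         min_occurrences, " and ", max_occurrences, " times was found in ",
         max_attempts, " draws", call. = FALSE)
  }
  cuts <- sort(unique(c(0L, found$starts - 1L, L)))
  d <- apply_Q(as.numeric(cuts))
  distances <- withr::with_seed(noise$seed, apply_noise(d, noise))
  structure(list(sequence_length = L, motif = found$motif, cuts = cuts,
                 n_sites = length(cuts), distances = distances),
            class = "digest_instance")
}

#' @export
print.digest_instance <- function(x, ...) {
  cat("<digest_instance> motif", x$motif, "->", x$n_sites, "cut positions,",
      length(x$distances), "fragment distances\n")
  invisible(x)
}

#' Generate a circular (Beltway) instance
#'
#' @param n Number of circle points.
#' @param seed Integer seed.
#' @return List with `angles` (sorted, uniform on \[0, 2*pi)) and `arcs`
#'   (sorted multiset of all n(n-1) directed arcs; the two arcs of every
#'   pair sum to 2*pi).
#' @export
make_beltway_instance <- function(n, seed = 1L) {
  stopifnot(n >= 2)
  theta <- withr::with_seed(seed, sort(stats::runif(n, 0, 2 * pi)))
  list(angles = theta, arcs = arcs_from_angles(theta))
}

#' Generate a labeled or simplified partial digest input
#'
#' Emits the measurement sets that define the two digest labelings: the
#' complete multiset `D` and endpoint distances `E` (interior points to both
#' ends) for `"lpdp"`, or adjacent distances `A` and `E` for `"spdp"`. Noise
#' is applied independently to every measured value.
#'
#' @param z Sorted point configuration (any scale; integer base-pair
#'   positions for relative noise).
#' @param kind `"lpdp"` or `"spdp"`.
#' @param noise A [noise_spec()].
#' @return For `"lpdp"`: list with `D`, `E`, `n`. For `"spdp"`: list with
#'   `A`, `E`, `n`.
#' @export
make_labeled_instance <- function(z, kind = c("lpdp", "spdp"),
                                  noise = noise_spec("none")) {
  kind <- match.arg(kind)
  n <- length(z)
  stopifnot(n >= 3)
  if (is.unsorted(z)) stop("z must be sorted", call. = FALSE)
  interior <- z[2:(n - 1)]
  E <- sort(c(z[n] - interior, interior - z[1]))
  withr::with_seed(noise$seed, {
    if (kind == "lpdp") {
      D <- apply_Q(z)
      list(D = apply_noise(D, noise), E = apply_noise(E, noise), n = n)
    } else {
      A <- diff(z)
      list(A = apply_noise(A, noise), E = apply_noise(E, noise), n = n)
    }
  })
}
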