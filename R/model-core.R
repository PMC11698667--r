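#' turnpike: reconstruct 1-D point sets from unassigned pairwise distances
#'
#' Solvers for the noisy Turnpike problem (points on a line) and the Beltway
#' problem (points on a circle) given only the unordered multiset of pairwise
#' distances, the situation encountered when mapping restriction sites from a
#' partial digest. The workhorse is a minorization-maximization (MM) scheme
#' that alternates between a sorting-based matching of distances to point
#' pairs and a closed-form point update, refined by divide-and-conquer
#' ([mmdq_solve()]) and extended to partitioned, labeled, and missing
#' distances ([block_mm_solve()], [beltway_solve()]). Small instances can be
#' certified globally optimal through a mixed-integer formulation
#' ([solve_exact()]).
#'
#' @useDynLib turnpike, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rcauchy rpois sd
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

# ---- internal helpers -------------------------------------------------------

unit <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot normalize a zero vector", call. = FALSE)
  x / nrm
}

center <- function(x) x - mean(x)

#' Number of points implied by a complete distance multiset
#'
#' Inverts m = n(n-1)/2. Errors when `m` is not a triangular number.
#'
#' @param m Number of pairwise distances.
#' @return Integer point count `n`.
#' @export
#' @examples
#' n_from_m(3)  # 3 points
#' n_from_m(10) # 5 points
n_from_m <- function(m) {
  stopifnot(length(m) == 1, m >= 1)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("length ", m, " is not n(n-1)/2 for any integer n", call. = FALSE)
  }
  as.integer(round(n))
}

# Width-major slot enumeration shared by every operator in the package:
# widths w = 1..n-1, and for each width the left endpoints i = 1..n-w.
# Returns a list with integer vectors i and j (slot k is the pair (i[k], j[k])).
slot_pairs <- function(n) {
  w <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  i <- sequence((n - 1L):1L)
  list(i = i, j = i + w)
}

# ---- validators -------------------------------------------------------------

#' Validate a point configuration
#'
#' A point configuration is a plain numeric vector holding n >= 2 sorted point
#' coordinates that sum to zero; when `normalized = TRUE` it must additionally
#' have unit Euclidean norm. These are the symmetry-breaking conventions that
#' make the reconstruction unique up to reflection: translation is removed by
#' centering, point labels by sorting, and (optionally) scale by normalizing.
#'
#' @param z Numeric vector of point coordinates.
#' @param normalized Require unit Euclidean norm?
#' @param tol Tolerance on the centering/norm checks.
#' @return `z`, invisibly, if valid; otherwise an error.
#' @export
check_points <- function(z, normalized = TRUE, tol = 1e-9) {
  if (!is.numeric(z) || length(z) < 2) {
    stop("a point configuration needs at least 2 numeric values", call. = FALSE)
  }
  if (is.unsorted(z)) stop("point values must be sorted ascending", call. = FALSE)
  if (abs(sum(z)) > tol * max(1, max(abs(z)))) {
    stop("point values must be centered (sum zero)", call. = FALSE)
  }
  if (normalized && abs(sqrt(sum(z^2)) - 1) > tol) {
    stop("point values must have unit Euclidean norm", call. = FALSE)
  }
  invisible(z)
}

#' Validate a distance multiset
#'
#' @param d Numeric vector of pairwise distances.
#' @param complete Require `length(d)` to equal n(n-1)/2 for some integer n?
#' @return `d`, invisibly, if valid.
#' @export
check_distances <- function(d, complete = TRUE) {
  if (!is.numeric(d) || length(d) < 1) stop("empty distance multiset", call. = FALSE)
  if (any(d < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (is.unsorted(d)) stop("distances must be sorted ascending", call. = FALSE)
  if (complete) n_from_m(length(d))
  invisible(d)
}

# ---- operations -------------------------------------------------------------

#' Canonicalize raw point coordinates
#'
#' Sorts, centers, and scales a set of point coordinates to unit Euclidean
#' norm. The pairwise distance multiset of the result equals that of the input
#' up to one global positive scale factor, so no information relevant to the
#' reconstruction problem is lost.
#'
#' @param raw Numeric vector of at least two coordinates, not all equal.
#' @return Sorted, centered, unit-norm numeric vector.
#' @export
#' @examples
#' normalize_points(c(0, 1, 3))
normalize_points <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 2) {
    stop("need at least two points", call. = FALSE)
  }
  z <- center(sort(raw))
  nrm <- sqrt(sum(z^2))
  if (nrm < 1e-14 * max(1, max(abs(raw)))) {
    stop("degenerate configuration: all points identical", call. = FALSE)
  }
  z / nrm
}

#' Rescale a distance multiset to match a unit-norm point set
#'
#' Applies the scale factor sqrt(n)/||D||, after which the multiset has
#' Euclidean norm sqrt(n) and is reproduced exactly by the unit-norm
#' normalization of its generating points in the noiseless case (the identity
#' ||D||^2 = n ||z||^2 holds for any centered z and its complete multiset).
#'
#' @param D Sorted distance multiset, complete for `n` points.
#' @param n Point count.
#' @return Rescaled distance multiset.
#' @export
rescale_distances <- function(D, n) {
  check_distances(D)
  stopifnot(n_from_m(length(D)) == n)
  nrm <- sqrt(sum(D^2))
  if (nrm == 0) stop("cannot rescale an all-zero distance multiset", call. = FALSE)
  D * sqrt(n) / nrm
}

#' Pairwise-difference operator (Q z)
#'
#' Computes all pairwise differences z\[j\] - z\[i\] (i < j) of a sorted point
#' vector without materializing the m-by-n incidence matrix. Slots are
#' enumerated width-major: all adjacent pairs first (width 1), then width 2,
#' and so on, with the left endpoint running 1..n-w within each width.
#'
#' @param z Sorted numeric vector of point coordinates.
#' @return Numeric vector of length n(n-1)/2 in width-major slot order.
#' @export
#' @examples
#' apply_Q(c(0, 1, 3)) # slots (1,2), (2,3), (1,3)
apply_Q <- function(z) {
  n <- length(z)
  stopifnot(n >= 2)
  if (is.unsorted(z)) stop("z must be sorted", call. = FALSE)
  sp <- slot_pairs(n)
  z[sp$j] - z[sp$i]
}

#' Adjoint pairwise-difference operator (Q^T d)
#'
#' Accumulates a slot-indexed vector back onto point coordinates: slot (i, j)
#' contributes -d to point i and +d to point j. The output always sums to
#' zero. Slot order must be the width-major order of [apply_Q()].
#'
#' @param d Numeric vector of length n(n-1)/2 in width-major slot order.
#' @param n Point count.
#' @return Numeric vector of length `n` summing to zero.
#' @export
apply_Qt <- function(d, n) {
  m <- n * (n - 1) / 2
  if (length(d) != m) {
    stop("d has length ", length(d), " but n = ", n, " needs ", m, call. = FALSE)
  }
  sp <- slot_pairs(n)
  out <- numeric(n)
  pos <- rowsum(d, sp$j)
  neg <- rowsum(d, sp$i)
  out[as.integer(rownames(pos))] <- pos
  out[as.integer(rownames(neg))] <- out[as.integer(rownames(neg))] - neg
  out
}

#' Map an index pair to its width-major slot, and back
#'
#' `interval_slot()` maps a pair (i, j), i < j, to its 1-based position in the
#' width-major slot enumeration; `slot_interval()` is the inverse. Fixing this
#' bijection once package-wide avoids silent permutation bugs between the
#' operator oracles, the matching sweep, and the exact model.
#'
#' @param i,j 1-based point indices with `i < j <= n`.
#' @param n Point count.
#' @return `interval_slot()`: integer slot in 1..n(n-1)/2.
#' @export
#' @examples
#' interval_slot(1, 3, n = 3) # 3
#' slot_interval(3, n = 3)    # c(1, 3)
interval_slot <- function(i, j, n) {
  if (any(i < 1) || any(j <= i) || any(j > n)) {
    stop("need 1 <= i < j <= n", call. = FALSE)
  }
  w <- j - i
  (w - 1) * n - w * (w - 1) / 2 + i
}

#' @rdname interval_slot
#' @param k Slot index in 1..n(n-1)/2.
#' @return `slot_interval()`: integer vector `c(i, j)`.
#' @export
slot_interval <- function(k, n) {
  m <- n * (n - 1) / 2
  if (any(k < 1) || any(k > m)) stop("slot out of range", call. = FALSE)
  sp <- slot_pairs(n)
  if (length(k) == 1) c(sp$i[k], sp$j[k]) else cbind(i = sp$i[k], j = sp$j[k])
}

#' Bilinear matching objective
#'
#' Evaluates the inner product between the pairwise differences of `z` and the
#' distances as assigned by a matching: sum over t of D\[t\] * (z\[j_t\] - z\[i_t\]).
#' By the rearrangement inequality this is maximized, for fixed `z`, by the
#' matching that assigns sorted distances to sorted intervals.
#'
#' @param z Sorted point configuration.
#' @param D Sorted distance multiset; entry t is assigned to `matching` row t.
#' @param matching A matching as returned by [sorted_match_apply()]: a list
#'   with integer vectors `i` and `j`, row t holding the interval that
#'   receives the t-th distance.
#' @return Scalar objective value.
#' @export
objective_value <- function(z, D, matching) {
  if (length(D) != length(matching$i) || length(matching$i) != length(matching$j)) {
    stop("matching and distance sizes differ", call. = FALSE)
  }
  if (max(matching$j) > length(z)) stop("matching indices exceed length(z)", call. = FALSE)
  sum(D * (z[matching$j] - z[matching$i]))
}

# ---- file I/O ---------------------------------------------------------------

#' Read or write a plain-text distance (or point) file
#'
#' One decimal value per line; blank lines and `#` comments are ignored; input
#' order is irrelevant because values are sorted on load.
#'
#' @param path File path.
#' @return `read_distances()`: sorted numeric vector.
#' @export
read_distances <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) stop("non-numeric entries in ", path, call. = FALSE)
  sort(vals)
}

#' @rdname read_distances
#' @param x Numeric vector to write.
#' @export
write_distances <- function(x, path) {
  writeLines(format(x, digits = 17, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}
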