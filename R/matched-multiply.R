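# Sorting-based matched multiplication: the inner kernel of every solver.
# One sweep pops intervals (i, j) in increasing current-length order from a
# frontier that never holds more than n - 1 entries (one per chain (k, k+t)),
# assigns the t-th smallest distance to the t-th popped interval, and
# accumulates -d / +d onto the two endpoints, producing Q^T P^T D without ever
# materializing Q or the permutation.

#' Matched adjoint multiply under the sorting assignment
#'
#' Computes `z+ = Q^T P^T D` where `P^T` is the permutation that assigns the
#' sorted distances to the intervals of `z` in increasing length order (the
#' closed-form matching step of the MM scheme). Equivalent to sorting the
#' pairwise differences of `z`, permuting `D` accordingly, and applying
#' [apply_Qt()], but runs with an O(n) frontier instead of materializing the
#' permutation. Ties between equal interval lengths break lexicographically
#' on (i, j).
#'
#' @param D Sorted, complete distance multiset (length n(n-1)/2).
#' @param z Sorted point configuration of length n (any scale).
#' @return List with `z` (the accumulated n-vector, sums to zero) and
#'   `matching` (list of integer vectors `i`, `j`: row t is the interval that
#'   received the t-th smallest distance).
#' @export
#' @examples
#' sorted_match_apply(c(1, 2, 3), c(-1, 0, 1))
sorted_match_apply <- function(D, z) {
  check_distances(D)
  n <- length(z)
  if (n_from_m(length(D)) != n) {
    stop("|D| = ", length(D), " is not complete for n = ", n, " points", call. = FALSE)
  }
  if (is.unsorted(z)) stop("z must be sorted", call. = FALSE)
  res <- cpp_match_apply(as.numeric(z), as.numeric(D))
  list(z = res$z, matching = list(i = res$i, j = res$j))
}

# ---- distance partitions ----------------------------------------------------

#' Construct a partitioned distance multiset
#'
#' A distance partition labels every interval slot of an n-point instance with
#' the segment its distance was observed in: label 0 marks slots whose
#' distance is missing (these are simulated from the running estimate during a
#' sweep), labels 1..k name observed segments, each holding its own sorted
#' distance list. Built-in label rules (`kind`) are evaluated in O(1) per
#' slot; a custom partition supplies an explicit label per width-major slot.
#'
#' @param n Point count of the (possibly lifted) instance.
#' @param segments List of sorted numeric vectors, one per observed segment.
#' @param kind One of `"trivial"` (one segment covering every slot),
#'   `"lpdp"` (segment 1 = endpoint-touching interior pairs, segment 2 = the
#'   rest), `"spdp"` (segment 1 = adjacencies, segment 2 = endpoint
#'   non-adjacent pairs, interior pairs missing), `"beltway"` (segment 2 = the
#'   n0 circumference slots (k, k + n0); segment 1 = lower-copy pairs and
#'   wrapping cross pairs, which hold the observed arcs; upper-copy
#'   duplicates and super-circumference pairs missing), or `"custom"`.
#' @param labels Integer vector of length n(n-1)/2 with one label per
#'   width-major slot (only for `kind = "custom"`).
#' @param n0 Original point count of a circular instance (only for
#'   `kind = "beltway"`, where `n = 2 * n0`).
#' @return An object of class `distance_partition`.
#' @export
distance_partition <- function(n, segments, kind = "custom", labels = NULL, n0 = NULL) {
  kind <- match.arg(kind, c("trivial", "lpdp", "spdp", "beltway", "custom"))
  stopifnot(n >= 2, is.list(segments), length(segments) >= 1)
  m <- n * (n - 1) / 2
  for (s in segments) {
    if (length(s) && (any(s < 0) || is.unsorted(s))) {
      stop("each segment must be sorted and nonnegative", call. = FALSE)
    }
  }
  if (kind == "custom") {
    if (is.null(labels) || length(labels) != m) {
      stop("custom partition needs one label per slot (", m, ")", call. = FALSE)
    }
    labels <- as.integer(labels)
    if (any(labels < 0) || any(labels > length(segments))) {
      stop("labels must lie in 0..", length(segments), call. = FALSE)
    }
  }
  if (kind == "beltway") {
    if (is.null(n0) || n != 2 * n0) stop("beltway partition needs n = 2 * n0", call. = FALSE)
  }
  pt <- structure(
    list(n = as.integer(n), kind = kind, segments = segments,
         labels = labels, n0 = if (is.null(n0)) 0L else as.integer(n0)),
    class = "distance_partition"
  )
  counts <- partition_label_counts(pt)
  sizes <- lengths(segments)
  if (length(counts$observed) != length(sizes) || any(counts$observed != sizes)) {
    stop("segment sizes (", paste(sizes, collapse = ", "),
         ") do not match their slot counts (",
         paste(counts$observed, collapse = ", "), ")", call. = FALSE)
  }
  pt
}

#' @export
print.distance_partition <- function(x, ...) {
  counts <- partition_label_counts(x)
  cat("<distance_partition> n =", x$n, " kind =", x$kind, "\n")
  cat("  observed segments:", paste(lengths(x$segments), collapse = ", "),
      " missing slots:", counts$missing, "\n")
  invisible(x)
}

# Labels for every width-major slot (materialized; used for validation and by
# the exact model, not by the O(n)-memory sweep).
partition_slot_labels <- function(pt) {
  sp <- slot_pairs(pt$n)
  n <- pt$n
  switch(pt$kind,
    trivial = rep.int(1L, length(sp$i)),
    lpdp = ifelse((sp$i == 1L & sp$j < n) | (sp$j == n & sp$i > 1L), 1L, 2L),
    spdp = ifelse(sp$j == sp$i + 1L, 1L,
      ifelse((sp$i == 1L & sp$j < n) | (sp$j == n & sp$i > 1L), 2L, 0L)),
    beltway = ifelse(sp$j - sp$i == pt$n0, 2L,
      ifelse(sp$j - sp$i < pt$n0 & sp$i <= pt$n0, 1L, 0L)),
    custom = pt$labels
  )
}

partition_label_counts <- function(pt) {
  lab <- partition_slot_labels(pt)
  k <- length(pt$segments)
  list(observed = vapply(seq_len(k), function(p) sum(lab == p), integer(1)),
       missing = sum(lab == 0L))
}

#' Trivial partition wrapping a complete distance multiset
#'
#' @param D Sorted complete distance multiset.
#' @return A `distance_partition` whose single segment covers every slot;
#'   solving it is identical to solving the plain instance.
#' @export
trivial_partition <- function(D) {
  check_distances(D)
  distance_partition(n_from_m(length(D)), list(sort(D)), kind = "trivial")
}

#' Matched adjoint multiply on a partitioned distance multiset
#'
#' The partition-aware version of [sorted_match_apply()]: intervals are popped
#' in increasing current-length order; an interval labeled p > 0 consumes the
#' next unused distance of segment p, and an interval labeled 0 (missing) uses
#' the simulated distance `z[j] - z[i]` from the current estimate. With the
#' trivial partition this reduces exactly to [sorted_match_apply()].
#'
#' @param partition A [distance_partition()].
#' @param z Sorted point vector of length `partition$n` (any scale).
#' @return List with `z` (accumulated n-vector), `matching` (pop-order
#'   intervals `i`, `j`), and `d` (the distance value used at each pop).
#' @export
partitioned_match_apply <- function(partition, z) {
  stopifnot(inherits(partition, "distance_partition"))
  if (length(z) != partition$n) {
    stop("z has length ", length(z), " but partition is for n = ", partition$n,
         call. = FALSE)
  }
  if (is.unsorted(z)) stop("z must be sorted", call. = FALSE)
  kind_code <- match(partition$kind, c("custom", "trivial", "lpdp", "spdp", "beltway")) - 1L
  res <- cpp_partition_match_apply(
    as.numeric(z), lapply(partition$segments, as.numeric), kind_code,
    partition$n0, if (is.null(partition$labels)) integer(0) else partition$labels
  )
  list(z = res$z, matching = list(i = res$i, j = res$j), d = res$d)
}
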