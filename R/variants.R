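# Reductions of the circular (Beltway) problem and of the two partial-digest
# labelings (LPDP: all pairwise distances plus labeled end distances; SPDP:
# adjacent distances plus end distances) to partitioned Turnpike instances.

#' Lift a circular instance to a partitioned linear instance
#'
#' Encodes n points on a circle of circumference 2*pi as 2n collinear points:
#' a lower copy `theta - 2*pi` followed by an upper copy `theta`. Observed
#' arcs are carried by the lower-copy pairs (the non-wrapping arcs) and the
#' wrapping cross pairs, exactly n(n-1) slots; the n slots (k, k + n) have the
#' known length 2*pi (the circumference) and form their own fixed segment;
#' the remaining slots (upper-copy duplicates and the cross pairs longer than
#' the circumference) are labeled missing and simulated from the running
#' estimate during a sweep. Slot accounting: n(n-1) observed + n fixed +
#' 2 C(n,2) missing = n(2n-1), the complete slot count of a 2n-point
#' instance.
#'
#' @param arcs Sorted multiset of all n(n-1) directed arc lengths, in radians
#'   on the unit circle.
#' @param n Number of circle points.
#' @param circumference Known circumference (2*pi for the unit circle).
#' @return A [distance_partition()] over 2n lifted points.
#' @export
beltway_lift <- function(arcs, n, circumference = 2 * pi) {
  if (length(arcs) != n * (n - 1)) {
    stop("expected n(n-1) = ", n * (n - 1), " arcs, got ", length(arcs), call. = FALSE)
  }
  if (any(arcs < 0) || any(arcs > circumference + 1e-9)) {
    stop("arcs must lie in [0, circumference]", call. = FALSE)
  }
  distance_partition(2L * n, list(sort(arcs), rep(circumference, n)),
                     kind = "beltway", n0 = n)
}

#' Directed arc multiset of an angle vector
#'
#' @param theta Angles in radians.
#' @param circumference Circle circumference (2*pi for angles).
#' @return Sorted multiset of the n(n-1) directed arcs (theta_b - theta_a
#'   mod circumference over ordered pairs a != b).
#' @export
arcs_from_angles <- function(theta, circumference = 2 * pi) {
  d <- outer(theta, theta, "-")
  sort((d[row(d) != col(d)]) %% circumference)
}

#' Solve the Beltway problem by block MM on the lifted instance
#'
#' Rescales the input arcs to a unit circle, lifts them with
#' [beltway_lift()], and iterates the partitioned matching sweep without
#' unit-norm projection (the scale is pinned by the fixed circumference
#' slots); after each sweep the two copies of every point are replaced by
#' their coupling-consistent average and the smallest angle is re-anchored
#' at zero. Because the landscape is as multimodal as the linear problem's,
#' each random restart is refined by split-completion passes: the current
#' angles decide which input arc of every pair is non-wrapping, that split
#' determines the complete distance multiset of the lifted 2n-point line
#' configuration, [mmdq_solve()] solves that ordinary linear instance, and
#' the recovered angles re-estimate the split (with a random single-point
#' reseed whenever a pass fails to improve). The best candidate across
#' restarts, judged by the l2 residual between recovered and input arc
#' multisets, is returned.
#'
#' @param arcs Sorted multiset of n(n-1) directed arc lengths (any
#'   circumference; both arcs of every pair must be present).
#' @param n Number of circle points.
#' @param config A [solver_config()]; `config$seed` seeds the restarts.
#' @param restarts Number of random initial angle vectors.
#' @param passes Split-completion refinement passes per restart.
#' @param inner_starts Initializer candidates for each inner linear solve.
#' @return Sorted angle vector in \[0, 2*pi) with attributes `circumference`
#'   (the estimated input circumference) and `arc_residual` (l2 residual on
#'   the unit circle).
#' @export
beltway_solve <- function(arcs, n, config = solver_config(), restarts = 20L,
                          passes = 8L, inner_starts = 6L) {
  cfg <- as_solver_config(config)
  if (length(arcs) != n * (n - 1)) {
    stop("expected n(n-1) arcs", call. = FALSE)
  }
  # both directed arcs of a pair sum to the circumference
  circ_in <- 2 * sum(arcs) / (n * (n - 1))
  arcs_u <- sort(arcs) * (2 * pi) / circ_in
  part <- beltway_lift(arcs_u, n)
  labels <- partition_slot_labels(part)
  two_pi <- 2 * pi
  scale <- sqrt(sum(arcs_u^2))
  resid_of <- function(th) sqrt(sum((arcs_from_angles(th) - arcs_u)^2))
  split_of <- function(th) {
    z <- c(th - two_pi, th)
    res <- partitioned_match_apply(part, z)
    lab <- labels[interval_slot(res$matching$i, res$matching$j, 2L * n)]
    obs <- lab == 1L
    lower <- res$matching$j[obs] <= n
    list(nw = sort(res$d[obs][lower]), wr = sort(res$d[obs][!lower]))
  }
  theta_of <- function(zplus) {
    th <- (zplus[(n + 1):(2 * n)] + zplus[1:n] + two_pi) / 2
    th <- sort(th %% two_pi)
    th - th[1]
  }
  seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  best <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      th <- sort(stats::runif(n, 0, two_pi))
      th <- th - th[1]
      th <- beltway_iterate(part, th, n, cfg)$theta
      cur <- list(theta = th, resid = resid_of(th))
      for (pass in seq_len(passes)) {
        if (cur$resid < 1e-9 * scale) break
        sp <- split_of(th)
        Dp <- sort(c(sp$nw, sp$nw, sp$wr, rep(two_pi, n), two_pi + sp$nw))
        Dr <- rescale_distances(Dp, 2L * n)
        ifit <- NULL
        for (k in seq_len(inner_starts)) {
          z0 <- if (k == 1) greedy_init(Dr) else {
            greedy_init(Dr, seed = sample.int(.Machine$integer.max - 1L, 1L),
                        flip_prob = 0.2)
          }
          f <- mmdq_solve(Dr, z0, cfg)
          rs <- sqrt(sum((sort(apply_Q(f$z)) - Dr)^2))
          if (is.null(ifit) || rs < ifit$rs) ifit <- list(fit = f, rs = rs)
          if (rs < 1e-9) break
        }
        zplus <- ifit$fit$z * sqrt(sum(Dp^2)) / sqrt(2 * n)
        th_new <- beltway_iterate(part, theta_of(zplus), n, cfg)$theta
        rn <- resid_of(th_new)
        if (rn < cur$resid) {
          cur <- list(theta = th_new, resid = rn)
          th <- th_new
        } else {
          # single-point reseed at an arc-informed position
          th <- cur$theta
          th[sample.int(n, 1)] <- (th[sample.int(n, 1)] + sample(arcs_u, 1)) %% two_pi
          th <- sort(th %% two_pi)
          th <- th - th[1]
        }
      }
      if (is.null(best) || cur$resid < best$resid) best <- cur
      if (best$resid < 1e-9 * scale) break
    }
    best
  })
  structure(best$theta, circumference = circ_in, arc_residual = best$resid)
}

# One restart of the coupled block iteration on the lifted instance.
beltway_iterate <- function(part, theta, n, cfg) {
  two_pi <- 2 * pi
  gaps <- function(th) diff(c(th, th[1] + two_pi))
  iters <- 0L
  for (t in seq_len(cfg$max_iters)) {
    iters <- t
    z <- c(theta - two_pi, theta)
    zr <- partitioned_match_apply(part, z)$z / (2 * n)
    th_new <- (zr[(n + 1):(2 * n)] + zr[1:n] + two_pi) / 2
    th_new <- sort(th_new %% two_pi)
    th_new <- th_new - th_new[1]
    # rotation-invariant convergence check on the circular gap vector
    if (max(abs(sort(gaps(th_new)) - sort(gaps(theta)))) < cfg$tol &&
        max(abs(th_new - theta)) < sqrt(cfg$tol)) {
      theta <- th_new
      break
    }
    theta <- th_new
  }
  list(theta = theta, iterations = iters)
}

#' Optimal order-preserving l1 matching of one sorted multiset into another
#'
#' Finds the order-preserving injection of `E` into `D` (both sorted) that
#' minimizes the total absolute difference over matched pairs, by an
#' O(|D| |E|) dynamic program. The cost is zero exactly when `E` is a
#' sub-multiset of `D`.
#'
#' @param D Sorted host multiset.
#' @param E Sorted multiset to embed, `length(E) <= length(D)`.
#' @return List with `indices` (for each entry of `E`, the matched index into
#'   `D`, strictly increasing) and `cost` (total l1 discrepancy).
#' @export
#' @examples
#' l1_monotone_subtract(c(1, 2, 3), c(1, 2))    # cost 0
#' l1_monotone_subtract(c(1, 10), c(4, 6))      # forced monotone match, cost 7
l1_monotone_subtract <- function(D, E) {
  nd <- length(E)
  md <- length(D)
  if (nd > md) stop("|E| must not exceed |D|", call. = FALSE)
  if (is.unsorted(D) || is.unsorted(E)) stop("both multisets must be sorted", call. = FALSE)
  if (nd == 0) return(list(indices = integer(0), cost = 0))
  # cost[a+1, b+1]: best cost matching the first b of E into the first a of D;
  # took[a, b] records whether D[a] was matched to E[b] on the optimal path
  cost <- matrix(Inf, md + 1, nd + 1)
  cost[, 1] <- 0
  took <- matrix(FALSE, md, nd)
  for (a in seq_len(md)) {
    b <- seq_len(min(a, nd))
    skip <- cost[a, b + 1]
    take <- cost[a, b] + abs(D[a] - E[b])
    choose_take <- take <= skip
    cost[a + 1, b + 1] <- ifelse(choose_take, take, skip)
    took[a, b] <- choose_take
  }
  idx <- integer(nd)
  a <- md
  b <- nd
  while (b >= 1) {
    if (took[a, b]) {
      idx[b] <- a
      b <- b - 1
    }
    a <- a - 1
    if (a < b) stop("internal: matching backtrack failed")
  }
  list(indices = idx, cost = cost[md + 1, nd + 1])
}

#' Partition a labeled partial digest input
#'
#' A labeled partial digest supplies, along with the complete distance
#' multiset `D`, the 2(n-2) distances of the interior points to the two
#' molecule ends. The end distances are matched into `D` by the optimal
#' order-preserving l1 matching ([l1_monotone_subtract()]); the matched
#' entries are replaced by the labeled values on the endpoint-touching
#' interior slots ((1, j), j < n and (i, n), i > 1), and the remainder of `D`
#' (including the full span (1, n)) forms the unlabeled segment. In the
#' noiseless case the matching removes exact copies at zero cost.
#'
#' @param D Sorted complete distance multiset for n points.
#' @param E Sorted endpoint distance multiset, length 2(n-2).
#' @return A [distance_partition()] of kind `"lpdp"` (segment 1 = `E`,
#'   segment 2 = the unmatched remainder of `D`).
#' @export
lpdp_prepare <- function(D, E) {
  check_distances(D)
  n <- n_from_m(length(D))
  if (length(E) != 2 * (n - 2)) {
    stop("expected |E| = 2(n-2) = ", 2 * (n - 2), ", got ", length(E), call. = FALSE)
  }
  E <- sort(E)
  matched <- l1_monotone_subtract(D, E)
  interior <- sort(D[-matched$indices])
  distance_partition(n, list(E, interior), kind = "lpdp")
}

#' Partition a simplified partial digest input
#'
#' A simplified partial digest supplies only the n-1 adjacent distances `A`
#' and the endpoint multiset `E` (which shares the two extreme adjacencies
#' with `A`). The two overlapping values are removed from `E` by picking the
#' pair of `A` entries whose l1-optimal monotone match into `E` is cheapest;
#' `A` is kept in full on the adjacency slots, the trimmed `E` goes on the
#' endpoint non-adjacent slots, and every interior slot is labeled missing
#' (simulated from the iterate during solving).
#'
#' @param A Sorted adjacent-distance multiset, length n-1.
#' @param E Sorted endpoint multiset, length 2(n-2).
#' @param n Point count.
#' @return A [distance_partition()] of kind `"spdp"` (segment 1 = `A`,
#'   segment 2 = trimmed `E`).
#' @export
spdp_prepare <- function(A, E, n) {
  if (length(A) != n - 1) {
    stop("expected |A| = n-1 = ", n - 1, ", got ", length(A), call. = FALSE)
  }
  if (n >= 3 && length(E) != 2 * (n - 2)) {
    stop("expected |E| = 2(n-2) = ", 2 * (n - 2), ", got ", length(E), call. = FALSE)
  }
  A <- sort(A)
  E <- sort(E)
  if (n <= 2) {
    return(distance_partition(n, list(A, numeric(0)), kind = "spdp"))
  }
  if (n == 3) {
    # E holds exactly the two extreme adjacencies; nothing else remains
    return(distance_partition(n, list(A, numeric(0)), kind = "spdp"))
  }
  # choose the two A entries that E duplicates (the extreme adjacencies)
  best <- NULL
  for (p in seq_len(length(A) - 1)) {
    for (q in (p + 1):length(A)) {
      mt <- l1_monotone_subtract(E, c(A[p], A[q]))
      if (is.null(best) || mt$cost < best$cost) {
        best <- list(cost = mt$cost, drop = mt$indices)
      }
    }
  }
  E_trim <- sort(E[-best$drop])
  distance_partition(n, list(A, E_trim), kind = "spdp")
}
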