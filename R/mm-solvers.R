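# Alternating minorization-maximization solvers. Each iteration matches the
# sorted distances to the intervals of the current iterate (closed-form
# permutation step, by the rearrangement inequality) and then takes the
# closed-form point update z <- Q^T P D, normalized on return. The bilinear
# objective <Qz, PD> is nondecreasing across iterations and the loop
# terminates finitely because a matching fully determines the next iterate.

#' Solver configuration
#'
#' @param tol Convergence threshold on the Euclidean distance between
#'   consecutive unit-normalized iterates.
#' @param max_iters Cap on inner MM iterations.
#' @param max_outer Cap on outer divide-and-conquer passes ([mmdq_solve()]).
#' @param max_depth Recursion depth cap for [mmdq_solve()]; `NULL` means
#'   ceiling(log2(n)) at call time.
#' @param min_subset Smallest half size that is still refined recursively.
#' @param seed Optional integer seed for solver-internal randomness.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(tol = 1e-10, max_iters = 500L, max_outer = 10L,
                          max_depth = NULL, min_subset = 4L, seed = NULL) {
  stopifnot(tol > 0, max_iters >= 1, max_outer >= 1, min_subset >= 3)
  if (!is.null(max_depth)) stopifnot(max_depth >= 0)
  structure(list(tol = tol, max_iters = as.integer(max_iters),
                 max_outer = as.integer(max_outer),
                 max_depth = if (is.null(max_depth)) NULL else as.integer(max_depth),
                 min_subset = as.integer(min_subset), seed = seed),
            class = "solver_config")
}

as_solver_config <- function(cfg) {
  if (is.null(cfg)) return(solver_config())
  if (inherits(cfg, "solver_config")) return(cfg)
  do.call(solver_config, cfg)
}

new_turnpike_fit <- function(z, matching, objective, iterations, converged,
                             method, trace) {
  structure(list(z = z, matching = matching, objective = objective,
                 iterations = iterations, converged = converged,
                 method = method, objective_trace = trace),
            class = "turnpike_fit")
}

#' @export
print.turnpike_fit <- function(x, ...) {
  cat("<turnpike_fit> method =", x$method, " n =", length(x$z), "\n")
  cat("  objective:", format(x$objective), " iterations:", x$iterations,
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}

# Shared iteration driver. `sweep` maps a sorted unit iterate to
# list(z = accumulated vector, matching, d = matched values, obs = logical
# mask of observed pops). Objectives are evaluated on the unit iterate and
# restricted to observed slots.
run_mm_loop <- function(sweep, z0, cfg, method) {
  if (is.unsorted(z0)) stop("z0 must be sorted", call. = FALSE)
  z_cur <- unit(center(z0))
  trace <- numeric(cfg$max_iters)
  converged <- FALSE
  iters <- 0L
  stagnant <- 0L
  for (t in seq_len(cfg$max_iters)) {
    res <- sweep(z_cur)
    iters <- t
    trace[t] <- sum(res$d[res$obs] *
                      (z_cur[res$matching$j[res$obs]] - z_cur[res$matching$i[res$obs]]))
    z_new <- unit(sort(res$z))
    if (sqrt(sum((z_new - z_cur)^2)) < cfg$tol) {
      z_cur <- z_new
      converged <- TRUE
      break
    }
    # the objective is nondecreasing over a finite state set, so a flat
    # objective means the iteration is cycling among equally good matchings
    if (t > 1 && trace[t] - trace[t - 1] <= 1e-14 * max(1, abs(trace[t]))) {
      stagnant <- stagnant + 1L
      if (stagnant >= 3L) {
        z_cur <- z_new
        converged <- TRUE
        break
      }
    } else {
      stagnant <- 0L
    }
    z_cur <- z_new
  }
  trace <- trace[seq_len(iters)]
  # final matching/objective consistent with the returned point vector
  res <- sweep(z_cur)
  obj <- sum(res$d[res$obs] *
               (z_cur[res$matching$j[res$obs]] - z_cur[res$matching$i[res$obs]]))
  new_turnpike_fit(z_cur, res$matching, obj, iters, converged, method, trace)
}

#' Alternating MM solver for the noisy Turnpike problem
#'
#' Iterates `z(t+1) = Q^T P_t D`, where `P_t` assigns the sorted distances to
#' the intervals of `z(t)` in increasing length order, until consecutive
#' unit-normalized iterates move less than `tol` or `max_iters` is reached.
#' The matching objective is nondecreasing across iterations and the returned
#' point configuration is sorted, centered, and unit-norm.
#'
#' @param D Sorted complete distance multiset.
#' @param z0 Sorted initial point configuration (see [gaussian_init()],
#'   [greedy_init()], [permutation_init()]).
#' @param config A [solver_config()] (or list of its arguments).
#' @return A `turnpike_fit` with elements `z`, `matching`, `objective`,
#'   `iterations`, `converged`, and the per-iteration `objective_trace`.
#' @export
#' @examples
#' D <- rescale_distances(c(1, 2, 3), 3)
#' fit <- mm_solve(D, gaussian_init(3, seed = 1))
#' fit$z * sqrt(42) # recovers (-4, -1, 5)
mm_solve <- function(D, z0, config = solver_config()) {
  cfg <- as_solver_config(config)
  check_distances(D)
  n <- n_from_m(length(D))
  if (length(z0) != n) stop("z0 has length ", length(z0), ", expected ", n, call. = FALSE)
  m <- length(D)
  Dn <- as.numeric(D)
  obs_all <- rep.int(TRUE, m)
  sweep <- function(z) {
    r <- cpp_match_apply(z, Dn) # pre-validated; hot loop skips the checks
    list(z = r$z, matching = list(i = r$i, j = r$j), d = Dn, obs = obs_all)
  }
  run_mm_loop(sweep, z0, cfg, "mm")
}

#' Split matched distances at a point-index boundary
#'
#' Routes each distance to the left block (both matched endpoints at or below
#' `split`), the right block (both above), or the cross block, according to
#' the matching. Block sizes are C(split, 2), C(n - split, 2), and
#' split * (n - split).
#'
#' @param D Sorted distance multiset aligned with `matching` (row t of the
#'   matching received `D[t]`).
#' @param matching Matching from a solver or [sorted_match_apply()].
#' @param split Boundary index, 1 <= split < n.
#' @return List with sorted numeric vectors `ll`, `rr`, `lr`.
#' @export
segment_distances <- function(D, matching, split) {
  stopifnot(length(D) == length(matching$i), split >= 1)
  left <- matching$j <= split
  right <- matching$i > split
  list(ll = sort(D[left]), rr = sort(D[right]), lr = sort(D[!left & !right]))
}

# Matrix-free conjugate gradient for the normal equations Q^T Q x = b on the
# centered subspace (Q^T Q = n I - 1 1^T, so the operator is x -> n x on
# centered vectors; CG is retained as the generic path and cross-checked
# against the closed form in the tests).
cg_solve_qtq <- function(b, n, tol = 1e-12, max_iters = 200L) {
  b <- center(b)
  x <- numeric(n)
  r <- b
  p <- r
  rs <- sum(r^2)
  for (it in seq_len(max_iters)) {
    if (sqrt(rs) < tol) break
    Ap <- n * p - sum(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  center(x)
}

#' Least-squares refit of a point subset from its internal distances
#'
#' Solves `argmin_z || Q_l z - P_l D_ll ||` over centered `z`, where the
#' matching `P_l` is produced by a recursive divide-and-conquer run on the
#' subset. Because the subset's distance set is complete, the normal
#' equations collapse to the closed form `z = Q^T (P_l D_ll) / n_l` on
#' centered vectors; a matrix-free conjugate-gradient path is available and
#' agrees to high precision.
#'
#' @param D_sub Sorted complete distance multiset of the subset.
#' @param z_sub Sorted current estimate for the subset (any scale).
#' @param config A [solver_config()].
#' @param method `"closed_form"` (default) or `"cg"`.
#' @return Centered, sorted refit of the subset at the scale of `D_sub`.
#' @export
refit_subset <- function(D_sub, z_sub, config = solver_config(),
                         method = c("closed_form", "cg")) {
  method <- match.arg(method)
  n_l <- length(z_sub)
  if (n_l < 2) return(z_sub)
  cfg <- as_solver_config(config)
  fit <- mmdq_rec(sort(D_sub), z_sub, cfg, depth = 0L)
  matched_accum <- sorted_match_apply(sort(D_sub), fit$z)$z
  if (method == "closed_form") {
    sort(center(matched_accum / n_l))
  } else {
    sort(cg_solve_qtq(matched_accum, n_l))
  }
}

# Core recursion shared by mmdq_solve and refit_subset. Depth counts levels
# below the top-level call; recursion stops below min_subset or past
# max_depth, where a plain MM pass supplies the matching.
mmdq_rec <- function(D, z0, cfg, depth) {
  n <- length(z0)
  fit <- mm_solve(D, z0, cfg)
  max_depth <- if (is.null(cfg$max_depth)) ceiling(log2(max(n, 2))) else cfg$max_depth
  if (n < cfg$min_subset || depth >= max_depth) return(fit)
  best <- fit
  for (pass in seq_len(cfg$max_outer)) {
    z_cur <- fit$z
    cand <- mmdq_consensus(D, z_cur, fit$matching, cfg, depth)
    fit_new <- mm_solve(D, cand, cfg)
    if (fit_new$objective > best$objective) best <- fit_new
    delta <- sqrt(sum((fit_new$z - z_cur)^2))
    fit <- fit_new
    if (delta < cfg$tol) break
  }
  new_turnpike_fit(best$z, best$matching, best$objective,
                   best$iterations, best$converged, "mmdq", best$objective_trace)
}

# Build the divide-and-conquer consensus candidate: split at the median
# position, re-solve each half on its own distance block, refit each half by
# least squares, re-anchor the halves at the data scale, and merge.
mmdq_consensus <- function(D, z_cur, matching, cfg, depth) {
  n <- length(z_cur)
  split <- ceiling(n / 2)
  segs <- segment_distances(D, matching, split)
  # current iterate at the scale of D, so half offsets are commensurate
  z_data <- z_cur * sqrt(sum(D^2)) / sqrt(n)
  left_idx <- seq_len(split)
  right_idx <- (split + 1):n
  refit_half <- function(D_half, idx) {
    z_half <- z_data[idx]
    n_h <- length(idx)
    if (n_h < 2 || length(D_half) == 0) return(z_half)
    sub <- mmdq_rec(D_half, sort(unit(center(z_half))), cfg, depth + 1L)
    accum <- sorted_match_apply(D_half, sub$z)$z
    sort(center(accum / n_h)) + mean(z_half)
  }
  zl <- refit_half(segs$ll, left_idx)
  zr <- refit_half(segs$rr, right_idx)
  unit(center(sort(c(zl, zr))))
}

#' Divide-and-conquer MM solver
#'
#' Wraps [mm_solve()] in an outer loop that recursively re-solves and refits
#' the left and right halves of the current estimate on their own distance
#' blocks, then re-merges them into a consensus iterate. The recursion acts
#' as a self-correcting mechanism: a half that was trapped in a local
#' maximum of the full problem is unlikely to be trapped in the same one when
#' solved in isolation. The best candidate seen across passes is returned,
#' so the result is never worse than plain [mm_solve()] from the same start.
#'
#' @inheritParams mm_solve
#' @return A `turnpike_fit` (method `"mmdq"`).
#' @export
mmdq_solve <- function(D, z0, config = solver_config()) {
  cfg <- as_solver_config(config)
  check_distances(D)
  n <- n_from_m(length(D))
  if (length(z0) != n) stop("z0 has length ", length(z0), ", expected ", n, call. = FALSE)
  fit <- mmdq_rec(D, z0, cfg, depth = 0L)
  fit$method <- "mmdq"
  fit
}

#' Block-descent MM solver for partitioned distance multisets
#'
#' Runs the MM iteration on a [distance_partition()]: every observed segment
#' is matched to its own slots in parallel (each by the sorting closed form)
#' and slots labeled missing are filled with the simulated distance from the
#' current iterate before the point update. With the trivial partition the
#' iterates are identical to [mm_solve()]. The reported objective is
#' restricted to observed slots.
#'
#' @param partition A [distance_partition()].
#' @param z0 Sorted initial point configuration of length `partition$n`.
#' @param config A [solver_config()].
#' @return A `turnpike_fit` (method `"block"`).
#' @export
block_mm_solve <- function(partition, z0, config = solver_config()) {
  cfg <- as_solver_config(config)
  stopifnot(inherits(partition, "distance_partition"))
  if (length(z0) != partition$n) {
    stop("z0 has length ", length(z0), ", expected ", partition$n, call. = FALSE)
  }
  labels <- partition_slot_labels(partition)
  n <- partition$n
  kind_code <- match(partition$kind, c("custom", "trivial", "lpdp", "spdp", "beltway")) - 1L
  segs <- lapply(partition$segments, as.numeric)
  cl <- if (is.null(partition$labels)) integer(0) else partition$labels
  sweep <- function(z) {
    r <- cpp_partition_match_apply(z, segs, kind_code, partition$n0, cl)
    obs <- labels[interval_slot(r$i, r$j, n)] > 0L
    list(z = r$z, matching = list(i = r$i, j = r$j), d = r$d, obs = obs)
  }
  run_mm_loop(sweep, z0, cfg, "block")
}
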