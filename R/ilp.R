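# Globally optimal reconstruction for small instances. The sorted matching
# is encoded exactly in a mixed-integer model: per observed segment, binary
# assignment variables link interval slots to sorted positions, big-M rows
# force the matched sorted value y_t to equal the slot length z[j] - z[i],
# and the convex scoring of the residuals r = D - y is driven to optimality
# through an epigraph variable tightened by lazy separation cuts. The scale
# is pinned by requiring the matched lengths to sum to the distances (no
# unit-norm constraint; the point variables are free rationals).

#' Objective specification for the exact solver
#'
#' Three support-function objectives over the residuals r = D - sort(Qz):
#' `"mm_support"` scores the pooled Euclidean norm of the residuals (the
#' convex counterpart of the matching objective, separated by the sorting
#' sweep); `"rel_linf"` scores the worst residual relative to its distance
#' (each residual inversely weighted by the input distance, after the
#' relative-error measurement model); `"part_linf"` scores the worst
#' additivity violation |d_st - d_sk - d_kt| over point triples of the
#' assigned distances (a line of points makes every distance the sum of its
#' parts).
#'
#' @param kind One of `"mm_support"`, `"rel_linf"`, `"part_linf"`.
#' @param weights Optional strictly positive per-rank weights overriding the
#'   defaults (only meaningful for the linf kinds).
#' @return A list of class `exact_objective`.
#' @export
exact_objective <- function(kind = c("mm_support", "rel_linf", "part_linf"),
                            weights = NULL) {
  kind <- match.arg(kind)
  if (!is.null(weights) && any(weights <= 0)) {
    stop("weights must be strictly positive", call. = FALSE)
  }
  structure(list(kind = kind, weights = weights), class = "exact_objective")
}

# ---- MILP backend (scipy/HiGHS via the bundled helper script) --------------

milp_python <- function() {
  py <- Sys.getenv("TURNPIKE_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) stop("no python interpreter found for the MILP backend", call. = FALSE)
  py
}

# problems: list of lists(c, integrality, lb, ub, rows = list(i, j, x),
# row_lb, row_ub, time_limit). Returns list of list(status, success, x, fun).
milp_solve_batch <- function(problems) {
  script <- system.file("python", "milp_solve.py", package = "turnpike")
  stopifnot(nzchar(script))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(list(problems = problems), fin,
                       auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(milp_python(), c(script, fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("MILP backend failed: ", paste(status, collapse = "\n"), call. = FALSE)
  }
  jsonlite::fromJSON(fout, simplifyVector = FALSE)$solutions
}

# ---- model construction -----------------------------------------------------

new_row_set <- function() {
  env <- new.env(parent = emptyenv())
  env$i <- list(); env$j <- list(); env$x <- list()
  env$lb <- list(); env$ub <- list(); env$nrow <- 0L
  env
}

add_row <- function(rows, cols, vals, lb, ub) {
  rows$nrow <- rows$nrow + 1L
  k <- rows$nrow
  rows$i[[k]] <- rep.int(rows$nrow, length(cols))
  rows$j[[k]] <- as.integer(cols)
  rows$x[[k]] <- as.numeric(vals)
  rows$lb[[k]] <- lb
  rows$ub[[k]] <- ub
  invisible(rows)
}

rows_as_list <- function(rows) {
  list(i = unlist(rows$i), j = unlist(rows$j), x = unlist(rows$x),
       lb = unlist(rows$lb), ub = unlist(rows$ub), nrow = rows$nrow)
}

#' Build the exact mixed-integer model for a partitioned instance
#'
#' Continuous point variables are ordered and centered; each observed
#' segment gets sorted-value variables y and a binary assignment matrix
#' linking its slots to its sorted positions through big-M rows (slots whose
#' distance is missing impose nothing; their simulated residual is zero by
#' construction). The epigraph variable t bounds the support-function score
#' of the residuals and is tightened by rows from [separation_cut()].
#'
#' @param partition A [distance_partition()].
#' @param objective An [exact_objective()].
#' @param n_limit Refuse instances with more points than this (the binary
#'   count grows quadratically in the segment sizes).
#' @param big_m Big-M bound; defaults to twice the largest observed distance.
#' @return A list of class `exact_model` (variable maps, triplet rows,
#'   bounds, metadata).
#' @export
build_exact_model <- function(partition, objective = exact_objective(),
                              n_limit = 15L, big_m = NULL) {
  stopifnot(inherits(partition, "distance_partition"),
            inherits(objective, "exact_objective"))
  n <- partition$n
  if (n > n_limit) {
    stop("exact model refused: n = ", n, " exceeds the limit ", n_limit,
         " (the assignment model needs O(m^2) binaries); raise n_limit ",
         "deliberately if you accept the cost", call. = FALSE)
  }
  labels <- partition_slot_labels(partition)
  if (objective$kind == "part_linf" && any(labels == 0L)) {
    stop("part_linf scoring needs every slot observed (no missing distances)",
         call. = FALSE)
  }
  sp <- slot_pairs(n)
  segs <- lapply(partition$segments, sort)
  nseg <- length(segs)
  seg_slots <- lapply(seq_len(nseg), function(p) which(labels == p))
  D_all <- unlist(segs)
  if (objective$kind == "rel_linf" && any(D_all <= 0)) {
    stop("rel_linf weights are 1/distance; zero distances are not scoreable",
         call. = FALSE)
  }
  M <- if (is.null(big_m)) 2 * max(D_all, 1e-12) else big_m

  # variable layout: z (n) | y blocks | X blocks (segments with >= 2 slots) | t
  idx_z <- seq_len(n)
  nv <- n
  idx_y <- vector("list", nseg)
  for (p in seq_len(nseg)) {
    mj <- length(segs[[p]])
    idx_y[[p]] <- if (mj > 0) nv + seq_len(mj) else integer(0)
    nv <- nv + mj
  }
  idx_X <- vector("list", nseg)
  for (p in seq_len(nseg)) {
    mj <- length(segs[[p]])
    if (mj >= 2) {
      idx_X[[p]] <- matrix(nv + seq_len(mj * mj), mj, mj) # [slot, rank]
      nv <- nv + mj * mj
    }
  }
  idx_t <- nv + 1L
  nv <- nv + 1L

  lb <- rep(-M, nv); ub <- rep(M, nv)
  integrality <- rep(0L, nv)
  for (p in seq_len(nseg)) {
    lb[idx_y[[p]]] <- 0
    if (!is.null(idx_X[[p]])) {
      lb[idx_X[[p]]] <- 0; ub[idx_X[[p]]] <- 1
      integrality[idx_X[[p]]] <- 1L
    }
  }
  lb[idx_t] <- 0; ub[idx_t] <- 1e30
  cvec <- numeric(nv); cvec[idx_t] <- 1

  rows <- new_row_set()
  add_row(rows, idx_z, rep(1, n), 0, 0)                       # centered
  for (k in seq_len(n - 1)) {                                  # ordered
    add_row(rows, idx_z[c(k, k + 1)], c(1, -1), -1e30, 0)
  }
  if (n >= 3) {                                                # mirror break
    add_row(rows, idx_z[c(1, 2, n - 1, n)], c(1, -1, 1, -1), -1e30, 0)
  }
  add_row(rows, idx_z[c(1, n)], c(-1, 1), -1e30, M)            # spread cap
  y_all <- unlist(idx_y)
  add_row(rows, y_all, rep(1, length(y_all)), sum(D_all), sum(D_all)) # pin

  for (p in seq_len(nseg)) {
    mj <- length(segs[[p]])
    if (mj == 0) next
    slots <- seg_slots[[p]]
    if (mj == 1) {
      s <- slots[1]
      add_row(rows, c(idx_y[[p]][1], idx_z[sp$j[s]], idx_z[sp$i[s]]),
              c(1, -1, 1), 0, 0)
      next
    }
    X <- idx_X[[p]]
    for (s in seq_len(mj)) add_row(rows, X[s, ], rep(1, mj), 1, 1)
    for (t in seq_len(mj)) add_row(rows, X[, t], rep(1, mj), 1, 1)
    for (t in seq_len(mj - 1)) {                               # y sorted
      add_row(rows, idx_y[[p]][c(t, t + 1)], c(1, -1), -1e30, 0)
    }
    for (s in seq_len(mj)) {
      zi <- idx_z[sp$i[slots[s]]]; zj <- idx_z[sp$j[slots[s]]]
      for (t in seq_len(mj)) {
        # |y_t - (z_j - z_i)| <= M (1 - X[s, t])
        add_row(rows, c(idx_y[[p]][t], zj, zi, X[s, t]), c(1, -1, 1, M), -1e30, M)
        add_row(rows, c(idx_y[[p]][t], zj, zi, X[s, t]), c(-1, 1, -1, M), -1e30, M)
      }
    }
  }

  # upfront epigraph rows: t bounds every single weighted residual
  if (objective$kind %in% c("mm_support", "rel_linf")) {
    for (p in seq_len(nseg)) {
      Dp <- segs[[p]]
      for (t in seq_along(Dp)) {
        w <- if (objective$kind == "rel_linf") {
          if (is.null(objective$weights)) Dp[t] else objective$weights[t]
        } else 1
        yv <- idx_y[[p]][t]
        add_row(rows, c(yv, idx_t), c(-1 / w, -1), -1e30, -Dp[t] / w)
        add_row(rows, c(yv, idx_t), c(1 / w, -1), -1e30, Dp[t] / w)
      }
    }
  }

  structure(list(partition = partition, objective = objective, n = n,
                 sp = sp, segments = segs, seg_slots = seg_slots,
                 idx = list(z = idx_z, y = idx_y, X = idx_X, t = idx_t),
                 nvar = nv, c = cvec, integrality = integrality,
                 lb = lb, ub = ub, rows = rows, big_m = M),
            class = "exact_model")
}

#' @export
print.exact_model <- function(x, ...) {
  nbin <- sum(x$integrality == 1)
  cat("<exact_model> n =", x$n, " vars =", x$nvar, "(", nbin, "binary )",
      " rows =", x$rows$nrow, " objective =", x$objective$kind, "\n")
  invisible(x)
}

# ---- incumbent bookkeeping --------------------------------------------------

# Evaluate the support-function score of an incumbent. `residuals` is a list
# of per-segment rank-wise residual vectors D - y; `assigned` is the n x n
# matrix of assigned distances by slot (needed for part_linf only).
sigma_eval <- function(objective, residuals, assigned = NULL,
                       segments = NULL) {
  r <- unlist(residuals)
  switch(objective$kind,
    mm_support = sqrt(sum(r^2)),
    rel_linf = {
      w <- unlist(lapply(seq_along(segments), function(p) {
        if (is.null(objective$weights)) segments[[p]] else objective$weights
      }))
      if (length(r) == 0) 0 else max(abs(r) / w)
    },
    part_linf = part_linf_sigma(assigned)$value
  )
}

part_linf_sigma <- function(dmat) {
  n <- nrow(dmat)
  best <- 0; triple <- NULL
  for (s in seq_len(n - 2)) {
    for (t in (s + 2):n) {
      for (k in (s + 1):(t - 1)) {
        v <- abs(dmat[s, t] - dmat[s, k] - dmat[k, t])
        if (v > best) { best <- v; triple <- c(s, k, t) }
      }
    }
  }
  list(value = best, triple = triple)
}

#' Separation oracle for the exact solver
#'
#' Given an incumbent's residuals (and, for `part_linf`, its assigned
#' distances), either certifies that the epigraph value already dominates
#' the support-function score or returns a violated cut: the normalized
#' residual direction for `mm_support` (t >= <x, r> for the maximizing unit
#' vector x), the worst weighted residual for `rel_linf`, or the worst
#' additivity triple for `part_linf` (conditioned on the three assignment
#' binaries that produced it).
#'
#' @param objective An [exact_objective()].
#' @param residuals List of per-segment rank-wise residuals `D - y`.
#' @param t_value Incumbent epigraph value.
#' @param assigned Matrix of assigned distances by slot pair (for
#'   `part_linf`).
#' @param segments Sorted per-segment distances (weights for `rel_linf`).
#' @param tol Violation tolerance.
#' @return `NULL` when no violated cut exists, else a cut description.
#' @export
separation_cut <- function(objective, residuals, t_value, assigned = NULL,
                           segments = NULL, tol = 1e-9) {
  sig <- sigma_eval(objective, residuals, assigned, segments)
  if (t_value >= sig - tol) return(NULL)
  switch(objective$kind,
    mm_support = {
      r <- unlist(residuals)
      list(kind = "support", x = relist_like(r / sqrt(sum(r^2)), residuals),
           value = sig)
    },
    rel_linf = {
      worst <- NULL
      for (p in seq_along(residuals)) {
        w <- if (is.null(objective$weights)) segments[[p]] else objective$weights
        if (length(residuals[[p]]) == 0) next
        sc <- abs(residuals[[p]]) / w
        t_star <- which.max(sc)
        if (is.null(worst) || sc[t_star] > worst$score) {
          worst <- list(score = sc[t_star], segment = p, rank = t_star,
                        sign = sign(residuals[[p]][t_star]), weight = w[t_star])
        }
      }
      c(list(kind = "ratio", value = sig), worst)
    },
    part_linf = {
      tr <- part_linf_sigma(assigned)
      list(kind = "triple", value = tr$value, triple = tr$triple)
    }
  )
}

relist_like <- function(flat, template) {
  out <- template
  pos <- 0L
  for (p in seq_along(template)) {
    len <- length(template[[p]])
    out[[p]] <- flat[pos + seq_len(len)]
    pos <- pos + len
  }
  out
}

# Append a cut (from separation_cut) as a model row.
apply_cut <- function(model, cut, assignment = NULL) {
  idx <- model$idx
  if (cut$kind == "support") {
    cols <- c(unlist(idx$y), idx$t)
    xs <- unlist(cut$x)
    dvals <- unlist(model$segments)
    add_row(model$rows, cols, c(-xs, -1), -1e30, -sum(xs * dvals))
  } else if (cut$kind == "ratio") {
    yv <- idx$y[[cut$segment]][cut$rank]
    dv <- model$segments[[cut$segment]][cut$rank]
    s <- if (cut$sign >= 0) 1 else -1
    # t >= s (D - y) / w
    add_row(model$rows, c(yv, idx$t), c(s / cut$weight, -1), -1e30,
            s * dv / cut$weight)
  } else if (cut$kind == "triple") {
    stopifnot(!is.null(assignment))
    tri <- cut$triple
    pairs <- rbind(c(tri[1], tri[3]), c(tri[1], tri[2]), c(tri[2], tri[3]))
    xvars <- apply(pairs, 1, function(ij) {
      s <- interval_slot(ij[1], ij[2], model$n)
      assignment_binary(model, assignment, s)
    })
    v <- cut$value
    add_row(model$rows, c(xvars, idx$t), c(v, v, v, -1), -1e30, 2 * v)
  }
  invisible(model)
}

# The X variable currently active for a width-major slot, per an incumbent
# assignment (list per segment: rank index per slot position).
assignment_binary <- function(model, assignment, slot) {
  for (p in seq_along(model$seg_slots)) {
    pos <- match(slot, model$seg_slots[[p]])
    if (!is.na(pos)) {
      X <- model$idx$X[[p]]
      if (is.null(X)) stop("slot ", slot, " belongs to a singleton segment")
      return(X[pos, assignment[[p]][pos]])
    }
  }
  stop("slot ", slot, " is not observed")
}

# ---- incumbent extraction ---------------------------------------------------

extract_incumbent <- function(model, x) {
  idx <- model$idx
  z <- x[idx$z]
  nseg <- length(model$segments)
  y <- lapply(seq_len(nseg), function(p) x[idx$y[[p]]])
  assignment <- vector("list", nseg)
  for (p in seq_len(nseg)) {
    mj <- length(model$segments[[p]])
    if (mj == 0) {
      assignment[[p]] <- integer(0)
    } else if (mj == 1) {
      assignment[[p]] <- 1L
    } else {
      Xv <- matrix(x[idx$X[[p]]], mj, mj)
      assignment[[p]] <- apply(Xv, 1, which.max)
    }
  }
  residuals <- lapply(seq_len(nseg), function(p) model$segments[[p]] - y[[p]])
  dmat <- matrix(NA_real_, model$n, model$n)
  for (p in seq_len(nseg)) {
    slots <- model$seg_slots[[p]]
    for (s in seq_along(slots)) {
      ii <- model$sp$i[slots[s]]; jj <- model$sp$j[slots[s]]
      dmat[ii, jj] <- model$segments[[p]][assignment[[p]][s]]
    }
  }
  list(z = z, y = y, assignment = assignment, residuals = residuals,
       assigned = dmat, t = x[idx$t])
}

# Does a point vector realize an assignment? True when, within every
# segment, the slot lengths of z are ordered consistently with the ranks the
# assignment gives them (so y = sort(Q z) reproduces the assigned values'
# positions and z is feasible for the exact model).
assignment_consistent <- function(model, assignment, z) {
  if (is.unsorted(z)) return(FALSE)
  lens <- apply_Q(z)
  for (p in seq_along(model$seg_slots)) {
    sl <- model$seg_slots[[p]]
    if (length(sl) < 2) next
    ord <- order(assignment[[p]])
    if (is.unsorted(lens[sl][ord])) return(FALSE)
  }
  TRUE
}

# Per-assignment least-squares lower bound (mm_support): with the assignment
# fixed, minimize ||d_assigned - Bz|| over centered z under the scale pin,
# ignoring the ordering constraints (hence a valid lower bound). Dense KKT
# solve; n is small here by construction.
assignment_sigma_lb <- function(model, inc) {
  n <- model$n
  slots <- unlist(model$seg_slots)
  if (length(slots) == 0) return(list(sigma = 0, z = numeric(n)))
  dvals <- unlist(lapply(seq_along(model$segments), function(p) {
    model$segments[[p]][inc$assignment[[p]]]
  }))
  B <- matrix(0, length(slots), n)
  for (s in seq_along(slots)) {
    B[s, model$sp$i[slots[s]]] <- -1
    B[s, model$sp$j[slots[s]]] <- 1
  }
  a <- colSums(B)
  C <- rbind(rep(1, n), a)
  b <- c(0, sum(unlist(model$segments)))
  kkt <- rbind(cbind(2 * crossprod(B), t(C)), cbind(C, matrix(0, 2, 2)))
  rhs <- c(2 * crossprod(B, dvals), b)
  sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
  if (is.null(sol)) return(list(sigma = 0, z = numeric(n)))
  z <- sol[seq_len(n)]
  list(sigma = sqrt(max(sum((dvals - B %*% z)^2), 0)), z = z)
}

# ---- the exact solver -------------------------------------------------------

#' Globally optimal reconstruction by MILP with lazy cuts
#'
#' Builds the exact model, warm-starts the epigraph with a cut derived from
#' an alternating-solver solution, and iterates: solve the MILP, score the
#' incumbent's residuals with the support function, and either certify
#' optimality (the epigraph lower bound meets the best feasible score) or
#' add the violated separation cut and re-solve. On proven optimality the
#' returned objective is no larger than that of any alternating-solver
#' solution of the same instance under the same scoring; noiseless
#' instances reach objective zero and exact recovery up to mirror image.
#'
#' @param partition A [distance_partition()] (use [trivial_partition()] for a
#'   plain instance).
#' @param objective An [exact_objective()].
#' @param time_limit Seconds allowed per MILP call.
#' @param max_cuts Cap on cut-loop iterations.
#' @param tol Optimality gap tolerance on the support-function value.
#' @param n_limit Passed to [build_exact_model()].
#' @return List of class `turnpike_exact`: `z` (sorted points at data
#'   scale), `objective` (best support-function value), `optimal` (logical:
#'   proven within `tol`), `gap`, `solves` (MILP calls), `assigned`
#'   (matrix of assigned distances).
#' @export
solve_exact <- function(partition, objective = exact_objective(),
                        time_limit = 60, max_cuts = 50L, tol = 1e-7,
                        n_limit = 15L) {
  model <- build_exact_model(partition, objective, n_limit = n_limit)
  warm <- exact_warm_start(model)
  best <- list(sigma = warm$sigma, z = warm$z, assigned = warm$assigned)
  if (!is.null(warm$cut)) apply_cut(model, warm$cut, warm$assignment)
  lower <- 0
  solves <- 0L
  # a zero-score incumbent is already certified (the score is nonnegative)
  while (best$sigma - lower > tol && solves < max_cuts) {
    prob <- list(c = model$c, integrality = model$integrality,
                 lb = model$lb, ub = model$ub,
                 rows = rows_as_list(model$rows)[c("i", "j", "x")],
                 row_lb = rows_as_list(model$rows)$lb,
                 row_ub = rows_as_list(model$rows)$ub,
                 time_limit = time_limit)
    sol <- milp_solve_batch(list(prob))[[1]]
    solves <- solves + 1L
    if (!isTRUE(sol$success) || is.null(sol$x)) break
    x <- unlist(sol$x)
    lower <- max(lower, sol$fun)
    inc <- extract_incumbent(model, x)
    sig <- sigma_eval(objective, inc$residuals, inc$assigned, model$segments)
    if (sig < best$sigma) best <- list(sigma = sig, z = inc$z, assigned = inc$assigned)
    if (objective$kind == "mm_support") {
      ref <- assignment_sigma_lb(model, inc)
      # the closed-form refit of the incumbent assignment is ILP-feasible
      # whenever it is sorted and its slot lengths honor the rank order
      if (ref$sigma < best$sigma &&
          assignment_consistent(model, inc$assignment, ref$z)) {
        best <- list(sigma = ref$sigma, z = ref$z, assigned = inc$assigned)
      }
      # conditional lower bound for this assignment (no-good style)
      xv <- unlist(lapply(seq_along(model$segments), function(p) {
        X <- model$idx$X[[p]]
        if (is.null(X)) return(integer(0))
        X[cbind(seq_len(nrow(X)), inc$assignment[[p]])]
      }))
      if (length(xv) > 0 && ref$sigma > tol) {
        add_row(model$rows, c(xv, model$idx$t),
                c(rep(ref$sigma, length(xv)), -1), -1e30,
                ref$sigma * (length(xv) - 1))
      }
    }
    cut <- separation_cut(objective, inc$residuals, sol$fun, inc$assigned,
                          model$segments, tol = tol / 10)
    if (is.null(cut)) {
      lower <- max(lower, sig)
      break
    }
    apply_cut(model, cut, inc$assignment)
  }
  structure(list(z = sort(best$z), objective = best$sigma,
                 optimal = (best$sigma - lower) <= max(tol, tol * best$sigma),
                 gap = best$sigma - lower, solves = solves,
                 assigned = best$assigned),
            class = "turnpike_exact")
}

#' @export
print.turnpike_exact <- function(x, ...) {
  cat("<turnpike_exact> n =", length(x$z), " objective =", format(x$objective),
      if (x$optimal) "(proven optimal)" else sprintf("(gap %.3g)", x$gap),
      " MILP solves:", x$solves, "\n")
  invisible(x)
}

# Warm start: run the alternating solver on the partition, rescale its unit
# solution to honor the pin, and derive the first cut from its residuals.
exact_warm_start <- function(model) {
  pt <- model$partition
  n <- model$n
  init <- if (pt$kind == "trivial") greedy_init(pt$segments[[1]]) else gaussian_init(n, seed = 7L)
  fit <- block_mm_solve(pt, init, solver_config(max_iters = 300))
  lens_all <- apply_Q(fit$z)
  obs_len_sum <- sum(unlist(lapply(model$seg_slots, function(s) lens_all[s])))
  s_fac <- if (obs_len_sum > 0) sum(unlist(model$segments)) / obs_len_sum else 1
  z_data <- fit$z * s_fac
  lens <- apply_Q(z_data)
  y <- lapply(model$seg_slots, function(s) sort(lens[s]))
  assignment <- lapply(model$seg_slots, function(s) rank(lens[s], ties.method = "first"))
  residuals <- lapply(seq_along(y), function(p) model$segments[[p]] - y[[p]])
  dmat <- matrix(NA_real_, n, n)
  for (p in seq_along(model$seg_slots)) {
    slots <- model$seg_slots[[p]]
    for (s in seq_along(slots)) {
      dmat[model$sp$i[slots[s]], model$sp$j[slots[s]]] <-
        model$segments[[p]][assignment[[p]][s]]
    }
  }
  sig <- sigma_eval(model$objective, residuals, dmat, model$segments)
  z_best <- z_data
  if (model$objective$kind == "mm_support") {
    ref <- assignment_sigma_lb(model, list(assignment = assignment))
    if (ref$sigma < sig && assignment_consistent(model, assignment, ref$z)) {
      sig <- ref$sigma
      z_best <- ref$z
    }
  }
  cut <- separation_cut(model$objective, residuals, 0, dmat, model$segments)
  list(sigma = sig, z = z_best, cut = cut, assignment = assignment,
       assigned = dmat)
}

# ---- certification oracles --------------------------------------------------

all_permutations <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(m - 1L)
  out <- matrix(0L, nrow(sub) * m, m)
  r <- 0L
  for (k in seq_len(m)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Exhaustive certification solve
#'
#' Enumerates assignments of the distance values to interval slots and fits
#' the points for each, returning the global optimum of the same scoring the
#' exact model uses (including the scale pin). For the `mm_support`
#' objective the per-assignment fit is closed-form and enumeration runs to
#' n = 5 (10! assignments, in compiled code); for the linf objectives every
#' assignment needs a small linear program and enumeration is capped at
#' n = 4. Used to certify [solve_exact()], never as a production solver.
#'
#' @param D Sorted complete distance multiset.
#' @param n Point count.
#' @param objective An [exact_objective()].
#' @return List with `z` (sorted fit) and `objective`.
#' @export
brute_force_solve <- function(D, n, objective = exact_objective()) {
  check_distances(D)
  stopifnot(n_from_m(length(D)) == n)
  if (objective$kind == "mm_support") {
    if (n > 5) stop("brute force (mm_support) refused for n > 5", call. = FALSE)
    res <- cpp_brute_force_l2(as.numeric(sort(D)), as.integer(n))
    return(list(z = sort(res$z), objective = res$objective))
  }
  if (n > 4) stop("brute force (", objective$kind, ") refused for n > 4", call. = FALSE)
  brute_force_linf(sort(D), n, objective)
}

brute_force_linf <- function(D, n, objective) {
  m <- length(D)
  sp <- slot_pairs(n)
  M <- 2 * max(D, 1e-12)
  S <- sum(D)
  a <- 2 * seq_len(n) - 1 - n
  perms <- all_permutations(m) # row: rank -> slot (slot holding rank t)
  probs <- vector("list", nrow(perms))
  sigmas <- rep(NA_real_, nrow(perms))
  for (pi in seq_len(nrow(perms))) {
    slot_of_rank <- perms[pi, ]
    rows <- new_row_set()
    nv <- n + 1L # z, t
    add_row(rows, seq_len(n), rep(1, n), 0, 0)
    add_row(rows, seq_len(n), a, S, S)
    for (k in seq_len(n - 1)) add_row(rows, c(k, k + 1), c(1, -1), -1e30, 0)
    add_row(rows, c(1, n), c(-1, 1), -1e30, M)
    for (t in seq_len(m - 1)) { # length ordering consistent with ranks
      s1 <- slot_of_rank[t]; s2 <- slot_of_rank[t + 1]
      add_row(rows, c(sp$j[s1], sp$i[s1], sp$j[s2], sp$i[s2]),
              c(1, -1, -1, 1), -1e30, 0)
    }
    if (objective$kind == "rel_linf") {
      for (t in seq_len(m)) {
        s <- slot_of_rank[t]
        w <- if (is.null(objective$weights)) D[t] else objective$weights[t]
        add_row(rows, c(sp$j[s], sp$i[s], n + 1L), c(1, -1, w), D[t], 1e30)
        add_row(rows, c(sp$j[s], sp$i[s], n + 1L), c(1, -1, -w), -1e30, D[t])
      }
    } else {
      # part_linf: the score depends on the assignment only; the LP is a
      # pure feasibility check for the ordering
      dmat <- matrix(NA_real_, n, n)
      for (t in seq_len(m)) {
        s <- slot_of_rank[t]
        dmat[sp$i[s], sp$j[s]] <- D[t]
      }
      sigmas[pi] <- part_linf_sigma(dmat)$value
    }
    rl <- rows_as_list(rows)
    cvec <- c(rep(0, n), 1)
    probs[[pi]] <- list(c = cvec, integrality = rep(0L, nv),
                        lb = c(rep(-M, n), 0), ub = c(rep(M, n), 1e30),
                        rows = rl[c("i", "j", "x")],
                        row_lb = rl$lb, row_ub = rl$ub, time_limit = 10)
  }
  sols <- milp_solve_batch(probs)
  best <- NULL
  for (pi in seq_len(nrow(perms))) {
    s <- sols[[pi]]
    if (!isTRUE(s$success) || is.null(s$x)) next
    val <- if (objective$kind == "rel_linf") s$fun else sigmas[pi]
    if (is.null(best) || val < best$objective) {
      best <- list(z = sort(unlist(s$x)[seq_len(n)]), objective = val)
    }
  }
  if (is.null(best)) stop("no feasible assignment found", call. = FALSE)
  best
}

#' Classical backtracking reconstruction (noiseless oracle)
#'
#' Largest-first backtracking with exact multiset bookkeeping: anchor the
#' span, then repeatedly place the largest unexplained distance at either
#' end, requiring every implied distance to be present, and backtrack on
#' failure. Intended for exact (noiseless) inputs in tests; returns `NULL`
#' when no placement reproduces the multiset.
#'
#' @param D Sorted complete distance multiset.
#' @param tol Equality tolerance for multiset membership.
#' @return Sorted point vector anchored at 0, or `NULL` on failure.
#' @export
backtracking_solve <- function(D, tol = 1e-9) {
  check_distances(D)
  n <- n_from_m(length(D))
  if (n == 2) return(c(0, D[1]))
  span <- D[length(D)]
  remove_one <- function(vals, x) {
    k <- which(abs(vals - x) <= tol + 1e-12 * max(1, x))
    if (length(k) == 0) return(NULL)
    vals[-k[1]]
  }
  remove_all <- function(vals, xs) {
    for (x in xs) {
      vals <- remove_one(vals, x)
      if (is.null(vals)) return(NULL)
    }
    vals
  }
  recurse <- function(points, remaining) {
    if (length(remaining) == 0) return(sort(points))
    y <- remaining[length(remaining)]
    for (cand in unique(c(y, span - y))) {
      left <- remove_all(remaining, abs(cand - points))
      if (!is.null(left)) {
        res <- recurse(c(points, cand), left)
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  recurse(c(0, span), D[-length(D)])
}
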