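#' @importFrom dplyr .data
NULL

# Scoring and protocol machinery. Reconstructions are compared to ground
# truth only after canonicalization (the distance multiset cannot tell a
# configuration from its mirror image), and restart selection never touches
# the ground truth: the best restart is the one whose implied distance
# multiset is closest to the *input* distances in l2.

#' Resolve the mirror ambiguity of an estimate
#'
#' Returns `z_est` or its reflection (negate and reverse), whichever has the
#' smaller mean absolute error against the reference configuration.
#'
#' @param z_est,z_ref Sorted, centered point configurations of equal length.
#' @return The better-aligned version of `z_est`.
#' @export
canonicalize <- function(z_est, z_ref) {
  if (length(z_est) != length(z_ref)) stop("size mismatch", call. = FALSE)
  refl <- rev(-z_est)
  if (mean(abs(refl - z_ref)) < mean(abs(z_est - z_ref))) refl else z_est
}

#' Distance multiset implied by an estimate, at input scale
#'
#' Solvers work with unit-norm configurations; this maps an estimate back to
#' the scale of an observed distance multiset via the identity
#' ||D||^2 = n ||z||^2.
#'
#' @param z Unit-norm sorted configuration.
#' @param D_input The observed distance multiset whose scale to match.
#' @return Sorted implied distance multiset at the scale of `D_input`.
#' @export
estimated_distances <- function(z, D_input) {
  sort(apply_Q(z)) * sqrt(sum(D_input^2)) / sqrt(length(z))
}

#' Score a reconstruction against ground truth and input
#'
#' MAE and MSE are computed index-by-index between the canonicalized
#' estimate and the reference (both sorted centered unit vectors); the
#' cosine similarity and l2 residual are computed between the estimate's
#' sorted implied distances and the sorted input distances; `normalized_mae`
#' divides the MAE by the noise magnitude when one is supplied.
#'
#' @param z_est Estimated configuration (unit norm).
#' @param z_ref Ground-truth configuration (unit norm).
#' @param D_input Observed (noisy) distance multiset.
#' @param epsilon Noise magnitude used to generate `D_input` (optional).
#' @return One-row tibble: `mae`, `mse`, `normalized_mae`,
#'   `cosine_similarity`, `l2_residual`.
#' @export
score_reconstruction <- function(z_est, z_ref, D_input, epsilon = NULL) {
  z_can <- canonicalize(z_est, z_ref)
  mae <- mean(abs(z_can - z_ref))
  mse <- mean((z_can - z_ref)^2)
  d_est <- sort(apply_Q(z_est))
  d_in <- sort(D_input)
  cosine <- sum(d_est * d_in) / (sqrt(sum(d_est^2)) * sqrt(sum(d_in^2)))
  l2 <- sqrt(sum((estimated_distances(z_est, D_input) - d_in)^2))
  tibble::tibble(
    mae = mae, mse = mse,
    normalized_mae = if (!is.null(epsilon) && epsilon > 0) mae / epsilon else NA_real_,
    cosine_similarity = cosine, l2_residual = l2
  )
}

#' Relative-uncertainty recovery criterion
#'
#' Declares a reconstruction successful when every recovered distance lies
#' within the relative uncertainty band of its ground-truth counterpart
#' (sorted order, inclusive boundary).
#'
#' @param D_est,D_true Sorted distance multisets of equal length.
#' @param r Relative uncertainty in \[0, 1\].
#' @return Logical flag.
#' @export
recovery_success <- function(D_est, D_true, r) {
  if (length(D_est) != length(D_true)) stop("size mismatch", call. = FALSE)
  all(abs(D_est - D_true) <= r * D_true)
}

#' Run the simulation/solve/score protocol
#'
#' For each instance: sample a point set, perturb its distance multiset,
#' solve with `restarts` greedy-family starts keeping the restart whose
#' implied distances have the smallest l2 residual against the *input*
#' distances (ground truth is used for scoring only), and score the winner.
#'
#' @param distributions Character vector from `"uniform"`, `"normal"`,
#'   `"cauchy"`.
#' @param n Points per instance.
#' @param epsilon Gaussian noise magnitude (standard deviation).
#' @param instances Instances per distribution.
#' @param restarts Restarts per instance.
#' @param method `"mmdq"` or `"mm"`.
#' @param config A [solver_config()].
#' @param seed Master seed; all per-instance seeds derive from it.
#' @return Tibble with one row per instance: identifiers, scores, and solver
#'   diagnostics. Summarize with [protocol_summary()].
#' @export
run_protocol <- function(distributions = c("uniform", "normal", "cauchy"),
                         n = 100, epsilon = 1e-6, instances = 10,
                         restarts = 10, method = c("mmdq", "mm"),
                         config = solver_config(), seed = 1L) {
  method <- match.arg(method)
  distributions <- match.arg(distributions, c("uniform", "normal", "cauchy"),
                             several.ok = TRUE)
  cfg <- as_solver_config(config)
  seeds <- withr::with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, 2L * length(distributions) * instances),
    ncol = 2L
  ))
  grid <- expand.grid(instance = seq_len(instances), distribution = distributions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    dist <- grid$distribution[g]
    inst <- grid$instance[g]
    z_true <- sample_points(dist, n, seed = seeds[g, 1])
    D <- make_noisy_instance(z_true, noise_spec("gaussian", epsilon, seed = seeds[g, 2]))
    sol <- solve_with_restarts(D, restarts, method, cfg, seed = seeds[g, 2])
    dplyr::bind_cols(
      tibble::tibble(distribution = dist, instance = inst, n = n,
                     epsilon = epsilon, restarts = restarts, method = method),
      score_reconstruction(sol$fit$z, z_true, D, epsilon),
      tibble::tibble(objective = sol$fit$objective,
                     iterations = sol$fit$iterations,
                     converged = sol$fit$converged)
    )
  })
  dplyr::bind_rows(rows)
}

# Solve one instance with greedy-family restarts; best by l2 residual
# between implied and input distances.
solve_with_restarts <- function(D, restarts, method, cfg, seed) {
  solver <- switch(method, mm = mm_solve, mmdq = mmdq_solve)
  inits <- restart_inits(D, restarts, seed)
  best <- NULL
  for (z0 in inits) {
    fit <- solver(D, z0, cfg)
    resid <- sqrt(sum((estimated_distances(fit$z, D) - D)^2))
    if (is.null(best) || resid < best$resid) best <- list(fit = fit, resid = resid)
  }
  best
}

#' Summarize a protocol run
#'
#' @param results Tibble from [run_protocol()].
#' @return Tibble with the pooled median normalized MAE (and raw MAE) plus
#'   one row per distribution.
#' @export
protocol_summary <- function(results) {
  pooled <- dplyr::summarise(results,
    distribution = "pooled",
    median_normalized_mae = stats::median(.data$normalized_mae),
    median_mae = stats::median(.data$mae),
    instances = dplyr::n()
  )
  per <- dplyr::summarise(
    dplyr::group_by(results, .data$distribution),
    median_normalized_mae = stats::median(.data$normalized_mae),
    median_mae = stats::median(.data$mae),
    instances = dplyr::n(),
    .groups = "drop"
  )
  dplyr::bind_rows(pooled, per)
}
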