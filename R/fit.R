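#' Configuration for model fitting
#'
#' @param window_size Context window size `N` (even, default 40).
#' @param stop_threshold Stop when the distance between consecutive
#'   concatenated `(w, eps, alpha)` vectors falls below this (default 0.1).
#' @param stop_metric `"euclidean"` (default) compares the Euclidean
#'   distance with the threshold; `"rms"` compares the RMS per-coordinate
#'   change instead, which keeps the same threshold meaningful when `N`
#'   changes.
#' @param max_outer_iterations Cap on outer iterations per barrier stage
#'   (default 25).
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for fold assignment.
#' @param lambda_start,lambda_end,lambda_factor Log-barrier continuation
#'   schedule: the barrier coefficient starts at `lambda_start` and is
#'   multiplied by `lambda_factor` until it reaches `lambda_end`
#'   (defaults 1e-2, 1e-6, 0.1, i.e. five stages).
#' @param inner_newton Newton steps per block per outer iteration
#'   (default 3).
#' @param initial_energy Optional named stacking-energy table used for
#'   initialisation and the null model; default
#'   [uniform_stacking_energy()]. Supply a published nearest-neighbour
#'   table here to reproduce that choice of null model.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(window_size = 40L,
                       stop_threshold = 0.1,
                       stop_metric = c("euclidean", "rms"),
                       max_outer_iterations = 25L,
                       folds = 5L,
                       seed = 1L,
                       lambda_start = 1e-2,
                       lambda_end = 1e-6,
                       lambda_factor = 0.1,
                       inner_newton = 3L,
                       initial_energy = NULL) {
  stop_metric <- match.arg(stop_metric)
  stopifnot(stop_threshold > 0, folds >= 2L, max_outer_iterations >= 1L,
            lambda_start > 0, lambda_end > 0, lambda_end <= lambda_start,
            lambda_factor > 0, lambda_factor < 1)
  structure(list(window_size = as.integer(window_size),
                 stop_threshold = stop_threshold,
                 stop_metric = stop_metric,
                 max_outer_iterations = as.integer(max_outer_iterations),
                 folds = as.integer(folds),
                 seed = as.integer(seed),
                 lambda_start = lambda_start,
                 lambda_end = lambda_end,
                 lambda_factor = lambda_factor,
                 inner_newton = as.integer(inner_newton),
                 initial_energy = initial_energy),
            class = "fit_config")
}

# Assemble the design data the optimizer works on.
#
# fit rows:  positions with full unambiguous context, keep mask TRUE and
#            count >= 1 (the least-squares objective needs log counts).
# eval rows: same but zero counts retained (deviance evaluation).
# D matrices hold the dinucleotide id of each of the N-1 window slots.
prepare_fit_data <- function(tracks, window_size) {
  if (inherits(tracks, "track_dataset")) tracks <- tracks$tracks
  stopifnot(length(tracks) > 0)
  per <- lapply(tracks, function(t) {
    L <- nchar(t$sequence)
    pos <- context_positions(L, window_size)
    if (length(pos) == 0L) return(NULL)
    did <- dinuc_ids(encode_bases(t$sequence))
    D <- window_dinuc_matrix(did, pos, window_size)
    ok <- rowSums(is.na(D)) == 0L & t$keep[pos]
    list(id = t$transcript_id,
         D = D[ok, , drop = FALSE],
         n = t$counts[pos][ok])
  })
  per <- Filter(Negate(is.null), per)
  if (length(per) == 0L)
    sb_stop("no transcript admits a full context window",
            "stackbias_objective_undefined")
  ids <- vapply(per, `[[`, character(1), "id")
  n_eval <- unlist(lapply(per, `[[`, "n"), use.names = FALSE)
  D_eval <- do.call(rbind, lapply(per, `[[`, "D"))
  trk_eval <- rep(seq_along(per),
                  vapply(per, function(p) length(p$n), integer(1)))
  fit_sel <- n_eval >= 1
  list(ids = ids,
       D_eval = D_eval, n_eval = n_eval, trk_eval = trk_eval,
       D_fit = D_eval[fit_sel, , drop = FALSE],
       n_fit = n_eval[fit_sel], trk_fit = trk_eval[fit_sel])
}

# sparse indicator matrices: ind[[m]] %*% w = sum_k w_k [D[,k] == m]
dinuc_indicators <- function(D) {
  k <- ncol(D)
  lapply(seq_len(16L), function(m) {
    hit <- which(D == m, arr.ind = TRUE)
    Matrix::sparseMatrix(i = hit[, 1L], j = hit[, 2L], x = 1,
                         dims = c(nrow(D), k))
  })
}

# energies for fit rows given the current eps (design matrix for w block)
eps_design <- function(D, eps) matrix(eps[D], nrow = nrow(D))

# residual of the log-scale least squares: r = log n - v_i - alpha + log(1+e^E)
ls_residual <- function(E, logn, v_row, alpha) logn - v_row - alpha + log1pexp(E)

# raw sum-of-squares objective
ls_objective_raw <- function(E, logn, v_row, alpha) {
  sum(ls_residual(E, logn, v_row, alpha)^2)
}

# reported (trace) objective: raw + barrier at the final lambda, so the
# trace is comparable across continuation stages and provably monotone
reported_objective <- function(raw, w, eps, lambda_report) {
  raw - lambda_report * (sum(log(w)) + sum(log(eps)))
}

# one damped Newton step on a parameter block of the penalized objective.
# X is dE/dtheta (rows = fit observations); returns the proposed full
# (w, eps) pair already renormalized to sum(w) = 1, or NULL if no step
# decreased the reported objective.
newton_block_step <- function(theta, X, E, logn, v_row, alpha,
                              lambda, lambda_report,
                              block, w, eps, D_fit, f_rep_current) {
  r <- ls_residual(E, logn, v_row, alpha)
  s <- stats::plogis(E)           # d log(1+e^E) / dE
  sp <- s * (1 - s)
  g_scale <- 2 * (r * s)
  grad <- drop(crossprod(X, g_scale)) - lambda / theta
  q <- 2 * (s^2 + r * sp)
  H <- crossprod(X * sqrt(pmax(q, 0)), X * sqrt(pmax(q, 0)))
  neg <- q < 0
  if (any(neg)) {
    Xn <- X[neg, , drop = FALSE]
    H <- H - crossprod(Xn * sqrt(-q[neg]), Xn * sqrt(-q[neg]))
  }
  diag(H) <- diag(H) + lambda / theta^2
  delta <- NULL
  tau <- 0
  for (try in 0:6) {
    Ht <- H
    if (tau > 0) diag(Ht) <- diag(Ht) + tau
    ch <- tryCatch(chol(Ht), error = function(e) NULL)
    if (!is.null(ch)) {
      delta <- -backsolve(ch, backsolve(ch, grad, transpose = TRUE))
      break
    }
    tau <- if (tau == 0) 1e-8 * mean(abs(diag(H))) + 1e-12 else tau * 100
  }
  if (is.null(delta)) delta <- -grad / (sqrt(sum(grad^2)) + 1)  # gradient fallback
  step <- 1
  for (bt in 1:40) {
    cand <- theta + step * delta
    if (all(cand > 0)) {
      if (block == "w") { w_c <- cand; eps_c <- eps } else { w_c <- w; eps_c <- cand }
      sc <- sum(w_c)
      w_c <- w_c / sc
      eps_c <- eps_c * sc
      E_c <- drop(eps_design(D_fit, eps_c) %*% w_c)
      raw_c <- ls_objective_raw(E_c, logn, v_row, alpha)
      f_rep_c <- reported_objective(raw_c, w_c, eps_c, lambda_report)
      if (f_rep_c <= f_rep_current - 1e-12 ||
          (bt == 1 && f_rep_c <= f_rep_current)) {
        return(list(w = w_c, eps = eps_c, E = E_c, f_rep = f_rep_c))
      }
    }
    step <- step / 2
  }
  NULL
}

#' Initialise fit parameters
#'
#' Per-transcript log-abundances start at the log mean per-base count
#' `v_i = log(total_reads_i / L_i)`; positional weights start uniform at
#' `1/(N-1)`; stacking energies at the configured initial table; the
#' intercept at 0. All-zero tracks are excluded with a warning.
#'
#' @param tracks A [track_dataset()] or list of tracks.
#' @param config A [fit_config()].
#' @return List with `params` (a [stacking_params()]) and `v` (named
#'   numeric).
#' @export
initialize_fit <- function(tracks, config = fit_config()) {
  if (inherits(tracks, "track_dataset")) tracks <- tracks$tracks
  nonzero <- vapply(tracks, function(t) t$total_reads > 0, logical(1))
  if (any(!nonzero))
    warning(sprintf("excluding %d all-zero track(s) from fitting",
                    sum(!nonzero)), call. = FALSE)
  tracks <- tracks[nonzero]
  if (length(tracks) == 0L)
    sb_stop("no track with positive counts", "stackbias_fit_error")
  v <- vapply(tracks, function(t) log(t$total_reads / nchar(t$sequence)),
              numeric(1))
  names(v) <- vapply(tracks, `[[`, character(1), "transcript_id")
  N <- config$window_size
  eps <- if (is.null(config$initial_energy)) uniform_stacking_energy(N) else {
    e <- config$initial_energy[DINUCLEOTIDES]
    names(e) <- DINUCLEOTIDES
    e
  }
  params <- stacking_params(eps, rep(1 / (N - 1), N - 1L), alpha = 0,
                            window_size = N)
  list(params = params, v = v, tracks = tracks)
}

#' Penalized least-squares objective of the bias model
#'
#' The sum over eligible positions (full unambiguous context, kept by the
#' preprocessing mask, count >= 1) of squared residuals
#' `(log n_ij - v_i - alpha - log affinity_ij)^2`. This is the quantity the
#' alternating Newton optimisation descends (plus the log barrier that
#' keeps `w` and `eps` positive).
#'
#' @param tracks A [track_dataset()] or list of tracks.
#' @param params A [stacking_params()].
#' @param v Named numeric of per-transcript log-abundances.
#' @param alpha Intercept; defaults to `params$alpha`.
#' @return Numeric scalar.
#' @export
model_objective <- function(tracks, params, v, alpha = params$alpha) {
  if (inherits(tracks, "track_dataset")) tracks <- tracks$tracks
  dat <- prepare_fit_data(tracks, params$window_size)
  if (length(dat$n_fit) == 0L)
    sb_stop("no eligible position (full context and count >= 1)",
            "stackbias_objective_undefined")
  if (!all(dat$ids %in% names(v)))
    sb_stop("v missing transcripts", "stackbias_bad_argument")
  E <- drop(eps_design(dat$D_fit, params$stacking_energy) %*%
              params$positional_weights)
  ls_objective_raw(E, log(dat$n_fit), v[dat$ids][dat$trk_fit], alpha)
}

#' Fit the read-start bias model
#'
#' Alternating penalized Newton optimisation of the log-scale least-squares
#' objective: (a) a damped Newton block update of the positional weights
#' `w` with stacking energies fixed, (b) a block update of the energies
#' `eps` with `w` fixed, (c) closed-form updates of the intercept `alpha`
#' (global mean residual) and the per-transcript log-abundances `v_i`
#' (per-transcript mean residual, the exact least-squares minimiser).
#' `sum(w) = 1` is restored after every block (only the products `w * eps`
#' enter the model, so this fixes the scale degeneracy without changing the
#' fit). Positivity of `w` and `eps` is maintained by a logarithmic barrier
#' whose coefficient is decayed over continuation stages
#' (`lambda_start` down to `lambda_end`); step acceptance and the recorded
#' objective trace use the barrier at the final coefficient, making the
#' trace non-increasing by construction.
#'
#' Iteration stops within a stage when the distance between consecutive
#' concatenated `(w, eps, alpha)` vectors drops below `stop_threshold`
#' (default 0.1) or after `max_outer_iterations`.
#'
#' @param tracks A [track_dataset()] or list of [transcript_track()]s
#'   (preprocess first if trimming/zero-dropping is wanted).
#' @param config A [fit_config()].
#' @return An object of class `bias_fit`: list with `params` (fitted
#'   [stacking_params()], intercept included), `v` (named log-abundances,
#'   reported as the closed-form Poisson MLE under the fitted preferences,
#'   which uses every eligible position including zeros),
#'   `objective_trace`, `converged`, `iterations`, `deviance`,
#'   `null_deviance` and `r_squared` (training-set deviance R-squared).
#' @export
fit_bias_model <- function(tracks, config = fit_config()) {
  init <- initialize_fit(tracks, config)
  tracks <- init$tracks
  N <- config$window_size
  dat <- prepare_fit_data(tracks, N)
  if (length(dat$n_fit) == 0L)
    sb_stop("no eligible position to fit", "stackbias_objective_undefined")
  ind <- dinuc_indicators(dat$D_fit)
  logn <- log(dat$n_fit)
  v <- init$v[dat$ids]
  w <- init$params$positional_weights
  eps <- init$params$stacking_energy
  alpha <- init$params$alpha
  lambda_report <- config$lambda_end

  lambdas <- c()
  l <- config$lambda_start
  while (l > config$lambda_end * (1 + 1e-12)) {
    lambdas <- c(lambdas, l)
    l <- l * config$lambda_factor
  }
  lambdas <- c(lambdas, config$lambda_end)

  E <- drop(eps_design(dat$D_fit, eps) %*% w)
  trace <- numeric(0)
  converged <- FALSE
  total_iter <- 0L
  dim_theta <- length(w) + 16L + 1L

  for (lambda in lambdas) {
    for (iter in seq_len(config$max_outer_iterations)) {
      total_iter <- total_iter + 1L
      theta_prev <- c(w, eps, alpha)
      v_row <- v[dat$trk_fit]
      raw <- ls_objective_raw(E, logn, v_row, alpha)
      f_rep <- reported_objective(raw, w, eps, lambda_report)

      # (a) positional-weight block
      for (k in seq_len(config$inner_newton)) {
        Xw <- eps_design(dat$D_fit, eps)
        stp <- newton_block_step(w, Xw, E, logn, v_row, alpha,
                                 lambda, lambda_report, "w", w, eps,
                                 dat$D_fit, f_rep)
        if (is.null(stp)) break
        w <- stp$w; eps <- stp$eps; E <- stp$E; f_rep <- stp$f_rep
      }
      # (b) stacking-energy block
      for (k in seq_len(config$inner_newton)) {
        Xe <- vapply(ind, function(M) as.vector(M %*% w),
                     numeric(length(logn)))
        stp <- newton_block_step(eps, Xe, E, logn, v_row, alpha,
                                 lambda, lambda_report, "eps", w, eps,
                                 dat$D_fit, f_rep)
        if (is.null(stp)) break
        w <- stp$w; eps <- stp$eps; E <- stp$E; f_rep <- stp$f_rep
      }
      # (c) closed-form intercept and abundance updates (exact minimisers)
      r <- ls_residual(E, logn, v[dat$trk_fit], alpha)
      alpha <- alpha + mean(r)
      r <- ls_residual(E, logn, v[dat$trk_fit], alpha)
      dv <- tapply(r, dat$trk_fit, mean)
      v[as.integer(names(dv))] <- v[as.integer(names(dv))] + as.numeric(dv)

      raw <- ls_objective_raw(E, logn, v[dat$trk_fit], alpha)
      if (!is.finite(raw))
        sb_stop("objective became non-finite; fit diverged",
                "stackbias_fit_diverged")
      trace <- c(trace, reported_objective(raw, w, eps, lambda_report))

      dist <- sqrt(sum((c(w, eps, alpha) - theta_prev)^2))
      if (config$stop_metric == "rms") dist <- dist / sqrt(dim_theta)
      if (dist < config$stop_threshold) { converged <- TRUE; break }
      converged <- FALSE
    }
  }

  params <- stacking_params(eps, w, alpha = alpha, window_size = N)
  # report v by the closed-form Poisson MLE under the fitted preferences
  # (the least-squares v used during descent conditions on n >= 1 and is
  # biased at moderate coverage; the closed form uses every eligible
  # position, zeros included)
  aff_eval <- binding_affinity(drop(eps_design(dat$D_eval, eps) %*% w))
  num <- tapply(dat$n_eval, dat$trk_eval, sum)
  den <- tapply(exp(alpha) * aff_eval, dat$trk_eval, sum)
  v_full <- rep(NA_real_, length(dat$ids))
  v_full[as.integer(names(num))] <- log(as.numeric(num)) -
    log(as.numeric(den))
  mu_eval <- exp(v_full[dat$trk_eval] + alpha) * aff_eval
  mu_eval[!is.finite(mu_eval)] <- 0
  dev <- deviance_from_counts(dat$n_eval, mu_eval)
  v <- v_full
  names(v) <- dat$ids
  v <- v[!is.na(v)]
  d0 <- null_model_deviance(tracks, config)
  structure(list(params = params,
                 v = v,
                 objective_trace = trace,
                 converged = converged,
                 iterations = total_iter,
                 deviance = dev,
                 null_deviance = d0,
                 r_squared = r_squared(dev, d0)),
            class = "bias_fit")
}

#' @export
print.bias_fit <- function(x, ...) {
  cat(sprintf(paste0("bias_fit: %d transcripts, %d outer iterations",
                     " (converged: %s)\n"),
              length(x$v), x$iterations, x$converged))
  cat(sprintf("  deviance %.4g vs null %.4g; training R^2 = %.3f\n",
              x$deviance, x$null_deviance, x$r_squared))
  invisible(x)
}
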