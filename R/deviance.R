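# Poisson deviance of counts n against rates mu; n log n taken as 0 at n = 0
deviance_from_counts <- function(n, mu) {
  if (any(mu <= 0 & n > 0))
    sb_stop("zero fitted rate at a nonzero count: infinite deviance",
            "stackbias_infinite_deviance")
  term <- ifelse(n > 0, n * log(n / mu), 0)
  2 * sum(term - (n - mu))
}

# eligible evaluation rows of one track: full unambiguous context + keep mask
track_eval <- function(track, params) {
  N <- params$window_size
  L <- nchar(track$sequence)
  pos <- context_positions(L, N)
  if (length(pos) == 0L)
    return(list(position = integer(0), n = numeric(0), affinity = numeric(0)))
  did <- dinuc_ids(encode_bases(track$sequence))
  D <- window_dinuc_matrix(did, pos, N)
  ok <- rowSums(is.na(D)) == 0L & track$keep[pos]
  D <- D[ok, , drop = FALSE]
  E <- drop(eps_design(D, params$stacking_energy) %*%
              params$positional_weights)
  list(position = pos[ok] - 1L, n = track$counts[pos][ok],
       affinity = binding_affinity(E))
}

# closed-form MLE of v_i given fixed preferences:
# v = log( sum n / sum exp(alpha) * affinity )
closed_form_v <- function(n, affinity, alpha) {
  denom <- sum(exp(alpha) * affinity)
  if (denom <= 0)
    sb_stop("zero denominator in abundance closed form",
            "stackbias_estimation_error")
  log(sum(n)) - log(denom)   # -Inf for all-zero tracks
}

#' Poisson deviance of a fitted bias model
#'
#' `2 * sum( n log(n / mu) - (n - mu) )` over every position with a full
#' unambiguous context that survives the preprocessing mask; zero-count
#' positions contribute through the `2 * mu` branch. Rates are
#' `mu_ij = exp(v_i + alpha) * affinity_ij`.
#'
#' @param tracks A [track_dataset()] or list of tracks.
#' @param params A [stacking_params()].
#' @param v Named numeric log-abundances covering all tracks.
#' @param alpha Intercept; defaults to `params$alpha`.
#' @return Non-negative numeric scalar.
#' @export
poisson_deviance <- function(tracks, params, v, alpha = params$alpha) {
  if (inherits(tracks, "track_dataset")) tracks <- tracks$tracks
  total <- 0
  for (t in tracks) {
    ev <- track_eval(t, params)
    if (length(ev$n) == 0L) next
    if (!t$transcript_id %in% names(v))
      sb_stop(sprintf("v missing transcript '%s'", t$transcript_id),
              "stackbias_bad_argument")
    mu <- exp(v[[t$transcript_id]] + alpha) * ev$affinity
    total <- total + deviance_from_counts(ev$n, mu)
  }
  total
}

#' Deviance R-squared
#'
#' `R^2 = 1 - d / d0`: 1 for a saturated fit, 0 when the fitted model does
#' no better than the null model.
#'
#' @param d Deviance of the fitted model (>= 0).
#' @param d0 Deviance of the null model (> 0).
#' @return Numeric scalar.
#' @export
r_squared <- function(d, d0) {
  stopifnot(d >= 0)
  if (d0 <= 0)
    sb_stop("null deviance must be positive", "stackbias_undefined_r2")
  1 - d / d0
}

#' Deviance of the null model
#'
#' The null model uses equal positional weights `w_k = 1/(N-1)`, the
#' configured initial stacking-energy table and `alpha = 0`; per-transcript
#' log-abundances are set by the closed-form MLE under those fixed
#' preferences. With the default uniform table every window has the same
#' affinity, so the null model is the constant-rate-per-transcript Poisson
#' model.
#'
#' @inheritParams poisson_deviance
#' @param config A [fit_config()] (supplies `window_size` and
#'   `initial_energy`).
#' @return The null deviance `d0`.
#' @export
null_model_deviance <- function(tracks, config = fit_config()) {
  if (inherits(tracks, "track_dataset")) tracks <- tracks$tracks
  params0 <- null_params(config$window_size, config$initial_energy)
  total <- 0
  for (t in tracks) {
    ev <- track_eval(t, params0)
    if (length(ev$n) == 0L) next
    v0 <- closed_form_v(ev$n, ev$affinity, 0)
    mu <- exp(v0) * ev$affinity
    mu[!is.finite(mu)] <- 0        # all-zero track: v0 = -Inf, mu = 0
    total <- total + deviance_from_counts(ev$n, mu)
  }
  total
}

#' Cross-validated deviance R-squared
#'
#' Partitions the transcripts into `config$folds` groups by a seeded
#' shuffle. For each fold the global parameters `(w, eps, alpha)` are fitted
#' on the remaining folds; held-out transcripts get their `v_i` from the
#' closed-form MLE with those parameters frozen. Held-out deviances `d` and
#' null deviances `d0` are pooled and `1 - sum(d) / sum(d0)` returned.
#'
#' @inheritParams null_model_deviance
#' @return Numeric scalar, with attributes `folds` (per-fold d and d0) and
#'   `n_transcripts`.
#' @export
cross_validated_r2 <- function(tracks, config = fit_config()) {
  if (inherits(tracks, "track_dataset")) tracks <- tracks$tracks
  ids <- vapply(tracks, `[[`, character(1), "transcript_id")
  names(tracks) <- ids
  if (length(tracks) < config$folds)
    sb_stop("need at least as many transcripts as folds",
            "stackbias_fit_error")
  shuffled <- withr::with_seed(config$seed, sample(ids))
  fold_of <- split(shuffled,
                   cut(seq_along(shuffled), config$folds, labels = FALSE))
  d_sum <- d0_sum <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    test_ids <- fold_of[[f]]
    train <- tracks[setdiff(ids, test_ids)]
    fitted <- fit_bias_model(train, config)
    d <- d0 <- 0
    params0 <- null_params(config$window_size, config$initial_energy)
    any_pos <- FALSE
    for (id in test_ids) {
      ev <- track_eval(tracks[[id]], fitted$params)
      if (length(ev$n) > 0L) {
        any_pos <- TRUE
        vh <- closed_form_v(ev$n, ev$affinity, fitted$params$alpha)
        mu <- exp(vh + fitted$params$alpha) * ev$affinity
        mu[!is.finite(mu)] <- 0
        d <- d + deviance_from_counts(ev$n, mu)
      }
      ev0 <- track_eval(tracks[[id]], params0)
      if (length(ev0$n) > 0L) {
        v0 <- closed_form_v(ev0$n, ev0$affinity, 0)
        mu0 <- exp(v0) * ev0$affinity
        mu0[!is.finite(mu0)] <- 0
        d0 <- d0 + deviance_from_counts(ev0$n, mu0)
      }
    }
    if (!any_pos) {
      warning(sprintf("fold %d has no eligible position; skipped", f),
              call. = FALSE)
      d_sum[f] <- d0_sum[f] <- NA_real_
      next
    }
    d_sum[f] <- d
    d0_sum[f] <- d0
  }
  ok <- !is.na(d_sum)
  out <- 1 - sum(d_sum[ok]) / sum(d0_sum[ok])
  attr(out, "folds") <- data.frame(fold = seq_len(config$folds),
                                   deviance = d_sum, null_deviance = d0_sum)
  attr(out, "n_transcripts") <- length(tracks)
  out
}

#' Predicted read-start track for one transcript
#'
#' Computes fitted per-position rates for `track` under frozen global
#' parameters, with the transcript's own abundance set by the closed-form
#' MLE — the held-out prediction used, e.g., to draw observed-versus-fitted
#' count tracks for a transcript left out of training.
#'
#' @param track A [transcript_track()].
#' @param params Fitted [stacking_params()].
#' @param alpha Intercept; defaults to `params$alpha`.
#' @return Data frame with `position` (0-based), `observed` and `fitted`
#'   columns over eligible positions.
#' @export
predict_track <- function(track, params, alpha = params$alpha) {
  ev <- track_eval(track, params)
  if (length(ev$n) == 0L)
    sb_stop("no eligible position on this track", "stackbias_bad_argument")
  vh <- closed_form_v(ev$n, ev$affinity, alpha)
  fitted <- exp(vh + alpha) * ev$affinity
  fitted[!is.finite(fitted)] <- 0
  data.frame(position = ev$position, observed = ev$n, fitted = fitted)
}
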