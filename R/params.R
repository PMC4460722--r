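#' The 16 ordered dinucleotides
#'
#' Lexicographic order `AA, AC, AG, AT, CA, ..., TT`; this is the key order
#' used everywhere a stacking-energy table appears (construction, JSON files,
#' internal integer encoding).
#'
#' @format Character vector of length 16.
#' @export
DINUCLEOTIDES <- paste0(rep(c("A", "C", "G", "T"), each = 4),
                        rep(c("A", "C", "G", "T"), times = 4))

sb_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "stackbias_error"),
                      call = call))
}

#' Construct a stacking-energy parameter set
#'
#' Bundles the three parameter groups of the read-start bias model: a
#' stacking-energy table `eps` over the 16 ordered dinucleotides, positional
#' weights `w_k` for the `N - 1` overlapping dinucleotides of an `N`-base
#' context window, and an intercept `alpha`. The free energy of a window is
#' `E = sum_k w_k * eps[b_k, b_{k+1}]` and its binding affinity
#' `1 / (1 + exp(E))`; see [free_energy()] and [binding_affinity()].
#'
#' Only the products `w_k * eps` enter the energy, so the overall scale of
#' `w` versus `eps` is not identifiable. The fitting code resolves this by
#' normalising `sum(w) = 1` after every optimisation block; the constructor
#' does not enforce the normalisation so that intermediate states remain
#' representable.
#'
#' @param stacking_energy Named numeric vector with exactly the 16 keys in
#'   [DINUCLEOTIDES] (any order; stored in lexicographic order). All values
#'   must be non-negative.
#' @param positional_weights Numeric vector of length `window_size - 1`,
#'   all non-negative.
#' @param alpha Finite numeric intercept on the log-rate scale.
#' @param window_size Even integer >= 4; number of bases in a context
#'   window. Default 40.
#' @return An object of class `stacking_params`.
#' @seealso [uniform_stacking_energy()], [null_params()],
#'   [read_params_json()]
#' @export
#' @examples
#' p <- null_params(window_size = 6)
#' p$positional_weights
stacking_params <- function(stacking_energy, positional_weights, alpha = 0,
                            window_size = 40L) {
  window_size <- as.integer(window_size)
  if (length(window_size) != 1L || is.na(window_size) ||
      window_size < 4L || window_size %% 2L != 0L)
    sb_stop("window_size must be a single even integer >= 4",
            "stackbias_bad_argument")
  if (is.null(names(stacking_energy)) ||
      !setequal(names(stacking_energy), DINUCLEOTIDES) ||
      length(stacking_energy) != 16L)
    sb_stop("stacking_energy must be named by exactly the 16 dinucleotides",
            "stackbias_corrupt_parameters")
  stacking_energy <- as.numeric(stacking_energy[DINUCLEOTIDES])
  names(stacking_energy) <- DINUCLEOTIDES
  if (anyNA(stacking_energy) || any(stacking_energy < 0))
    sb_stop("stacking energies must be non-negative and finite",
            "stackbias_corrupt_parameters")
  positional_weights <- as.numeric(positional_weights)
  if (length(positional_weights) != window_size - 1L)
    sb_stop(sprintf("positional_weights must have length window_size - 1 = %d",
                    window_size - 1L), "stackbias_corrupt_parameters")
  if (anyNA(positional_weights) || any(positional_weights < 0))
    sb_stop("positional weights must be non-negative and finite",
            "stackbias_corrupt_parameters")
  alpha <- as.numeric(alpha)
  if (length(alpha) != 1L || !is.finite(alpha))
    sb_stop("alpha must be a single finite number", "stackbias_bad_argument")
  structure(
    list(stacking_energy = stacking_energy,
         positional_weights = positional_weights,
         alpha = alpha,
         window_size = window_size),
    class = "stacking_params")
}

#' @export
print.stacking_params <- function(x, ...) {
  cat(sprintf("stacking_params: window %d nt, %d free parameters\n",
              x$window_size, parameter_count(x$window_size)))
  cat(sprintf("  alpha = %.4g; sum(w) = %.4g; energy range [%.4g, %.4g]\n",
              x$alpha, sum(x$positional_weights),
              min(x$stacking_energy), max(x$stacking_energy)))
  invisible(x)
}

#' Uniform initial stacking-energy table
#'
#' All 16 dinucleotides at `1 / (window_size - 1)`: the initialisation used
#' at the start of fitting and (by default) in the null model. A published
#' nearest-neighbour table can be supplied anywhere this default is accepted.
#'
#' @inheritParams stacking_params
#' @return Named numeric vector of length 16.
#' @export
uniform_stacking_energy <- function(window_size = 40L) {
  e <- rep(1 / (window_size - 1), 16L)
  names(e) <- DINUCLEOTIDES
  e
}

#' Null-model parameter set
#'
#' Equal positional weights `w_k = 1/(N-1)`, the initial stacking-energy
#' table and `alpha = 0`. The deviance of this model is the reference
#' `d0` of the deviance R-squared.
#'
#' @inheritParams stacking_params
#' @param stacking_energy Optional named table; default
#'   [uniform_stacking_energy()].
#' @return A `stacking_params` object.
#' @export
null_params <- function(window_size = 40L, stacking_energy = NULL) {
  if (is.null(stacking_energy))
    stacking_energy <- uniform_stacking_energy(window_size)
  stacking_params(stacking_energy,
                  rep(1 / (window_size - 1), window_size - 1L),
                  alpha = 0, window_size = window_size)
}

#' Number of free model parameters
#'
#' `(window_size - 1)` positional weights + 16 stacking energies + 1
#' intercept; 56 for the default 40-base window.
#'
#' @inheritParams stacking_params
#' @return Integer.
#' @export
#' @examples
#' parameter_count(40) # 56
parameter_count <- function(window_size) {
  window_size <- as.integer(window_size)
  if (length(window_size) != 1L || is.na(window_size) ||
      window_size < 4L || window_size %% 2L != 0L)
    sb_stop("window_size must be a single even integer >= 4",
            "stackbias_bad_argument")
  (window_size - 1L) + 16L + 1L
}

#' Read / write parameter sets as JSON
#'
#' The file holds keys `window_size`, `alpha`, `positional_weights` (array
#' of length `N - 1`, order `k = 1..N-1`) and `stacking_energy` (object
#' keyed `AA`..`TT` in lexicographic order). Values are written at full
#' precision so a round trip is lossless.
#'
#' @param params A `stacking_params` object.
#' @param path File path.
#' @return `read_params_json()` returns a `stacking_params`;
#'   `write_params_json()` returns `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "stacking_params"))
  obj <- list(window_size = params$window_size,
              alpha = params$alpha,
              positional_weights = params$positional_weights,
              stacking_energy = as.list(params$stacking_energy))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stacking_params(unlist(obj$stacking_energy),
                  obj$positional_weights,
                  alpha = obj$alpha,
                  window_size = obj$window_size)
}
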