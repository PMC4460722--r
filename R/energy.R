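# Sequence encoding helpers. Bases are coded A=1, C=2, G=3, T=4; the ordered
# dinucleotide (b1, b2) gets index (b1 - 1) * 4 + b2, which matches the
# lexicographic order of DINUCLEOTIDES. Ambiguous bases encode as NA and
# poison every window that touches them.

encode_bases <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]],
        c("A", "C", "G", "T"))
}

# dinucleotide ids along a coded sequence; length L - 1
dinuc_ids <- function(codes) {
  n <- length(codes)
  if (n < 2L) return(integer(0))
  (codes[-n] - 1L) * 4L + codes[-1L]
}

# 1-based positions admitting a full window: p - N/2 >= 1, p + N/2 - 1 <= L
context_positions <- function(L, window_size) {
  h <- window_size %/% 2L
  if (L < window_size) return(integer(0))
  seq.int(h + 1L, L - h + 1L)
}

# rows: one eligible position; cols: the N - 1 dinucleotide ids of its window
window_dinuc_matrix <- function(did, positions_1based, window_size) {
  h <- window_size %/% 2L
  k <- window_size - 1L
  idx <- outer(positions_1based - h - 1L, seq_len(k), `+`)
  matrix(did[idx], nrow = length(positions_1based), ncol = k)
}

# numerically stable log(1 + exp(x)); -log affinity
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Extract the sequence context of a read-start position
#'
#' The context window spans `N/2` bases upstream through `N/2 - 1` bases
#' downstream of the read-start base, the start base included: offsets
#' `-N/2 .. +N/2 - 1`, so for the default 40-base window 20 upstream and 19
#' downstream. Positions whose window would run off either end of the
#' transcript have no context and raise a `stackbias_context_unavailable`
#' error; windows containing an ambiguous base (anything outside A/C/G/T)
#' raise `stackbias_window_rejected`. Callers fitting or predicting simply
#' skip such positions.
#'
#' @param sequence Nucleotide string.
#' @param position 0-based coordinate of the read-start base.
#' @param window_size Even integer >= 4.
#' @return A `context_window`: list with `bases` (length-`N` string) and
#'   `focal_offset` (0-based index of the read-start base in the window,
#'   always `N/2`).
#' @export
#' @examples
#' extract_context("ACGTAC", 2, 4) # window "ACGT", focal offset 2
extract_context <- function(sequence, position, window_size = 40L) {
  window_size <- as.integer(window_size)
  L <- nchar(sequence)
  h <- window_size %/% 2L
  position <- as.integer(position)
  if (position < 0L || position >= L)
    sb_stop("position outside the sequence", "stackbias_bad_argument")
  if (position < h || position > L - h)
    sb_stop(sprintf("no full %d nt context at position %d (needs %d..%d)",
                    window_size, position, h, L - h),
            "stackbias_context_unavailable")
  bases <- substr(sequence, position - h + 1L, position + h)
  if (grepl("[^ACGTacgt]", bases))
    sb_stop("window contains an ambiguous base", "stackbias_window_rejected")
  structure(list(bases = toupper(bases), focal_offset = h),
            class = "context_window")
}

#' Free energy of a context window
#'
#' The weighted sum of stacking energies over the `N - 1` overlapping
#' dinucleotides of the window: `E = sum_k w_k * eps[b_k, b_{k+1}]`.
#'
#' @param window A `context_window` from [extract_context()], or a plain
#'   nucleotide string of length `params$window_size`.
#' @param params A [stacking_params()] object.
#' @return Non-negative numeric scalar (given non-negative `w`, `eps`).
#' @export
free_energy <- function(window, params) {
  stopifnot(inherits(params, "stacking_params"))
  bases <- if (inherits(window, "context_window")) window$bases else window
  if (nchar(bases) != params$window_size)
    sb_stop("window length does not match params$window_size",
            "stackbias_bad_argument")
  ids <- dinuc_ids(encode_bases(bases))
  if (anyNA(ids))
    sb_stop("window contains an ambiguous base", "stackbias_window_rejected")
  sum(params$positional_weights * params$stacking_energy[ids])
}

#' Binding affinity of a free energy
#'
#' The logistic complement `1 / (1 + exp(E))`: strictly decreasing in the
#' energy, bounded in (0, 1), and at most 0.5 whenever `E >= 0`. Large
#' positive energies underflow smoothly towards 0.
#'
#' @param energy Numeric vector of free energies.
#' @return Numeric vector in (0, 1).
#' @export
#' @examples
#' binding_affinity(0) # 0.5
binding_affinity <- function(energy) {
  stopifnot(is.numeric(energy))
  stats::plogis(-energy)
}

#' Per-position Poisson rate
#'
#' `mu_ij = exp(v_i) * exp(alpha) * affinity`: the transcript-level rate
#' `exp(v_i)` modulated by the sequencing preference of the local context.
#'
#' @param v Transcript log-abundance `v_i = log(mu_i)`.
#' @param alpha Model intercept.
#' @param affinity Binding affinity in (0, 1).
#' @return Numeric rate(s).
#' @export
poisson_rate <- function(v, alpha, affinity) {
  if (any(!is.finite(affinity)) || any(affinity <= 0))
    sb_stop("affinity must be positive", "stackbias_bad_argument")
  exp(v + alpha + log(affinity))
}

#' Affinity profile along a transcript
#'
#' Computes the binding affinity at every position of `sequence` that admits
#' a full, unambiguous context window. Positions without full context (the
#' first `N/2` and last `N/2 - 1` bases) and windows containing ambiguous
#' bases are absent from the profile.
#'
#' @param sequence Nucleotide string, longer than the window.
#' @param params A [stacking_params()] object.
#' @param transcript_id Identifier attached to the output rows.
#' @return A data frame of class `affinity_profile` with columns
#'   `transcript_id`, `position` (0-based), `affinity`, and
#'   `rate_multiplier = exp(alpha) * affinity`.
#' @export
affinity_profile <- function(sequence, params, transcript_id = "seq") {
  stopifnot(inherits(params, "stacking_params"))
  N <- params$window_size
  L <- nchar(sequence)
  pos <- context_positions(L, N)
  if (length(pos) == 0L) {
    warning(sprintf("sequence '%s' shorter than the %d nt window: empty profile",
                    transcript_id, N), call. = FALSE)
    out <- data.frame(transcript_id = character(0), position = integer(0),
                      affinity = numeric(0), rate_multiplier = numeric(0))
    class(out) <- c("affinity_profile", "data.frame")
    return(out)
  }
  did <- dinuc_ids(encode_bases(sequence))
  D <- window_dinuc_matrix(did, pos, N)
  ok <- rowSums(is.na(D)) == 0L
  D <- D[ok, , drop = FALSE]
  pos <- pos[ok]
  E <- as.vector(matrix(params$stacking_energy[D], nrow = nrow(D)) %*%
                   params$positional_weights)
  out <- data.frame(transcript_id = rep(transcript_id, length(pos)),
                    position = pos - 1L,
                    affinity = binding_affinity(E),
                    rate_multiplier = exp(params$alpha) * binding_affinity(E))
  class(out) <- c("affinity_profile", "data.frame")
  out
}

#' Export an affinity profile as TSV
#'
#' Writes `transcript_id`, `position` (0-based) and `affinity` columns.
#'
#' @param profile An `affinity_profile` (or any data frame with those
#'   columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affinity_tsv <- function(profile, path) {
  utils::write.table(profile[, c("transcript_id", "position", "affinity")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
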