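#' Bias-corrected transcript abundance estimate
#'
#' The closed-form maximum-likelihood estimator of the transcript-level
#' rate under fixed sequencing preferences:
#' `mu = sum_j n_j / sum_j exp(alpha) * affinity_j`, both sums over the same
#' eligible positions (full unambiguous context surviving the preprocessing
#' mask). With constant preference this reduces to mean coverage divided by
#' that preference.
#'
#' @param track A [transcript_track()].
#' @param params Fitted [stacking_params()].
#' @param alpha Intercept used in the denominator; defaults to
#'   `params$alpha`.
#' @return One-row data frame: `transcript_id`, `mu`, `n_positions_used`,
#'   `total_counts`.
#' @export
#' @examples
#' # counts (1,2,3,4) at preference 0.5 everywhere -> mu = 10 / 2 = 5
estimate_abundance <- function(track, params, alpha = params$alpha) {
  ev <- track_eval(track, params)
  if (length(ev$n) == 0L)
    sb_stop(sprintf("transcript %s has no eligible position",
                    track$transcript_id), "stackbias_estimation_error")
  denom <- sum(exp(alpha) * ev$affinity)
  if (denom <= 0)
    sb_stop("zero denominator in abundance estimate",
            "stackbias_estimation_error")
  data.frame(transcript_id = track$transcript_id,
             mu = sum(ev$n) / denom,
             n_positions_used = length(ev$n),
             total_counts = sum(ev$n))
}

#' Abundance table for a whole dataset
#'
#' Applies [estimate_abundance()] to every track and appends the RPKM
#' baseline computed with the dataset's library size.
#'
#' @param dataset A [track_dataset()].
#' @inheritParams estimate_abundance
#' @return Data frame with one row per transcript: `transcript_id`, `mu`,
#'   `n_positions_used`, `total_counts`, `rpkm`.
#' @export
abundance_table <- function(dataset, params, alpha = params$alpha) {
  stopifnot(inherits(dataset, "track_dataset"))
  rows <- do.call(rbind, lapply(dataset$tracks, estimate_abundance,
                                params = params, alpha = alpha))
  rows$rpkm <- rpkm(vapply(dataset$tracks, `[[`, numeric(1), "total_reads"),
                    vapply(dataset$tracks, function(t) nchar(t$sequence),
                           numeric(1)),
                    dataset$library_size)
  rownames(rows) <- NULL
  rows
}

#' Reads per kilobase per million mapped reads
#'
#' `10^9 * C / (N_lib * L)` for `C` reads on a transcript of length `L` bp
#' in a library of `N_lib` mapped reads: the classical length- and
#' depth-normalized baseline.
#'
#' @param total_transcript_reads Reads mapped to the transcript (`C`).
#' @param transcript_length Transcript length in bp (`L`), > 0.
#' @param library_size Total mapped reads (`N_lib`), > 0.
#' @return Numeric vector.
#' @export
#' @examples
#' rpkm(1000, 2000, 1e7) # 50
rpkm <- function(total_transcript_reads, transcript_length, library_size) {
  if (any(transcript_length <= 0))
    sb_stop("transcript_length must be positive", "stackbias_bad_argument")
  if (any(library_size <= 0))
    sb_stop("library_size must be positive", "stackbias_bad_argument")
  1e9 * total_transcript_reads / (library_size * transcript_length)
}

#' Spearman rank correlation between estimates and a gold standard
#'
#' Intersects the two named vectors and returns Spearman's rank correlation
#' (average ranks for ties) over the shared identifiers. The shared-set
#' size is attached as attribute `n_shared`.
#'
#' @param estimates,gold Named numeric vectors.
#' @return Correlation in `[-1, 1]` with attribute `n_shared`.
#' @export
rank_correlation <- function(estimates, gold) {
  shared <- intersect(names(estimates), names(gold))
  if (length(shared) < 3L)
    sb_stop("fewer than 3 shared identifiers: correlation undefined",
            "stackbias_correlation_undefined")
  out <- stats::cor(estimates[shared], gold[shared], method = "spearman")
  attr(out, "n_shared") <- length(shared)
  out
}

#' Drop transcripts below an RPKM threshold
#'
#' Retains entries whose RPKM is at least `threshold` (0.1 reproduces the
#' usual low-expression filter before gold-standard comparisons).
#'
#' @param estimates Named numeric vector of abundance estimates.
#' @param rpkm_values Named numeric vector of RPKM values (same names).
#' @param threshold Non-negative cutoff; default 0.1.
#' @return Filtered `estimates`, with attributes `n_removed` and
#'   `n_retained`.
#' @export
filter_low_expression <- function(estimates, rpkm_values, threshold = 0.1) {
  stopifnot(threshold >= 0)
  keep <- names(estimates)[names(estimates) %in%
                             names(rpkm_values)[rpkm_values >= threshold]]
  out <- estimates[keep]
  if (length(out) == 0L)
    warning("all transcripts fall below the RPKM threshold", call. = FALSE)
  attr(out, "n_removed") <- length(estimates) - length(out)
  attr(out, "n_retained") <- length(out)
  out
}
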