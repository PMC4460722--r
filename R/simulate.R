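#' Simulate random transcript sequences
#'
#' I.i.d. nucleotides with `P(G) + P(C) = gc_content`, the G/C and A/T
#' probabilities split evenly. Sequences carry no Markov structure by
#' default, so any count structure in downstream simulations is
#' attributable solely to the planted energy model; set `markov_order = 1`
#' with a `markov_bias` to add first-order dependence for robustness tests.
#'
#' @param n_transcripts Number of sequences.
#' @param length Length of each sequence (scalar or vector recycled to
#'   `n_transcripts`).
#' @param gc_content GC fraction in (0, 1); scalar or per-transcript
#'   vector (a gradient of GC contents makes composition-driven bias
#'   visible in abundance comparisons).
#' @param seed Integer seed; same seed, same sequences.
#' @param markov_order 0 (default, i.i.d.) or 1.
#' @param markov_bias For `markov_order = 1`, multiplicative boost applied
#'   to the probability of repeating the previous base (default 2).
#' @return Named character vector `tx001, tx002, ...`.
#' @export
simulate_sequences <- function(n_transcripts, length, gc_content = 0.5,
                               seed = 1L, markov_order = 0L,
                               markov_bias = 2) {
  if (any(gc_content <= 0) || any(gc_content >= 1))
    sb_stop("gc_content must lie strictly in (0, 1)", "stackbias_bad_argument")
  if (n_transcripts == 0L) return(stats::setNames(character(0), character(0)))
  length <- rep_len(length, n_transcripts)
  gc_content <- rep_len(gc_content, n_transcripts)
  bases <- c("A", "C", "G", "T")
  seqs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_transcripts), function(i) {
      p <- c((1 - gc_content[i]) / 2, gc_content[i] / 2,
             gc_content[i] / 2, (1 - gc_content[i]) / 2)
      if (markov_order == 0L) {
        paste(sample(bases, length[i], replace = TRUE, prob = p),
              collapse = "")
      } else {
        x <- integer(length[i])
        x[1L] <- sample.int(4L, 1L, prob = p)
        for (j in seq_len(length[i] - 1L)) {
          q <- p
          q[x[j]] <- q[x[j]] * markov_bias
          x[j + 1L] <- sample.int(4L, 1L, prob = q / sum(q))
        }
        paste(bases[x], collapse = "")
      }
    }, character(1))
  })
  names(seqs) <- sprintf("tx%03d", seq_len(n_transcripts))
  seqs
}

#' A GC-favouring planted parameter set
#'
#' A convenient non-uniform truth for simulations: the stacking energy of a
#' dinucleotide grows with its G/C content (`base + strength` per G or C),
#' so GC-rich contexts have higher energy and lower affinity, and the
#' positional weights follow a triangular profile peaking at the read-start
#' base (positions near the start position influence the preference most,
#' echoing the shape recovered from real libraries). Weights are normalised
#' to sum to 1.
#'
#' @param window_size Even integer >= 4 (default 40).
#' @param strength Energy increment per G/C base in the dinucleotide
#'   (default 1.5).
#' @param base Baseline energy of an A/T-only dinucleotide (default 0.3).
#' @param alpha Intercept (default 0).
#' @return A [stacking_params()] object.
#' @export
gc_bias_params <- function(window_size = 40L, strength = 1.5, base = 0.3,
                           alpha = 0) {
  gc_count <- vapply(strsplit(DINUCLEOTIDES, ""), function(b)
    sum(b %in% c("C", "G")), numeric(1))
  eps <- base + strength * gc_count
  names(eps) <- DINUCLEOTIDES
  k <- window_size - 1L
  focal <- window_size %/% 2L
  w <- pmax(1 - abs(seq_len(k) - focal) / focal, 0.05)
  w <- w / sum(w)
  stacking_params(eps, w, alpha = alpha, window_size = window_size)
}

#' Ground truth for a count simulation
#'
#' Bundles planted parameters, per-transcript log-abundances and sequences
#' with the seed that generated them.
#'
#' @param params A [stacking_params()] (`w*`, `eps*`, `alpha*`).
#' @param v_true Named numeric of true log-abundances `v_i`.
#' @param sequences Named character vector of transcript sequences (names
#'   matching `v_true`).
#' @param seed Integer seed; counts drawn from this truth use `seed + 1`
#'   so they are independent of the sequence draw.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(params, v_true, sequences, seed) {
  stopifnot(inherits(params, "stacking_params"))
  if (!setequal(names(v_true), names(sequences)))
    sb_stop("v_true and sequences must share names", "stackbias_bad_argument")
  if (any(!is.finite(v_true)))
    sb_stop("v_true must be finite", "stackbias_bad_argument")
  structure(list(params = params,
                 v_true = v_true[names(sequences)],
                 sequences = sequences,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

#' One-call simulation truth with planted bias
#'
#' Draws sequences with [simulate_sequences()] and log-abundances
#' `v_i ~ Uniform(v_range[1], v_range[2])`, attaching the given (default
#' GC-favouring) parameter set. Defaults emulate a small deep-coverage
#' study: 50 transcripts of 1000 nt, `alpha* = 0`, abundances between 1 and
#' 20 expected starts per position before preference.
#'
#' @param n_transcripts,length,gc_content,seed Passed to
#'   [simulate_sequences()].
#' @param v_range Range of true `v_i` (natural-log scale); default
#'   `c(log(1), log(20))`.
#' @param params Planted [stacking_params()]; default [gc_bias_params()].
#' @return A [sim_truth()].
#' @export
simulate_truth <- function(n_transcripts = 50L, length = 1000L,
                           gc_content = 0.5, seed = 1L,
                           v_range = c(log(1), log(20)),
                           params = gc_bias_params()) {
  seqs <- simulate_sequences(n_transcripts, length, gc_content, seed)
  v <- withr::with_seed(as.integer(seed) + 2L,
                        stats::runif(n_transcripts, v_range[1], v_range[2]))
  names(v) <- names(seqs)
  sim_truth(params, v, seqs, seed)
}

#' Simulate per-position read-start counts from a truth
#'
#' For every position with a full unambiguous context window, draws
#' `n_ij ~ Poisson(exp(v_i + alpha*) * affinity_ij)`; positions without
#' full context get zero counts. Deterministic given the truth's seed.
#'
#' @param truth A [sim_truth()].
#' @return A [track_dataset()] with one track per transcript.
#' @export
simulate_counts <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  rate_cap <- 1e9
  profiles <- lapply(names(truth$sequences), function(id) {
    prof <- affinity_profile(truth$sequences[[id]], truth$params, id)
    rate <- exp(truth$v_true[[id]] + truth$params$alpha) * prof$affinity
    if (any(!is.finite(rate)) || any(rate > rate_cap))
      sb_stop(sprintf("Poisson rate overflow on transcript %s", id),
              "stackbias_bad_argument")
    list(id = id, position = prof$position, rate = rate)
  })
  tracks <- withr::with_seed(truth$seed + 1L, {
    lapply(profiles, function(p) {
      L <- nchar(truth$sequences[[p$id]])
      counts <- numeric(L)
      counts[p$position + 1L] <- stats::rpois(length(p$rate), p$rate)
      transcript_track(p$id, truth$sequences[[p$id]], counts)
    })
  })
  track_dataset(tracks)
}

#' Write a SAM + FASTA fixture realising a count dataset
#'
#' Emits one forward-strand, full-match alignment record per simulated read
#' start (a read of `read_length` bases, truncated at the transcript end),
#' plus the matching FASTA. Running [counts_from_alignments()] on the pair
#' reproduces the input counts exactly.
#'
#' @param dataset A [track_dataset()].
#' @param read_length Read length in bp (default 25); must not exceed the
#'   shortest transcript.
#' @param sam_path,fasta_path Output paths.
#' @return Invisibly, `list(sam = sam_path, fasta = fasta_path)`.
#' @export
make_sam_fixture <- function(dataset, read_length = 25L,
                             sam_path, fasta_path) {
  stopifnot(inherits(dataset, "track_dataset"))
  lens <- vapply(dataset$tracks, function(t) nchar(t$sequence), integer(1))
  if (read_length > min(lens))
    sb_stop("read_length exceeds the shortest transcript",
            "stackbias_bad_argument")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(dataset$tracks), lens))
  per_track <- lapply(dataset$tracks, function(t) {
    L <- nchar(t$sequence)
    pos <- rep(seq_len(L), t$counts)        # one entry per read
    if (length(pos) == 0L) return(character(0))
    len <- pmin(read_length, L - pos + 1L)
    sprintf("\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
            t$transcript_id, pos, len,
            substr(rep(t$sequence, length(pos)), pos, pos + len - 1L),
            strrep("I", len))
  })
  records <- unlist(per_track, use.names = FALSE)
  if (length(records) > 0L)
    records <- paste0(sprintf("r%06d", seq_along(records)), records)
  writeLines(c(header, records), sam_path)
  write_fasta(vapply(dataset$tracks, `[[`, character(1), "sequence"),
              fasta_path)
  invisible(list(sam = sam_path, fasta = fasta_path))
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
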