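#' A transcript's sequence with per-position read-start counts
#'
#' `counts[j]` is the number of reads whose leftmost aligned base falls on
#' the j-th position (1-based internally; 0-based at every file boundary).
#' A logical `keep` mask carries preprocessing decisions (end trimming,
#' zero-count removal) as a view: masked positions are excluded from fitting
#' and evaluation but underlying coordinates are untouched, so sequence
#' contexts stay correct.
#'
#' @param transcript_id Identifier.
#' @param sequence Nucleotide string.
#' @param counts Non-negative integer vector, same length as `sequence`.
#' @param keep Optional logical mask, same length; default all `TRUE`.
#' @return An object of class `transcript_track` with fields
#'   `transcript_id`, `sequence`, `counts`, `keep`, `total_reads`.
#' @export
transcript_track <- function(transcript_id, sequence, counts, keep = NULL) {
  L <- nchar(sequence)
  counts <- as.numeric(counts)
  if (length(counts) != L)
    sb_stop("counts length must equal sequence length",
            "stackbias_bad_argument")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    sb_stop("counts must be non-negative integers", "stackbias_bad_argument")
  if (is.null(keep)) keep <- rep(TRUE, L)
  if (length(keep) != L || anyNA(keep))
    sb_stop("keep mask must be logical of sequence length",
            "stackbias_bad_argument")
  structure(list(transcript_id = as.character(transcript_id),
                 sequence = toupper(sequence),
                 counts = counts,
                 keep = as.logical(keep),
                 total_reads = sum(counts)),
            class = "transcript_track")
}

#' @export
print.transcript_track <- function(x, ...) {
  cat(sprintf("transcript_track %s: %d nt, %d read starts, %d positions kept\n",
              x$transcript_id, nchar(x$sequence), x$total_reads,
              sum(x$keep)))
  invisible(x)
}

#' Bundle transcript tracks into a dataset
#'
#' @param tracks List of [transcript_track()] objects with unique ids.
#' @param library_size Total mapped reads in the library; defaults to the
#'   sum of track totals. Must be at least that sum.
#' @return An object of class `track_dataset`: list with `tracks` (named
#'   list) and `library_size`.
#' @export
track_dataset <- function(tracks, library_size = NULL) {
  stopifnot(all(vapply(tracks, inherits, logical(1), "transcript_track")))
  ids <- vapply(tracks, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids))
    sb_stop("transcript ids must be unique", "stackbias_bad_argument")
  names(tracks) <- ids
  total <- sum(vapply(tracks, `[[`, numeric(1), "total_reads"))
  if (is.null(library_size)) library_size <- total
  if (library_size < total)
    sb_stop("library_size smaller than the summed track counts",
            "stackbias_bad_argument")
  structure(list(tracks = tracks, library_size = library_size),
            class = "track_dataset")
}

#' @export
print.track_dataset <- function(x, ...) {
  cat(sprintf("track_dataset: %d transcripts, %d read starts (library size %d)\n",
              length(x$tracks),
              sum(vapply(x$tracks, `[[`, numeric(1), "total_reads")),
              as.integer(x$library_size)))
  invisible(x)
}

#' Apply end trimming and zero-count masking to a track
#'
#' Reproduces the standard preprocessing: mask the first and last
#' `trim_ends` positions and, optionally, every zero-count position. The
#' operation edits the `keep` mask only, never the coordinates, and is
#' idempotent.
#'
#' @param track A [transcript_track()].
#' @param trim_ends Non-negative integer; 20 reproduces the spike-in
#'   protocol.
#' @param drop_zero_positions Mask positions with zero counts as well.
#' @return The track with an updated `keep` mask.
#' @export
preprocess_track <- function(track, trim_ends = 0L,
                             drop_zero_positions = FALSE) {
  stopifnot(inherits(track, "transcript_track"))
  trim_ends <- as.integer(trim_ends)
  if (trim_ends < 0L)
    sb_stop("trim_ends must be >= 0", "stackbias_bad_argument")
  L <- nchar(track$sequence)
  if (2L * trim_ends >= L)
    sb_stop(sprintf("transcript %s shorter than 2 * trim_ends",
                    track$transcript_id), "stackbias_track_excluded")
  keep <- track$keep
  if (trim_ends > 0L) {
    keep[seq_len(trim_ends)] <- FALSE
    keep[seq.int(L - trim_ends + 1L, L)] <- FALSE
  }
  if (drop_zero_positions) keep <- keep & track$counts > 0
  track$keep <- keep
  track
}

#' Select the highest-expressed single-isoform training transcripts
#'
#' Ranks candidate transcripts by mean per-base start count
#' (`total_reads / length`) and returns the top `k`, mirroring the usual
#' training protocol of 100 highest-expressed single-isoform transcripts.
#' Ties break by transcript id (lexicographic). If fewer than `k` qualify,
#' all are returned with a warning.
#'
#' @param dataset A [track_dataset()].
#' @param single_isoform_ids Identifiers eligible for training (single
#'   isoform genes); `NULL` means all transcripts qualify.
#' @param k Number of transcripts to select (default 100).
#' @return Character vector of transcript ids, best first.
#' @export
select_training_set <- function(dataset, single_isoform_ids = NULL,
                                k = 100L) {
  stopifnot(inherits(dataset, "track_dataset"), k >= 1L)
  ids <- names(dataset$tracks)
  if (!is.null(single_isoform_ids)) ids <- intersect(ids, single_isoform_ids)
  if (length(ids) == 0L)
    sb_stop("no transcripts match single_isoform_ids",
            "stackbias_empty_selection")
  score <- vapply(dataset$tracks[ids], function(t)
    t$total_reads / nchar(t$sequence), numeric(1))
  ord <- order(-score, ids)
  ids <- ids[ord]
  if (length(ids) < k) {
    warning(sprintf("only %d transcripts available; k = %d requested",
                    length(ids), k), call. = FALSE)
    return(ids)
  }
  ids[seq_len(k)]
}

#' Read / write per-position count tables as TSV
#'
#' Columns `transcript_id`, `position` (0-based), `count`; every position of
#' every transcript is written, so the table round-trips transcript lengths.
#' Reading requires the transcript sequences (a named character vector, a
#' `Biostrings::DNAStringSet`, or a FASTA path) so that tracks carry their
#' sequence context.
#'
#' @param dataset A [track_dataset()] (or list of tracks).
#' @param path TSV path.
#' @param sequences Named sequences or FASTA path.
#' @param library_size Optional library size for the rebuilt dataset.
#' @return `write_counts_tsv()` returns `path` invisibly;
#'   `read_counts_tsv()` returns a [track_dataset()].
#' @export
write_counts_tsv <- function(dataset, path) {
  tracks <- if (inherits(dataset, "track_dataset")) dataset$tracks else dataset
  tab <- do.call(rbind, lapply(tracks, function(t)
    data.frame(transcript_id = t$transcript_id,
               position = seq_along(t$counts) - 1L,
               count = as.integer(t$counts))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, sequences, library_size = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "integer"))
  sequences <- as_sequence_set(sequences)
  tracks <- lapply(split(tab, tab$transcript_id), function(d) {
    id <- d$transcript_id[1L]
    if (!id %in% names(sequences))
      sb_stop(sprintf("no sequence for transcript '%s'", id),
              "stackbias_reconciliation_error")
    L <- nchar(sequences[[id]])
    counts <- numeric(L)
    if (any(d$position < 0L | d$position >= L))
      sb_stop(sprintf("counts for '%s' reference positions outside 0..%d",
                      id, L - 1L), "stackbias_bad_argument")
    counts[d$position + 1L] <- d$count
    transcript_track(id, sequences[[id]], counts)
  })
  track_dataset(tracks, library_size = library_size)
}

# normalise the many ways of supplying sequences to a named character vector
as_sequence_set <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && !grepl("^[ACGTNacgtn]+$", sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (methods::is(sequences, "XStringSet")) {
    out <- as.character(sequences)
    names(out) <- sub("\\s.*$", "", names(sequences))
    return(out)
  }
  if (!is.character(sequences) || is.null(names(sequences)))
    sb_stop("sequences must be a named character vector, DNAStringSet or FASTA path",
            "stackbias_bad_argument")
  sequences
}
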