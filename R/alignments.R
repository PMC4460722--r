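#' Build per-position read-start counts from a transcriptome alignment
#'
#' Tallies, for every transcript in `fasta`, the number of primary mapped
#' forward-strand alignments whose leftmost aligned base falls on each
#' position. Unmapped, secondary, supplementary, reverse-strand and
#' low-MAPQ records are excluded and tallied in a skip log attached to the
#' result (`attr(x, "skip_log")`). Transcripts with no reads get all-zero
#' tracks. The library size of the returned dataset is the number of primary
#' mapped records on either strand.
#'
#' Alignments must be against transcript sequences (no spliced genome
#' coordinates). SAM input is converted on the fly via
#' [Rsamtools::asBam()].
#'
#' @param alignments Path to a SAM or BAM file.
#' @param fasta Transcript sequences: FASTA path, named character vector or
#'   `DNAStringSet`.
#' @param min_mapq Minimum mapping quality; records below it are skipped
#'   (default 0; missing MAPQ passes).
#' @return A [track_dataset()] with one track per FASTA sequence and a
#'   `skip_log` attribute summarising excluded records.
#' @export
counts_from_alignments <- function(alignments, fasta, min_mapq = 0L) {
  sequences <- as_sequence_set(fasta)
  bam <- alignments
  if (grepl("\\.sam$", alignments, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignments,
                            tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "strand", "pos", "mapq")))[[1L]]
  flag <- res$flag
  n <- length(flag)
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  reverse <- !unmapped & res$strand == "-"
  mapq <- res$mapq
  low_mapq <- !is.na(mapq) & mapq < min_mapq & !unmapped
  accepted <- !unmapped & !secondary & !supplementary & !reverse & !low_mapq

  used_refs <- unique(as.character(res$rname[!unmapped]))
  missing_refs <- setdiff(used_refs, names(sequences))
  if (length(missing_refs) > 0L)
    sb_stop(paste0("alignment references absent from FASTA: ",
                   paste(missing_refs, collapse = ", ")),
            "stackbias_reconciliation_error")

  tracks <- lapply(names(sequences), function(id) {
    L <- nchar(sequences[[id]])
    sel <- accepted & as.character(res$rname) == id
    pos <- res$pos[sel]
    pos <- pos[!is.na(pos) & pos >= 1L & pos <= L]
    transcript_track(id, sequences[[id]], tabulate(pos, nbins = L))
  })
  primary_mapped <- sum(!unmapped & !secondary & !supplementary)
  out <- track_dataset(tracks, library_size = max(primary_mapped,
                                                  sum(accepted)))
  attr(out, "skip_log") <- list(
    total_records = n,
    accepted = sum(accepted),
    unmapped = sum(unmapped),
    secondary = sum(secondary),
    supplementary = sum(supplementary),
    reverse_strand = sum(reverse & !secondary & !supplementary),
    below_min_mapq = sum(low_mapq))
  out
}

#' Write the skip log of an alignment import as plain text
#'
#' @param dataset Result of [counts_from_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_skip_log <- function(dataset, path) {
  log <- attr(dataset, "skip_log")
  if (is.null(log)) sb_stop("dataset has no skip log", "stackbias_bad_argument")
  writeLines(sprintf("%s\t%d", names(log), unlist(log)), path)
  invisible(path)
}
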