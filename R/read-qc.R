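#' Clip low-quality terminal spans from a read
#'
#' Removes the maximal span at each end of the read in which every base has
#' Phred quality `qmax` or less (Q20 corresponds to a 1/100 error rate).
#' Both the 5' and 3' ends are clipped.  A read whose remaining core is
#' shorter than `min_len` bases is discarded.
#'
#' @param seq single base string.
#' @param qual integer vector of Phred scores, one per base.
#' @param qmax clip bases with quality <= `qmax` (default 20).
#' @param min_len minimum retained length (default 36).
#' @return `list(seq=, qual=, clipped=)` for a retained read, or `NULL`
#'   when the core is shorter than `min_len`.
#' @export
clip_terminal <- function(seq, qual, qmax = 20L, min_len = 36L) {
  keep <- qual > qmax
  if (!any(keep)) return(NULL)
  from <- which(keep)[1]
  to <- which(keep)[length(which(keep))]
  if (to - from + 1L < min_len) return(NULL)
  list(seq = substr(seq, from, to),
       qual = qual[from:to],
       clipped = length(qual) - (to - from + 1L))
}

#' Quality-fraction filter
#'
#' A read passes when at least `min_fraction` of its bases have Phred
#' quality `qmin` or higher (boundary inclusive: Q21 counts).  Empty reads
#' fail.
#'
#' @param qual integer vector of Phred scores.
#' @param qmin minimum qualifying quality (default 21).
#' @param min_fraction required fraction of qualifying bases (default 0.90).
#' @return `TRUE` to keep the read, `FALSE` to drop it.
#' @export
fraction_filter <- function(qual, qmin = 21L, min_fraction = 0.90) {
  n <- length(qual)
  if (n == 0L) return(FALSE)
  sum(qual >= qmin) / n >= min_fraction
}

#' Mask low-quality bases with N
#'
#' Replaces every base whose quality is `qmax` or less with `N`; quality
#' values are left unchanged so downstream tools can still see them.
#'
#' @param seq single base string.
#' @param qual integer vector of Phred scores.
#' @param qmax mask bases with quality <= `qmax` (default 20).
#' @return The masked base string.
#' @export
mask_low_quality <- function(seq, qual, qmax = 20L) {
  low <- which(qual <= qmax)
  if (length(low) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[low] <- "N"
  paste(ch, collapse = "")
}

#' Detect single-nucleotide artifact reads
#'
#' Reproduces the FASTX-toolkit "artifact" purge as: a read whose bases,
#' ignoring N, are all one nucleotide.  This is a stand-in rule — the
#' original tool's exact definition is undocumented — but such degenerate
#' reads are unambiguous artifacts under any reading.
#'
#' @param seq single base string.
#' @return `TRUE` when the read is an artifact.
#' @export
is_artifact <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch <- ch[ch != "N"]
  length(unique(ch)) <= 1L
}

#' Run the full read-cleaning chain
#'
#' Applies, in order: quality-offset conversion (when the input still
#' carries raw ASCII codes), artifact purging, terminal clipping at Q20,
#' the 36-base minimum-length filter, the 90 percent Q>=21 fraction
#' filter, and masking of residual bases at Q<=20.  The fraction filter is
#' evaluated before masking, so a retained read has at most 10 percent of
#' its bases masked.
#'
#' @param reads read-set tibble ([read_fastq()] output or [read_set()]).
#' @param offset quality encoding offset (33 or 64); only used when the
#'   input's `qual` column still holds raw ASCII codes.
#' @param clip_qmax terminal-clip threshold (default 20).
#' @param min_len minimum post-clip length (default 36).
#' @param frac_qmin,min_fraction fraction-filter parameters (defaults 21
#'   and 0.90).
#' @param mask_qmax masking threshold (default 20).
#' @return `list(reads=, stats=)` where `reads` is the cleaned read set
#'   (order preserved) and `stats` a one-row tibble with columns
#'   `input_reads`, `input_bases`, `retained_reads`, `retained_bases`,
#'   `clipped_bases`, `masked_bases`.
#' @export
qc_pipeline <- function(reads, offset = 33L, clip_qmax = 20L, min_len = 36L,
                        frac_qmin = 21L, min_fraction = 0.90,
                        mask_qmax = 20L) {
  if (identical(attr(reads$qual, "scale"), "ascii")) {
    reads <- convert_quality(reads, offset)
  }
  n_in <- nrow(reads)
  bases_in <- sum(nchar(reads$seq))
  keep <- logical(n_in)
  out_seq <- character(n_in)
  out_qual <- vector("list", n_in)
  clipped <- 0L
  masked <- 0L
  for (i in seq_len(n_in)) {
    if (is_artifact(reads$seq[i])) next
    cl <- clip_terminal(reads$seq[i], reads$qual[[i]], clip_qmax, min_len)
    if (is.null(cl)) next
    if (!fraction_filter(cl$qual, frac_qmin, min_fraction)) next
    keep[i] <- TRUE
    clipped <- clipped + cl$clipped
    masked <- masked + sum(cl$qual <= mask_qmax)
    out_seq[i] <- mask_low_quality(cl$seq, cl$qual, mask_qmax)
    out_qual[[i]] <- cl$qual
  }
  cleaned <- reads[keep, , drop = FALSE]
  cleaned$seq <- out_seq[keep]
  cleaned$qual <- out_qual[keep]
  stats <- tibble(
    input_reads = n_in,
    input_bases = bases_in,
    retained_reads = nrow(cleaned),
    retained_bases = sum(nchar(cleaned$seq)),
    clipped_bases = clipped,
    masked_bases = masked
  )
  list(reads = cleaned, stats = stats)
}
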