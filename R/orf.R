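#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames `+1,+2,+3` translate the sequence offset by 0, 1 and 2 bases;
#' frames `-1,-2,-3` translate the reverse complement with the same
#' offsets.  Trailing partial codons are dropped, stop codons render as
#' `*`, and N-containing codons as `X`.
#'
#' @param seq nucleotide string.
#' @return Named character vector of six peptides
#'   (`"+1","+2","+3","-1","-2","-3"`); empty strings when the sequence
#'   is shorter than the frame's first codon.
#' @export
six_frame_translate <- function(seq) {
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  if (nchar(seq) < 3L) {
    return(setNames(rep("", 6L), frames))
  }
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    len <- (length(s) - off) %/% 3L * 3L
    if (len < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1L, width = len),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }
  setNames(c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
             one(rev, 0L), one(rev, 1L), one(rev, 2L)), frames)
}

#' Longest open reading frame across six translation frames
#'
#' The ORF is the maximal stop-free peptide substring over all frames; no
#' start codon is required.  Ties are resolved deterministically: frame
#' order `+1,+2,+3,-1,-2,-3`, then leftmost occurrence within the frame.
#'
#' @param frames named character vector of six peptides
#'   ([six_frame_translate()] output).
#' @return `list(frame=, orf=, length=)`; `orf` may be empty when every
#'   frame is all stops.
#' @export
longest_orf <- function(frames) {
  best <- list(frame = names(frames)[1], orf = "", length = 0L)
  for (f in names(frames)) {
    runs <- strsplit(frames[[f]], "*", fixed = TRUE)[[1]]
    if (length(runs) == 0L) next
    lens <- nchar(runs)
    i <- which.max(lens)  # leftmost maximum
    if (lens[i] > best$length) {
      best <- list(frame = f, orf = runs[i], length = lens[i])
    }
  }
  best
}
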