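#' Construct a read set
#'
#' A read set is the package's in-memory representation of sequenced reads:
#' a tibble with one row per read and columns `id` (character), `seq`
#' (nucleotide string over A/C/G/T/N) and `qual` (list column of integer
#' per-base Phred scores, same length as `seq`).  Extra columns (e.g. the
#' provenance columns added by [simulate_reads()]) are carried along
#' untouched.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of base strings.
#' @param qual list of integer vectors of per-base Phred scores.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_set <- function(id = character(), seq = character(), qual = list()) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (length(qual) > 0L) {
    ok <- vapply(seq_along(seq), function(i) {
      length(qual[[i]]) == nchar(seq[i])
    }, logical(1))
    if (!all(ok)) {
      stop("quality length differs from sequence length for read(s): ",
           paste(head(id[!ok], 3), collapse = ", "))
    }
  }
  tibble(id = as.character(id), seq = as.character(seq), qual = qual)
}

#' Read a FASTQ file into a read set with raw ASCII scores
#'
#' Strict four-line-record FASTQ parser (gzip-transparent via R
#' connections).  Quality characters are kept as raw ASCII codes in the
#' `qual` list column; pass the result through [convert_quality()] with the
#' file's declared offset to obtain Phred scores.
#'
#' @param path path to a FASTQ file (may be gzip-compressed).
#' @return A read-set tibble whose `qual` column holds raw ASCII codes
#'   (attribute `scale` set to `"ascii"`).
#' @seealso [convert_quality()], [write_fastq()]
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: number of lines (", length(lines),
         ") is not a multiple of 4 in ", path)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    out <- read_set()
    attr(out$qual, "scale") <- "ascii"
    return(out)
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  if (any(substr(hdr, 1L, 1L) != "@")) {
    stop("malformed FASTQ: header line does not start with '@' in ", path)
  }
  id <- sub("^@", "", sub("\\s.*$", "", hdr))
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(nchar(seqs) != nchar(quals))) {
    bad <- which(nchar(seqs) != nchar(quals))[1]
    stop("malformed FASTQ: sequence/quality length mismatch for read ",
         id[bad])
  }
  qual <- lapply(quals, function(q) as.integer(charToRaw(q)))
  out <- read_set(id, seqs, qual)
  attr(out$qual, "scale") <- "ascii"
  out
}

#' Convert raw ASCII quality codes to Phred scores
#'
#' Subtracts the declared encoding offset (33 for the Sanger/modern
#' Illumina dialect, 64 for the legacy Illumina dialect) from the raw
#' ASCII codes.  Any character below the declared offset is diagnostic of
#' a mis-declared encoding and raises an error naming the offending read.
#'
#' @param reads read-set tibble whose `qual` column holds raw ASCII codes
#'   (as produced by [read_fastq()]).
#' @param offset integer, 33 or 64.
#' @return The read set with `qual` holding integer Phred scores.
#' @export
convert_quality <- function(reads, offset = c(33L, 64L)) {
  offset <- as.integer(offset[1])
  if (!offset %in% c(33L, 64L)) stop("offset must be 33 or 64")
  below <- vapply(reads$qual, function(q) any(q < offset), logical(1))
  if (any(below)) {
    stop("malformed FASTQ: quality character below declared offset ",
         offset, " in read ", reads$id[which(below)[1]])
  }
  reads$qual <- lapply(reads$qual, function(q) q - offset)
  attr(reads$qual, "scale") <- "phred"
  reads
}

#' Write a read set to FASTQ
#'
#' @param reads read-set tibble with integer Phred scores in `qual`.
#' @param path output path (a `.gz` suffix writes gzip-compressed).
#' @param offset quality encoding offset, 33 (default) or 64.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  offset <- as.integer(offset)
  if (!offset %in% c(33L, 64L)) stop("offset must be 33 or 64")
  qstr <- vapply(reads$qual, function(q) {
    rawToChar(as.raw(pmin(q, 62L) + offset))
  }, character(1))
  rec <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qstr))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Write named sequences to FASTA
#'
#' Thin wrapper over [Biostrings::writeXStringSet()] accepting a plain
#' named character vector of nucleotide or amino-acid sequences.
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param type `"dna"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path path to a FASTA file.
#' @param type `"dna"` or `"aa"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
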