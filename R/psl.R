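PSL_COLS <- c("matches", "misMatches", "repMatches", "nCount",
              "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
              "strand", "qName", "qSize", "qStart", "qEnd",
              "tName", "tSize", "tStart", "tEnd",
              "blockCount", "blockSizes", "qStarts", "tStarts")

empty_psl <- function() {
  as_tibble(setNames(
    c(rep(list(integer()), 8), list(character()), list(character()),
      rep(list(integer()), 3), list(character()),
      rep(list(integer()), 4), rep(list(character()), 3)),
    PSL_COLS))
}

#' Read a headerless 21-column PSL alignment file
#'
#' PSL is Blat's tab-separated alignment format; block coordinates are
#' 0-based half-open.  The standard 5-line `psLayout` header, if present,
#' is skipped.
#'
#' @param path path to a PSL file.
#' @return Tibble with the 21 standard PSL columns (`matches`,
#'   `misMatches`, ..., `tStarts`).
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  # tolerate the optional psLayout header block
  is_data <- grepl("^[0-9]+\t", lines)
  lines <- lines[is_data]
  if (length(lines) == 0L) return(empty_psl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    stop("PSL parse error: line ", which(nf != 21L)[1],
         " has ", nf[nf != 21L][1], " columns (expected 21)")
  }
  m <- do.call(rbind, fields)
  int_cols <- c(1:8, 11:13, 15:18)
  df <- as_tibble(setNames(as.data.frame(m, stringsAsFactors = FALSE),
                           PSL_COLS))
  for (j in int_cols) df[[j]] <- as.integer(df[[j]])
  df
}

#' Write alignments as headerless PSL
#'
#' @param psl tibble with the 21 PSL columns (see [read_psl()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psl <- function(psl, path) {
  stopifnot(all(PSL_COLS %in% names(psl)))
  write.table(psl[, PSL_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Exact-substring alignment of reads against reference sequences
#'
#' A deliberately naive aligner used to build PSL fixtures for the
#' depletion and expression-counting stages: each read is reported
#' against every reference in which its full sequence occurs as an exact
#' forward-strand substring (one PSL row per occurrence site is not
#' needed downstream, so only the first site per reference is reported).
#' Reads containing N never match.  This is fixture plumbing, not a
#' replacement for a real aligner.
#'
#' @param reads read-set tibble.
#' @param refs named character vector of reference nucleotide sequences.
#' @return PSL tibble of exact full-length matches.
#' @export
align_exact <- function(reads, refs) {
  stopifnot(!is.null(names(refs)))
  if (nrow(reads) == 0L || length(refs) == 0L) return(empty_psl())
  widths <- nchar(reads$seq)
  rows <- vector("list", length(refs))
  # one matchPDict sweep per reference; constant-width dictionaries only,
  # so group reads by width
  for (w in unique(widths)) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(
      gsub("N", "A", reads$seq[idx])))  # placeholder; N reads filtered below
    has_n <- grepl("N", reads$seq[idx], fixed = TRUE)
    for (r in seq_along(refs)) {
      hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(refs[[r]]))
      starts <- Biostrings::startIndex(hits)
      hit_i <- which(lengths(starts) > 0L & !has_n)
      if (length(hit_i) == 0L) next
      t_start <- vapply(starts[hit_i], `[[`, integer(1), 1L) - 1L
      rows[[r]] <- rbind(rows[[r]], data.frame(
        i = idx[hit_i], ref = names(refs)[r], tStart = t_start,
        stringsAsFactors = FALSE))
    }
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) return(empty_psl())
  w <- nchar(reads$seq[rows$i])
  tibble(
    matches = w, misMatches = 0L, repMatches = 0L, nCount = 0L,
    qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L, tBaseInsert = 0L,
    strand = "+", qName = reads$id[rows$i], qSize = w,
    qStart = 0L, qEnd = w,
    tName = rows$ref, tSize = nchar(refs[rows$ref]),
    tStart = rows$tStart, tEnd = rows$tStart + w,
    blockCount = 1L, blockSizes = paste0(w, ","),
    qStarts = "0,", tStarts = paste0(rows$tStart, ",")
  )
}

#' Deplete rRNA-derived reads using PSL alignments
#'
#' Any read with at least one alignment to the rRNA reference whose
#' matched-base count reaches `min_matches` is discarded; all other reads
#' are retained in their original order.  Alignments naming reads absent
#' from the input produce a warning and are ignored.  The matched-base
#' threshold stands in for the aligner's default minimum reportable score
#' and is exposed because the upstream acceptance rule is a configuration
#' choice, not a fixed constant.
#'
#' @param reads read-set tibble.
#' @param psl PSL tibble of alignments of these reads against an rRNA
#'   reference ([read_psl()] / [align_exact()]).
#' @param min_matches minimum `matches` for an alignment to trigger
#'   discard (default 30).
#' @return `list(retained=, discarded=, stats=)`; `stats` has columns
#'   `input_reads`, `retained_reads`, `discarded_reads`,
#'   `retained_bases`.
#' @export
deplete_rrna <- function(reads, psl, min_matches = 30L) {
  hits <- psl[psl$matches >= min_matches, , drop = FALSE]
  unknown <- setdiff(unique(hits$qName), reads$id)
  if (length(unknown) > 0L) {
    warning("ignoring alignments for ", length(unknown),
            " read id(s) not present in the read set")
  }
  bad <- reads$id %in% hits$qName
  list(
    retained = reads[!bad, , drop = FALSE],
    discarded = reads[bad, , drop = FALSE],
    stats = tibble(
      input_reads = nrow(reads),
      retained_reads = sum(!bad),
      discarded_reads = sum(bad),
      retained_bases = sum(nchar(reads$seq[!bad]))
    )
  )
}
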