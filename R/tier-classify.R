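BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore", "ppos", "slen")

#' Parse an extended BLASTX tabular report
#'
#' Reads the 14-column tab-separated dialect
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore ppos slen` (one HSP per line; `ppos` is the percentage
#' of positively-similar aligned residues).  HSPs are grouped into one
#' homology hit per (query, subject) pair, and each query's hits are
#' sorted by best bitscore descending.
#'
#' For minus-frame HSPs BLASTX reports `qstart > qend`; coordinates are
#' normalized so that `q_start < q_end` always holds and the reading
#' frame (computed from the aligned start and the query length) carries
#' the strand sign.
#'
#' @param path path to the tabular report (or a connection).
#' @param query_lengths named integer vector of query (PUT) lengths in
#'   nucleotides, typically `nchar()` of the PUT FASTA; BLAST tabular
#'   output does not carry query lengths.
#' @return Named list: `query_id` -> list of homology hits.  Each hit is
#'   a list with `query_id`, `subject_id`, `query_len`, `subject_len`,
#'   `best_bitscore`, `best_evalue` and `hsps` (tibble with columns
#'   `q_start`, `q_end`, `s_start`, `s_end`, `align_len`, `positives`,
#'   `frame`, `bitscore`, `evalue`).
#' @export
parse_blast_tabular <- function(path, query_lengths) {
  lines <- if (inherits(path, "connection")) readLines(path)
           else readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 14L)) {
    stop("BLAST tabular parse error: line ", which(nf != 14L)[1],
         " has ", nf[nf != 14L][1], " columns (expected 14)")
  }
  m <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(m) <- BLAST_COLS
  for (j in c("pident", "evalue", "bitscore", "ppos")) {
    m[[j]] <- as.numeric(m[[j]])
  }
  for (j in c("length", "mismatch", "gapopen", "qstart", "qend",
              "sstart", "send", "slen")) {
    m[[j]] <- as.integer(m[[j]])
  }
  missing_q <- setdiff(unique(m$qseqid), names(query_lengths))
  if (length(missing_q) > 0L) {
    stop("no query length supplied for: ",
         paste(head(missing_q, 3), collapse = ", "))
  }
  qlen <- as.integer(query_lengths[m$qseqid])
  minus <- m$qstart > m$qend
  qlo <- ifelse(minus, m$qend, m$qstart)
  qhi <- ifelse(minus, m$qstart, m$qend)
  frame <- ifelse(minus,
                  -(((qlen - qhi) %% 3L) + 1L),
                  ((qlo - 1L) %% 3L) + 1L)
  positives <- as.integer(round(m$ppos / 100 * m$length))
  key <- paste(m$qseqid, m$sseqid, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    hit <- list(
      query_id = m$qseqid[idx[1]],
      subject_id = m$sseqid[idx[1]],
      query_len = qlen[idx[1]],
      subject_len = m$slen[idx[1]],
      best_bitscore = max(m$bitscore[idx]),
      best_evalue = min(m$evalue[idx]),
      hsps = tibble(
        q_start = qlo[idx], q_end = qhi[idx],
        s_start = m$sstart[idx], s_end = m$send[idx],
        align_len = m$length[idx], positives = positives[idx],
        frame = as.integer(frame[idx]),
        bitscore = m$bitscore[idx], evalue = m$evalue[idx]
      )
    )
    out[[m$qseqid[idx[1]]]] <- c(out[[m$qseqid[idx[1]]]], list(hit))
  }
  lapply(out, function(hits) {
    bs <- vapply(hits, `[[`, numeric(1), "best_bitscore")
    hits[order(-bs)]
  })
}

#' Select the top-scoring hit for a query
#'
#' The hit with the maximal best bitscore; ties are broken by lower best
#' E-value, then by lexicographically smaller subject id, so the choice
#' is deterministic.
#'
#' @param hits nonempty list of homology hits for one query
#'   ([parse_blast_tabular()] element).
#' @return The winning hit.
#' @export
top_hit <- function(hits) {
  if (length(hits) == 0L) stop("top_hit: empty hit list")
  bs <- vapply(hits, `[[`, numeric(1), "best_bitscore")
  ev <- vapply(hits, `[[`, numeric(1), "best_evalue")
  sid <- vapply(hits, `[[`, character(1), "subject_id")
  ord <- order(-bs, ev, sid)
  hits[[ord[1]]]
}

#' Merged subject coverage of a hit
#'
#' Fraction of the subject protein covered by the union of the hit's HSP
#' subject intervals (overlaps counted once); frames are ignored when
#' merging.
#'
#' @param hit a homology hit.
#' @return Coverage in `[0, 1]`.
#' @export
subject_coverage <- function(hit) {
  ir <- IRanges::reduce(IRanges::IRanges(start = hit$hsps$s_start,
                                         end = hit$hsps$s_end))
  sum(IRanges::width(ir)) / hit$subject_len
}

#' Assign a PUT to a homology tier
#'
#' Tiers are mutually disjoint and assigned by a demotion cascade:
#'
#' * **gold** — the top hit has exactly one HSP, the PUT is at least
#'   300 nt, the subject protein at least 100 aa, at least 75 percent of
#'   aligned residues are positively similar, and the HSP's subject span
#'   (`s_end - s_start + 1`) covers at least 90 percent of the subject
#'   length.
#' * **silver** — otherwise, the PUT is at least 100 nt and the merged
#'   subject coverage over all HSPs is at least 75 percent.
#' * **bronze** — otherwise, the PUT is at least 100 nt and merged
#'   coverage is at least 30 percent.
#' * **none** — otherwise, or when there is no hit.
#'
#' "Hit length" is measured in subject (amino-acid) coordinates since it
#' is compared against the subject protein's length.
#'
#' @param put_id PUT identifier (carried into the result).
#' @param put_len PUT length in nucleotides.
#' @param hit the PUT's top homology hit, or `NULL` for no hit.
#' @return One-row tibble with columns `put_id`, `tier`, `subject_id`,
#'   `coverage`, `positives_frac`, `n_hsps`, `reason`.
#' @export
assign_tier <- function(put_id, put_len, hit = NULL) {
  if (is.null(hit)) {
    return(tibble(put_id = put_id, tier = "none",
                  subject_id = NA_character_, coverage = NA_real_,
                  positives_frac = NA_real_, n_hsps = 0L,
                  reason = "no hit"))
  }
  n_hsps <- nrow(hit$hsps)
  cov <- subject_coverage(hit)
  pos_frac <- sum(hit$hsps$positives) / sum(hit$hsps$align_len)
  span <- hit$hsps$s_end[1] - hit$hsps$s_start[1] + 1L
  gold <- n_hsps == 1L &&
    put_len >= 300L &&
    hit$subject_len >= 100L &&
    pos_frac >= 0.75 &&
    span / hit$subject_len >= 0.90
  tier <- if (gold) "gold"
          else if (put_len >= 100L && cov >= 0.75) "silver"
          else if (put_len >= 100L && cov >= 0.30) "bronze"
          else "none"
  reason <- switch(tier,
    gold = "single HSP, length/subject/positives/span criteria met",
    silver = "merged subject coverage >= 0.75",
    bronze = "merged subject coverage >= 0.30",
    none = "hit below bronze criteria")
  tibble(put_id = put_id, tier = tier, subject_id = hit$subject_id,
         coverage = cov, positives_frac = pos_frac,
         n_hsps = n_hsps, reason = reason)
}

#' Classify a PUT collection into homology tiers
#'
#' Runs [top_hit()] then [assign_tier()] for every PUT; PUTs without any
#' BLASTX record are assigned tier "none".
#'
#' @param hits_by_query [parse_blast_tabular()] output.
#' @param put_lengths named integer vector of PUT lengths (all PUTs, not
#'   just those with hits).
#' @return Tibble with one row per PUT (see [assign_tier()]).
#' @export
classify_tiers <- function(hits_by_query, put_lengths) {
  stopifnot(!is.null(names(put_lengths)))
  rows <- lapply(names(put_lengths), function(q) {
    hit <- if (q %in% names(hits_by_query)) top_hit(hits_by_query[[q]])
           else NULL
    assign_tier(q, as.integer(put_lengths[[q]]), hit)
  })
  dplyr::bind_rows(rows)
}

#' Trim a gold PUT to its aligned CDS and translate it
#'
#' End sequences not incorporated into the BLASTX alignment are trimmed:
#' the CDS is the query span `q_start..q_end` of the single HSP
#' (reverse-complemented first when the frame is negative), any trailing
#' partial codon is dropped, and the CDS is translated under the standard
#' genetic code with internal stops rendered as `*` and N-containing
#' codons as `X`.
#'
#' @param put_seq PUT nucleotide sequence.
#' @param hit the PUT's single-HSP gold top hit.
#' @return `list(put_id=, cds=, protein=, frame=)`.
#' @export
trim_and_translate <- function(put_seq, hit) {
  stopifnot(nrow(hit$hsps) == 1L)
  h <- hit$hsps
  if (h$q_start < 1L || h$q_end > nchar(put_seq)) {
    stop("HSP coordinates outside PUT sequence for ", hit$query_id)
  }
  cds <- substr(put_seq, h$q_start, h$q_end)
  if (h$frame < 0L) {
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds)))
  }
  cds <- substr(cds, 1L, (nchar(cds) %/% 3L) * 3L)
  protein <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "solve",
    no.init.codon = TRUE))
  list(put_id = hit$query_id, cds = cds, protein = protein,
       frame = h$frame)
}
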