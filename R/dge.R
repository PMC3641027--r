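#' Assign reads to PUTs from PSL alignments
#'
#' A read counts toward a PUT only when at least `min_fraction` of its
#' length aligned with perfect sequence identity: zero mismatches within
#' the aligned blocks and matched bases of at least
#' `ceiling(min_fraction * read_length)`.  Among qualifying alignments
#' the winner is the one with the most matched bases; ties are broken by
#' the lexicographically smallest PUT id so assignment is deterministic.
#' Each read is associated with at most one PUT.
#'
#' @param psl PSL tibble of read-vs-PUT alignments ([read_psl()]).
#' @param min_fraction minimum aligned fraction of the read length
#'   (default 0.95).
#' @return Tibble with one row per assigned read: `read_id`, `put_id`,
#'   `matched_bases`, `read_len`.
#' @export
assign_reads <- function(psl, min_fraction = 0.95) {
  cand <- psl[psl$misMatches == 0L &
              psl$matches >= ceiling(min_fraction * psl$qSize), ,
              drop = FALSE]
  if (nrow(cand) == 0L) {
    return(tibble(read_id = character(), put_id = character(),
                  matched_bases = integer(), read_len = integer()))
  }
  cand |>
    dplyr::arrange(.data$qName, dplyr::desc(.data$matches),
                   .data$tName) |>
    dplyr::distinct(.data$qName, .keep_all = TRUE) |>
    dplyr::transmute(read_id = .data$qName, put_id = .data$tName,
                     matched_bases = .data$matches,
                     read_len = .data$qSize)
}

#' Accumulate read counts from PUTs to their NR proteins
#'
#' Counts emanating from multiple PUTs associated with the same NR
#' protein (e.g. isoforms of one gene) are summed onto that protein.
#'
#' @param assignments [assign_reads()] tibble.
#' @param put_to_protein named character vector mapping PUT id to
#'   protein id; must cover every assigned PUT.
#' @return Named integer vector of read counts per protein id.
#' @export
count_to_protein <- function(assignments, put_to_protein) {
  missing <- setdiff(unique(assignments$put_id), names(put_to_protein))
  if (length(missing) > 0L) {
    stop("assigned PUT(s) missing from the PUT-to-protein map: ",
         paste(head(missing, 3), collapse = ", "))
  }
  prot <- put_to_protein[assignments$put_id]
  tab <- table(prot)
  setNames(as.integer(tab), names(tab))
}

#' Normalize counts by the sample's total read count
#'
#' Digital expression counts are normalized relative to the total number
#' of reads pooled within the sample — not the number of assigned reads.
#'
#' @param counts named numeric vector of per-protein counts.
#' @param total_reads total reads in the sample; must be positive and at
#'   least `sum(counts)`.
#' @return Named numeric vector of fractions.
#' @export
normalize_counts <- function(counts, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (total_reads < sum(counts)) {
    stop("total_reads (", total_reads,
         ") is smaller than the summed counts (", sum(counts), ")")
  }
  counts / total_reads
}

#' Rank per-protein expression fold changes between two conditions
#'
#' Normalizes each condition's counts by its own total, then for every
#' protein with a raw count of at least `min_count` in both conditions
#' computes `fold = max(normalized) / min(normalized)` and the direction
#' of change with respect to the infected condition (`up` when infected
#' exceeds control; exact ties are reported `up` by convention).
#' Proteins detected in only one condition receive no finite fold and
#' are reported separately as exclusive.
#'
#' @param control_counts,infected_counts named numeric vectors of raw
#'   per-protein counts ([count_to_protein()]).
#' @param control_total,infected_total total reads per condition used
#'   for normalization.
#' @param min_count minimum raw count in both conditions for a ranked
#'   fold (default 1).
#' @return `list(ranked=, exclusive=)`.  `ranked` is a tibble sorted by
#'   fold descending with columns `protein_id`, `fold`, `direction`,
#'   `norm_control`, `norm_infected`, `raw_control`, `raw_infected`;
#'   `exclusive` lists proteins detected in one condition only.
#' @export
rank_fold_changes <- function(control_counts, infected_counts,
                              control_total, infected_total,
                              min_count = 1L) {
  ids <- union(names(control_counts), names(infected_counts))
  rc <- setNames(rep(0, length(ids)), ids)
  rc[names(control_counts)] <- control_counts
  ri <- setNames(rep(0, length(ids)), ids)
  ri[names(infected_counts)] <- infected_counts
  nc <- normalize_counts(rc, control_total)
  ni <- normalize_counts(ri, infected_total)
  both <- rc >= min_count & ri >= min_count
  ranked <- tibble(
    protein_id = ids[both],
    fold = unname(pmax(nc[both], ni[both]) / pmin(nc[both], ni[both])),
    direction = unname(ifelse(ni[both] >= nc[both], "up", "down")),
    norm_control = unname(nc[both]),
    norm_infected = unname(ni[both]),
    raw_control = unname(rc[both]),
    raw_infected = unname(ri[both])
  ) |>
    dplyr::arrange(dplyr::desc(.data$fold), .data$protein_id)
  excl <- !both & (rc > 0 | ri > 0)
  exclusive <- tibble(
    protein_id = ids[excl],
    present_in = unname(ifelse(rc[excl] > 0, "control", "infected")),
    raw_control = unname(rc[excl]),
    raw_infected = unname(ri[excl])
  )
  list(ranked = ranked, exclusive = exclusive)
}
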