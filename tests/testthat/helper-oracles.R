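# Independent oracle implementations, written as direct transcriptions of
# the rules and kept structurally separate from the package code paths
# they check.

# --- tier oracle: direct inequalities over the raw hit geometry --------

# interval union length by explicit sweep (no IRanges)
union_len <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e + 1L) {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- starts[i]; cur_e <- ends[i]
    } else {
      cur_e <- max(cur_e, ends[i])
    }
  }
  total + (cur_e - cur_s + 1L)
}

oracle_tier <- function(put_len, subject_len, s_starts, s_ends,
                        positives, align_lens) {
  n_hsp <- length(s_starts)
  pos_ok <- sum(positives) / sum(align_lens) >= 0.75
  span1 <- s_ends[1] - s_starts[1] + 1L
  if (n_hsp == 1L && put_len >= 300L && subject_len >= 100L &&
      pos_ok && span1 / subject_len >= 0.90) {
    return("gold")
  }
  cov <- union_len(s_starts, s_ends) / subject_len
  if (put_len >= 100L && cov >= 0.75) return("silver")
  if (put_len >= 100L && cov >= 0.30) return("bronze")
  "none"
}

# build a homology-hit object directly (bypasses the parser)
make_hit <- function(query_id = "Q", subject_id = "S", query_len,
                     subject_len, s_starts, s_ends, positives,
                     align_lens, q_starts = NULL, q_ends = NULL,
                     frames = NULL, bitscores = NULL,
                     evalues = NULL) {
  n <- length(s_starts)
  if (is.null(q_starts)) q_starts <- rep(1L, n)
  if (is.null(q_ends)) q_ends <- q_starts + 3L * align_lens - 1L
  if (is.null(frames)) frames <- rep(1L, n)
  if (is.null(bitscores)) bitscores <- rep(100, n)
  if (is.null(evalues)) evalues <- rep(1e-20, n)
  list(query_id = query_id, subject_id = subject_id,
       query_len = query_len, subject_len = subject_len,
       best_bitscore = max(bitscores), best_evalue = min(evalues),
       hsps = tibble::tibble(
         q_start = q_starts, q_end = q_ends,
         s_start = as.integer(s_starts), s_end = as.integer(s_ends),
         align_len = as.integer(align_lens),
         positives = as.integer(positives),
         frame = as.integer(frames), bitscore = bitscores,
         evalue = evalues))
}

# random hit geometry spanning the tier decision boundaries
random_tier_case <- function() {
  put_len <- sample(c(99L, 100L, 150L, 299L, 300L, 301L, 500L), 1L)
  subject_len <- sample(c(60L, 99L, 100L, 101L, 200L, 1000L), 1L)
  n_hsp <- sample(1:3, 1L)
  s_starts <- integer(n_hsp); s_ends <- integer(n_hsp)
  lo <- 1L
  for (i in seq_len(n_hsp)) {
    # bias span choices toward the 0.30/0.75/0.90 coverage boundaries
    frac <- sample(c(0.10, 0.299, 0.30, 0.301, 0.5, 0.749, 0.75,
                     0.899, 0.90, 0.95, 1.0), 1L)
    span <- max(1L, round(frac * subject_len / n_hsp))
    if (lo + span - 1L > subject_len) span <- subject_len - lo + 1L
    if (span < 1L) { s_starts <- s_starts[seq_len(i - 1L)]
                     s_ends <- s_ends[seq_len(i - 1L)]; break }
    s_starts[i] <- lo
    s_ends[i] <- lo + span - 1L
    lo <- s_ends[i] + sample(c(0L, 1L, 2L, 10L), 1L) + 1L
    if (lo > subject_len) { s_starts <- s_starts[seq_len(i)]
                            s_ends <- s_ends[seq_len(i)]; break }
  }
  align_lens <- s_ends - s_starts + 1L
  pos_frac <- sample(c(0.5, 0.749, 0.75, 0.751, 0.9, 1.0), 1L)
  positives <- pmin(align_lens, round(pos_frac * align_lens))
  list(put_len = put_len, subject_len = subject_len,
       s_starts = s_starts, s_ends = s_ends,
       positives = positives, align_lens = align_lens)
}

# --- QC oracle: per-read brute-force reimplementation -----------------

oracle_qc_read <- function(seq, qual) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(unique(ch[ch != "N"])) <= 1L) return(NULL)  # artifact
  # clip: scan inward from each end past bases with q <= 20
  from <- 1L
  while (from <= length(qual) && qual[from] <= 20L) from <- from + 1L
  to <- length(qual)
  while (to >= 1L && qual[to] <= 20L) to <- to - 1L
  if (from > to) return(NULL)
  ch <- ch[from:to]; qual <- qual[from:to]
  if (length(ch) < 36L) return(NULL)
  if (sum(qual >= 21L) / length(qual) < 0.90) return(NULL)
  ch[qual <= 20L] <- "N"
  paste(ch, collapse = "")
}

# --- longest-ORF oracle: exhaustive substring scan --------------------

oracle_longest_orf_len <- function(frames) {
  best <- 0L
  for (pep in frames) {
    n <- nchar(pep)
    if (n == 0L) next
    for (i in seq_len(n)) {
      for (j in i:n) {
        sub <- substr(pep, i, j)
        if (!grepl("*", sub, fixed = TRUE)) {
          best <- max(best, j - i + 1L)
        } else {
          break
        }
      }
    }
  }
  best
}

# --- fixture writers --------------------------------------------------

write_domtbl_fixture <- function(path, rows) {
  # rows: data.frame with family_name, family_acc, query_id, evalue,
  # score; pads the remaining hmmscan --domtblout columns
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    paste(rows$family_name[i], rows$family_acc[i], "120",
          rows$query_id[i], "-", "240",
          format(rows$evalue[i]), format(rows$score[i]), "0.1",
          "1", "1", format(rows$evalue[i]), format(rows$evalue[i]),
          format(rows$score[i]), "0.1",
          "1", "100", "5", "110", "2", "115", "0.95",
          "synthetic domain hit")
  }, character(1))
  writeLines(c("#                     --- full sequence ---", lines),
             path)
  path
}

write_pfam2go_fixture <- function(path, df) {
  # df: pfam_acc, pfam_name, go_name, go_id
  writeLines(c("!version date: synthetic",
               sprintf("Pfam:%s %s > GO:%s ; %s", df$pfam_acc,
                       df$pfam_name, df$go_name, df$go_id)), path)
  path
}

write_kegg2go_fixture <- function(path, df) {
  # df: kegg_id, go_name, go_id
  writeLines(c("!version date: synthetic",
               sprintf("KEGG:%s > GO:%s ; %s", df$kegg_id, df$go_name,
                       df$go_id)), path)
  path
}

# small hand-built ontologies for chain / diamond fixtures
chain_ontology <- function() {
  ontology_graph(
    tibble::tibble(
      id = c("GO:0008150", "GO:0000001", "GO:0000002", "GO:0000003"),
      name = c("biological_process", "A", "B", "C"),
      namespace = rep("biological_process", 4)),
    list("GO:0000001" = "GO:0008150",
         "GO:0000002" = "GO:0000001",
         "GO:0000003" = "GO:0000002"))
}

diamond_ontology <- function() {
  ontology_graph(
    tibble::tibble(
      id = c("GO:0008150", "GO:0000011", "GO:0000012", "GO:0000020"),
      name = c("biological_process", "A1", "A2", "C"),
      namespace = rep("biological_process", 4)),
    list("GO:0000011" = "GO:0008150",
         "GO:0000012" = "GO:0008150",
         "GO:0000020" = c("GO:0000011", "GO:0000012")))
}
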