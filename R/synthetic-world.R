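# All generator randomness flows through a single integer seed; the
# caller's RNG state is saved and restored.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# fixed, deterministic codon per amino acid (alphabetically first codon)
# so back-translated frames are exact and BLAST-record geometry is
# computable without an aligner
codon_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  vapply(unique(gc), function(aa) sort(names(gc)[gc == aa])[1],
         character(1))
})

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

#' Back-translate a peptide with a fixed codon choice
#'
#' Every amino acid maps to one fixed codon (the alphabetically first
#' codon of the standard genetic code), so translation of the result
#' recovers the input exactly and alignment geometry is fully
#' deterministic.
#'
#' @param peptide amino-acid string.
#' @return Nucleotide string of length `3 * nchar(peptide)`.
#' @export
back_translate <- function(peptide) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  paste(codon_by_aa[aa], collapse = "")
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# largest-remainder apportionment of n into named fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

synthetic_bitscore <- function(positives) round(2 * positives + 40)

#' Generate a synthetic transcriptome world with planted ground truth
#'
#' Builds a small protein reference and a transcript collection in which
#' every transcript carries a planted tier destiny (`gold`, `silver`,
#' `bronze` or `none`) realized by construction:
#'
#' * **gold** transcripts back-translate a single contiguous region
#'   covering at least 90 percent of a protein of at least 100 aa, are at
#'   least 300 nt, and are emitted as a single HSP with a positives
#'   fraction of at least 0.75; about half are placed on the minus
#'   strand.
#' * **silver** transcripts either split their protein match into two
#'   HSPs (jointly covering at least 75 percent — gold-disqualified by
#'   HSP count) or derive from a protein shorter than 100 aa with a PUT
#'   length below 300 nt.
#' * **bronze** transcripts cover between 30 and 60 percent of their
#'   protein.
#' * **none** transcripts are random sequence and emit no BLASTX record.
#'
#' Two-condition transcript abundances are generated such that the
#' requested fold changes hold exactly on the abundance scale; all other
#' transcripts share one common background fold absorbing the
#' renormalization.
#'
#' @param n_proteins number of reference proteins.
#' @param n_transcripts number of transcripts (PUTs).
#' @param tier_mix named fractions over
#'   `c("gold","silver","bronze","none")`; must sum to 1.
#' @param planted_folds optional numeric vector of abundance fold
#'   changes (infected / control) planted on the first
#'   `length(planted_folds)` gold transcripts.
#' @param seed integer seed; worlds are byte-identical for equal seeds.
#' @return A `synthetic_world` list: `proteins`, `transcripts` (tibbles),
#'   `hsps` (per-transcript planted alignment geometry),
#'   `abundances$control` / `abundances$infected` (named fractions
#'   summing to 1), `planted_folds` (named by transcript id),
#'   `put_to_protein`, `rrna_reference`, `seed`.
#' @export
make_world <- function(n_proteins = 20L, n_transcripts = 40L,
                       tier_mix = c(gold = 0.4, silver = 0.2,
                                    bronze = 0.2, none = 0.2),
                       planted_folds = NULL, seed = 1L) {
  tiers <- c("gold", "silver", "bronze", "none")
  if (is.null(names(tier_mix)) || !all(names(tier_mix) %in% tiers)) {
    stop("tier_mix must be named with gold/silver/bronze/none")
  }
  mix <- setNames(rep(0, 4L), tiers)
  mix[names(tier_mix)] <- tier_mix
  if (abs(sum(mix) - 1) > 1e-9 || any(mix < 0)) {
    stop("tier_mix fractions must be nonnegative and sum to 1")
  }
  if (n_proteins < 1L || n_transcripts < 1L) {
    stop("counts must be positive")
  }
  with_seed(seed, {
    prot_len <- sample(100:250, n_proteins, replace = TRUE)
    proteins <- tibble(
      id = sprintf("P%04d", seq_len(n_proteins)),
      seq = vapply(prot_len, rand_protein, character(1)),
      length = as.integer(prot_len)
    )
    counts <- apportion(n_transcripts, mix)
    destiny <- rep(tiers, counts)
    tx_id <- sprintf("T%04d", seq_len(n_transcripts))
    tx_seq <- character(n_transcripts)
    tx_prot <- rep(NA_character_, n_transcripts)
    hsps <- list()
    big <- which(proteins$length >= 100L)
    used <- integer(0)  # transcripts take distinct source proteins
                        # while any remain: with one fixed codon per
                        # amino acid, two transcripts from one protein
                        # share exact nucleotide sequence, which would
                        # cross-map reads and dilute planted folds
    for (i in seq_len(n_transcripts)) {
      d <- destiny[i]
      if (d == "none") {
        tx_seq[i] <- rand_dna(sample(150:400, 1L))
        next
      }
      if (d == "silver" && i %% 2L == 0L) {
        # short-PUT silver variant: its own sub-100-aa protein
        L <- sample(60:90, 1L)
        pid <- sprintf("P%04d_s%02d", n_proteins + 1L, i)
        pseq <- rand_protein(L)
        proteins <- dplyr::bind_rows(
          proteins, tibble(id = pid, seq = pseq, length = L))
      } else {
        pool <- setdiff(big, used)
        if (length(pool) == 0L) pool <- big
        p <- pool[sample.int(length(pool), 1L)]
        used <- c(used, p)
        pid <- proteins$id[p]
        pseq <- proteins$seq[p]
        L <- proteins$length[p]
      }
      tx_prot[i] <- pid
      if (d == "gold") {
        span <- max(ceiling(0.90 * L),
                    floor(runif(1, 0.92, 1.0) * L))
        span <- min(span, L)
        s_start <- sample.int(L - span + 1L, 1L)
        cds <- back_translate(substr(pseq, s_start, s_start + span - 1L))
        u5 <- sample(10:80, 1L); u3 <- sample(10:80, 1L)
        if (3L * span + u5 + u3 < 300L) u3 <- 300L - 3L * span - u5
        seq <- paste0(rand_dna(u5), cds, rand_dna(u3))
        q_lo <- u5 + 1L; q_hi <- u5 + 3L * span
        minus <- runif(1) < 0.5
        if (minus) {
          len <- nchar(seq)
          seq <- revcomp_chr(seq)
          tmp <- q_lo
          q_lo <- len - q_hi + 1L
          q_hi <- len - tmp + 1L
        }
        pos <- as.integer(round(runif(1, 0.78, 1.0) * span))
        hsps[[tx_id[i]]] <- tibble(
          q_start = if (minus) q_hi else q_lo,
          q_end = if (minus) q_lo else q_hi,
          s_start = s_start, s_end = s_start + span - 1L,
          align_len = span, positives = pos,
          bitscore = synthetic_bitscore(pos))
        tx_seq[i] <- seq
      } else if (d == "silver" && i %% 2L != 0L) {
        # two-HSP silver: joint coverage >= 0.75, gap between blocks
        cov <- runif(1, 0.76, 0.88)
        gap <- sample(5:min(15L, max(5L, floor(0.08 * L))), 1L)
        total <- ceiling(cov * L)
        span1 <- floor(total / 2); span2 <- total - span1
        s1 <- sample.int(max(1L, L - total - gap), 1L)
        s1e <- s1 + span1 - 1L
        s2 <- s1e + gap + 1L
        s2e <- s2 + span2 - 1L
        cds1 <- back_translate(substr(pseq, s1, s1e))
        cds2 <- back_translate(substr(pseq, s2, s2e))
        u5 <- sample(10:40, 1L); u3 <- sample(10:40, 1L)
        linker <- sample(7:20, 1L)
        seq <- paste0(rand_dna(u5), cds1, rand_dna(linker), cds2,
                      rand_dna(u3))
        p1 <- as.integer(round(runif(1, 0.76, 1.0) * span1))
        p2 <- as.integer(round(runif(1, 0.76, 1.0) * span2))
        hsps[[tx_id[i]]] <- tibble(
          q_start = c(u5 + 1L, u5 + 3L * span1 + linker + 1L),
          q_end = c(u5 + 3L * span1,
                    u5 + 3L * span1 + linker + 3L * span2),
          s_start = c(s1, s2), s_end = c(s1e, s2e),
          align_len = c(span1, span2), positives = c(p1, p2),
          bitscore = synthetic_bitscore(c(p1, p2)))
        tx_seq[i] <- seq
      } else if (d == "silver") {
        # short-PUT silver: coverage >= 0.78 of a < 100 aa protein,
        # PUT < 300 nt
        span <- ceiling(runif(1, 0.78, 0.95) * L)
        s_start <- sample.int(L - span + 1L, 1L)
        cds <- back_translate(substr(pseq, s_start, s_start + span - 1L))
        u5 <- sample(5:12, 1L); u3 <- sample(5:12, 1L)
        seq <- paste0(rand_dna(u5), cds, rand_dna(u3))
        stopifnot(nchar(seq) < 300L, nchar(seq) >= 100L)
        pos <- as.integer(round(runif(1, 0.78, 1.0) * span))
        hsps[[tx_id[i]]] <- tibble(
          q_start = u5 + 1L, q_end = u5 + 3L * span,
          s_start = s_start, s_end = s_start + span - 1L,
          align_len = span, positives = pos,
          bitscore = synthetic_bitscore(pos))
        tx_seq[i] <- seq
      } else { # bronze: coverage in [0.31, 0.60)
        span <- max(ceiling(0.31 * L),
                    floor(runif(1, 0.32, 0.60) * L))
        s_start <- sample.int(L - span + 1L, 1L)
        cds <- back_translate(substr(pseq, s_start, s_start + span - 1L))
        u5 <- sample(10:60, 1L); u3 <- sample(10:60, 1L)
        seq <- paste0(rand_dna(u5), cds, rand_dna(u3))
        pos <- as.integer(round(runif(1, 0.78, 1.0) * span))
        hsps[[tx_id[i]]] <- tibble(
          q_start = u5 + 1L, q_end = u5 + 3L * span,
          s_start = s_start, s_end = s_start + span - 1L,
          align_len = span, positives = pos,
          bitscore = synthetic_bitscore(pos))
        tx_seq[i] <- seq
      }
    }
    transcripts <- tibble(
      id = tx_id, seq = tx_seq, length = nchar(tx_seq),
      protein_id = tx_prot, destiny = destiny
    )
    # abundances: background weights, planted transcripts at controlled
    # control fractions so infected/control equals the requested fold
    # exactly
    folds <- setNames(numeric(0), character(0))
    ctl <- setNames(runif(n_transcripts, 0.5, 1.5), tx_id)
    ctl <- ctl / sum(ctl)
    inf <- ctl
    if (!is.null(planted_folds)) {
      if (any(planted_folds <= 0)) stop("planted folds must be positive")
      gold_ids <- tx_id[destiny == "gold"]
      if (length(planted_folds) > length(gold_ids)) {
        stop("more planted folds than gold transcripts")
      }
      tgt <- gold_ids[seq_along(planted_folds)]
      folds <- setNames(as.numeric(planted_folds), tgt)
      c_t <- pmin(0.01, 0.4 / folds)
      if (sum(c_t * folds) >= 1) stop("planted folds too large to embed")
      rest <- setdiff(tx_id, tgt)
      ctl[tgt] <- c_t
      ctl[rest] <- (1 - sum(c_t)) * ctl[rest] / sum(ctl[rest])
      inf <- ctl
      inf[tgt] <- c_t * folds
      inf[rest] <- (1 - sum(inf[tgt])) * ctl[rest] / sum(ctl[rest])
    }
    stopifnot(abs(sum(ctl) - 1) < 1e-9, abs(sum(inf) - 1) < 1e-9)
    put_to_protein <- setNames(tx_prot, tx_id)
    structure(list(
      proteins = proteins, transcripts = transcripts, hsps = hsps,
      abundances = list(control = ctl, infected = inf),
      planted_folds = folds,
      put_to_protein = put_to_protein[!is.na(put_to_protein)],
      rrna_reference = rand_dna(2000L), seed = as.integer(seed)
    ), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", nrow(x$transcripts), "transcripts /",
      nrow(x$proteins), "proteins; destinies:",
      paste(names(table(x$transcripts$destiny)),
            table(x$transcripts$destiny), collapse = ", "),
      "\n")
  invisible(x)
}

#' Emit the world's planted BLASTX records as extended tabular rows
#'
#' Produces the 14-column dialect consumed by [parse_blast_tabular()]
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore ppos slen`), one HSP per row, with geometry that
#' matches the planted tier destinies exactly.  Transcripts with a
#' destiny of `none` emit no record.
#'
#' @param world a [make_world()] object.
#' @param path optional output path; when given, rows are written as a
#'   headerless TSV.
#' @return Tibble of tabular rows (invisibly when `path` is given).
#' @export
emit_blastx_tabular <- function(world, path = NULL) {
  if (nrow(world$proteins) == 0L) stop("world has no proteins")
  rows <- lapply(names(world$hsps), function(txid) {
    h <- world$hsps[[txid]]
    pid <- world$put_to_protein[[txid]]
    slen <- world$proteins$length[world$proteins$id == pid]
    tibble(
      qseqid = txid, sseqid = pid, pident = 100.0,
      length = h$align_len, mismatch = 0L, gapopen = 0L,
      qstart = h$q_start, qend = h$q_end,
      sstart = h$s_start, send = h$s_end,
      evalue = pmax(10^(-h$bitscore / 10), 1e-180),
      bitscore = h$bitscore,
      ppos = round(100 * h$positives / h$align_len, 2),
      slen = slen
    )
  })
  tab <- dplyr::bind_rows(rows)
  if (!is.null(path)) {
    write_blast_tabular(tab, path)
    return(invisible(tab))
  }
  tab
}

#' Write a BLAST tabular tibble as headerless TSV
#'
#' @param tab tibble from [emit_blastx_tabular()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(tab, path) {
  df <- as.data.frame(tab)
  df$evalue <- format(df$evalue, digits = 3, scientific = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Two-state read quality model
#'
#' Reads carry a high baseline quality with, at probability `tail_prob`,
#' a geometric-length low-quality span at the 3' end (and at probability
#' `tail_prob / 2` also at the 5' end) — the minimal model that gives
#' the terminal-clipping, fraction-filter and masking rules work to do.
#'
#' @param q_high baseline Phred quality (default 38).
#' @param q_low terminal-span quality (default 15).
#' @param tail_prob probability a read has a 3' low-quality span
#'   (default 0.5).
#' @param tail_mean mean span length in bases (default 6).
#' @return Parameter list.
#' @export
qual_model <- function(q_high = 38L, q_low = 15L, tail_prob = 0.5,
                       tail_mean = 6) {
  list(q_high = as.integer(q_high), q_low = as.integer(q_low),
       tail_prob = tail_prob, tail_mean = tail_mean)
}

#' Simulate a condition's read set from a synthetic world
#'
#' Reads are drawn from transcripts proportional to the condition's
#' abundance fractions, with a binomially-sampled fraction drawn from
#' the rRNA reference instead; read positions are uniform along each
#' source.  Base calls copy the source exactly (no substitution errors);
#' qualities follow the two-state [qual_model()].
#'
#' @param world a [make_world()] object.
#' @param condition `"control"` or `"infected"`.
#' @param n_reads number of reads.
#' @param read_len read length in bases (default 72); must not exceed
#'   the shortest transcript.
#' @param qmodel a [qual_model()].
#' @param rrna_fraction fraction of reads drawn from the rRNA reference
#'   (default 0).
#' @param seed integer seed.
#' @return Read-set tibble with provenance columns `source_id` and
#'   `start` (`source_id` is `"rRNA"` for contaminant reads).
#' @export
simulate_reads <- function(world, condition = c("control", "infected"),
                           n_reads = 1000L, read_len = 72L,
                           qmodel = qual_model(), rrna_fraction = 0,
                           seed = 1L) {
  condition <- match.arg(condition)
  if (nrow(world$transcripts) == 0L) stop("empty world")
  if (read_len > min(world$transcripts$length)) {
    stop("read_len exceeds the shortest transcript (",
         min(world$transcripts$length), " nt)")
  }
  ab <- world$abundances[[condition]]
  with_seed(seed, {
    n_rrna <- rbinom(1L, n_reads, rrna_fraction)
    n_tx <- n_reads - n_rrna
    src_i <- sample.int(nrow(world$transcripts), n_tx, replace = TRUE,
                        prob = ab[world$transcripts$id])
    src_id <- c(world$transcripts$id[src_i], rep("rRNA", n_rrna))
    src_len <- c(world$transcripts$length[src_i],
                 rep(nchar(world$rrna_reference), n_rrna))
    src_seq <- c(world$transcripts$seq[src_i],
                 rep(world$rrna_reference, n_rrna))
    ord <- sample.int(n_reads)
    src_id <- src_id[ord]; src_len <- src_len[ord]
    src_seq <- src_seq[ord]
    start <- 1L + floor(runif(n_reads) * (src_len - read_len + 1L))
    seqs <- substr(src_seq, start, start + read_len - 1L)
    tail3 <- ifelse(runif(n_reads) < qmodel$tail_prob,
                    pmin(read_len,
                         rgeom(n_reads, 1 / (qmodel$tail_mean + 1)) + 1L),
                    0L)
    tail5 <- ifelse(runif(n_reads) < qmodel$tail_prob / 2,
                    pmin(read_len - tail3,
                         rgeom(n_reads, 1 / (qmodel$tail_mean + 1)) + 1L),
                    0L)
    qual <- if (qmodel$tail_prob == 0) {
      rep(list(rep(qmodel$q_high, read_len)), n_reads)
    } else {
      lapply(seq_len(n_reads), function(i) {
        q <- rep(qmodel$q_high, read_len)
        if (tail3[i] > 0L) {
          q[(read_len - tail3[i] + 1L):read_len] <- qmodel$q_low
        }
        if (tail5[i] > 0L) q[1:tail5[i]] <- qmodel$q_low
        q
      })
    }
    out <- read_set(sprintf("%s_r%06d", condition, seq_len(n_reads)),
                    seqs, qual)
    out$source_id <- src_id
    out$start <- start
    out
  })
}

#' Generate a toy three-domain GO ontology
#'
#' Builds an acyclic is_a DAG with the three standard roots
#' (`biological_process`, `cellular_component`, `molecular_function`),
#' `depth` levels below each root and `branching` terms per level; terms
#' below the first level have a 30 percent chance of a second parent so
#' multi-path GO-Slim rollups are exercised.
#'
#' @param depth number of levels below each root (at least 2).
#' @param branching terms per level.
#' @param seed integer seed.
#' @return An [ontology_graph()].
#' @export
make_toy_ontology <- function(depth = 3L, branching = 3L, seed = 1L) {
  if (depth < 2L) stop("depth must be at least 2")
  roots <- c(biological_process = "GO:0008150",
             cellular_component = "GO:0005575",
             molecular_function = "GO:0003674")
  with_seed(seed, {
    ids <- unname(roots)
    nms <- names(roots)
    ns <- names(roots)
    parents <- setNames(vector("list", 3L), unname(roots))
    parents[] <- list(character(0))
    k <- 0L
    for (d in seq_along(roots)) {
      prev <- roots[[d]]
      for (lev in seq_len(depth)) {
        cur <- character(branching)
        for (b in seq_len(branching)) {
          k <- k + 1L
          id <- sprintf("GO:%07d", 1000000L + k)
          cur[b] <- id
          ids <- c(ids, id)
          nms <- c(nms, sprintf("%s level-%d term %d",
                                names(roots)[d], lev, b))
          ns <- c(ns, names(roots)[d])
          par <- sample(prev, 1L)
          if (lev > 1L && length(prev) > 1L && runif(1) < 0.3) {
            par <- c(par, sample(setdiff(prev, par), 1L))
          }
          parents[[id]] <- par
        }
        prev <- cur
      }
    }
    ontology_graph(tibble(id = ids, name = nms, namespace = ns),
                   parents)
  })
}

#' Generate a replicated Ct table with planted fold changes
#'
#' Emulates a two-condition qRT-PCR panel: endogenous control genes sit
#' at a fixed baseline Ct in both conditions; each target gene's
#' control-condition delta-Ct is centered at 0 and its
#' infected-condition delta-Ct is shifted by `-log2(fold)`, so the
#' planted fold is recovered exactly at zero noise.  Gaussian technical
#' noise of `noise_sd` cycles is added to every Ct measurement.
#'
#' @param genes character vector of target gene labels.
#' @param fold_changes numeric vector (recycled to `length(genes)`) of
#'   planted infected/control expression folds; must be positive.
#' @param n_bio,n_tech numbers of biological and technical replicates
#'   (defaults 3 and 3).
#' @param noise_sd technical noise standard deviation in cycles
#'   (default 0.2).
#' @param seed integer seed.
#' @param controls labels of the endogenous control genes.
#' @param baseline_ct control-gene Ct baseline (default 20).
#' @return Ct tibble (`gene`, `condition`, `bio_rep`, `tech_rep`, `ct`)
#'   with the control labels in attribute `"controls"` and planted folds
#'   in attribute `"planted_folds"`.
#' @export
make_ct_table <- function(genes, fold_changes, n_bio = 3L, n_tech = 3L,
                          noise_sd = 0.2, seed = 1L,
                          controls = c("ref18S", "refEFTu"),
                          baseline_ct = 20) {
  if (n_bio < 1L || n_tech < 1L) stop("replicate counts must be >= 1")
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  folds <- setNames(rep_len(fold_changes, length(genes)), genes)
  with_seed(seed, {
    rows <- list()
    for (cond in c("control", "infected")) {
      for (b in seq_len(n_bio)) {
        for (g in c(controls, genes)) {
          mu <- if (g %in% controls) baseline_ct
                else if (cond == "control") baseline_ct
                else baseline_ct - log2(folds[[g]])
          rows[[length(rows) + 1L]] <- tibble(
            gene = g, condition = cond, bio_rep = b,
            tech_rep = seq_len(n_tech),
            ct = mu + rnorm(n_tech, 0, noise_sd))
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "controls") <- controls
    attr(out, "planted_folds") <- folds
    out
  })
}
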