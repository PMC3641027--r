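#' Parse hmmscan --domtblout output and keep each query's top family
#'
#' hmmscan's domain table is whitespace-separated with 22 fixed columns
#' followed by a free-text description.  Per query, the retained hit is
#' the Pfam family with the lowest full-sequence E-value at or below
#' `evalue_cutoff`; ties go to the higher full-sequence bitscore, then
#' the lexicographically smaller accession.  Queries whose best E-value
#' exceeds the cutoff are left unannotated.
#'
#' @param path path to a `--domtblout` file.
#' @param evalue_cutoff full-sequence E-value inclusion threshold
#'   (default `1e-2`).
#' @return Tibble with one row per annotated query: `query_id`,
#'   `family_acc`, `family_name`, `full_seq_evalue`, `bitscore`.
#' @export
parse_domtbl_top_hit <- function(path, evalue_cutoff = 1e-2) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(tibble(query_id = character(), family_acc = character(),
                  family_name = character(), full_seq_evalue = numeric(),
                  bitscore = numeric()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 22L)) {
    bad <- which(nf < 22L)[1]
    stop("domtblout parse error: line ", lineno[bad], " has ", nf[bad],
         " fields (expected >= 22)")
  }
  df <- tibble(
    family_name = vapply(fields, `[[`, character(1), 1L),
    family_acc = vapply(fields, `[[`, character(1), 2L),
    query_id = vapply(fields, `[[`, character(1), 4L),
    full_seq_evalue = as.numeric(vapply(fields, `[[`, character(1), 7L)),
    bitscore = as.numeric(vapply(fields, `[[`, character(1), 8L))
  )
  if (anyNA(df$full_seq_evalue) || anyNA(df$bitscore)) {
    bad <- which(is.na(df$full_seq_evalue) | is.na(df$bitscore))[1]
    stop("domtblout parse error: non-numeric score field at line ",
         lineno[bad])
  }
  df |>
    dplyr::filter(.data$full_seq_evalue <= evalue_cutoff) |>
    dplyr::arrange(.data$query_id, .data$full_seq_evalue,
                   dplyr::desc(.data$bitscore), .data$family_acc) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}

#' Read an external2go mapping table (pfam2go, kegg2go)
#'
#' Parses the GO Consortium's standard line format, e.g.
#' `Pfam:PF00001 7tm_1 > GO:G protein-coupled receptor activity ;
#' GO:0004930`; comment lines starting with `!` are skipped.
#'
#' @param path path to a mapping file.
#' @return Tibble with columns `external_id` (the token after the
#'   namespace prefix), `external_name`, `go_name`, `go_id`.
#' @export
read_external2go <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  m <- regmatches(lines,
    regexec("^[A-Za-z_]+:(\\S+)\\s*(\\S*)\\s*>\\s*GO:(.*)\\s*;\\s*(GO:\\d{7})\\s*$",
            lines))
  ok <- lengths(m) == 5L
  if (!all(ok)) {
    stop("external2go parse error at line ", which(!ok)[1])
  }
  tibble(
    external_id = vapply(m, `[[`, character(1), 2L),
    external_name = vapply(m, `[[`, character(1), 3L),
    go_name = trimws(vapply(m, `[[`, character(1), 4L)),
    go_id = vapply(m, `[[`, character(1), 5L)
  )
}

#' Tally identifier counts
#'
#' @param ids character vector of identifiers (with repeats).
#' @return `list(counts=, unique=, total=)` where `counts` is a named
#'   integer vector.
#' @export
annotation_tally <- function(ids) {
  tab <- table(ids)
  list(counts = setNames(as.integer(tab), names(tab)),
       unique = length(tab), total = length(ids))
}

#' Roll Pfam hits up to GO terms, stratified by GO domain
#'
#' Each Pfam hit contributes every GO term its family maps to in the
#' pfam2go table (families can map to zero, one or several terms).
#' Tallies are stratified by the ontology domain of each GO term; terms
#' absent from the ontology raise a warning and are tallied under
#' `unmapped`.
#'
#' @param hits [parse_domtbl_top_hit()] tibble.
#' @param pfam2go [read_external2go()] tibble for pfam2go (external ids
#'   are Pfam accessions; version-suffixed accessions like `PF00001.21`
#'   in `hits` are matched on the base accession).
#' @param graph an [ontology_graph()] supplying GO domains.
#' @return Named list of [annotation_tally()] results, one per GO domain
#'   plus `all` (every mapped term) and, when needed, `unmapped`.
#' @export
pfam_to_go <- function(hits, pfam2go, graph) {
  acc <- sub("\\.\\d+$", "", hits$family_acc)
  go <- unlist(lapply(acc, function(a) {
    pfam2go$go_id[pfam2go$external_id == a]
  }), use.names = FALSE)
  ns <- graph$terms$namespace[match(go, graph$terms$id)]
  if (anyNA(ns) && length(go) > 0L) {
    warning(sum(is.na(ns)), " GO term occurrence(s) absent from the ",
            "ontology; tallied as unmapped")
  }
  out <- list(all = annotation_tally(go))
  for (d in c("biological_process", "cellular_component",
              "molecular_function")) {
    out[[d]] <- annotation_tally(go[!is.na(ns) & ns == d])
  }
  if (anyNA(ns)) out$unmapped <- annotation_tally(go[is.na(ns)])
  out
}

#' Map GO terms to KEGG identifiers via kegg2go
#'
#' @param terms character vector of GO term ids.
#' @param kegg2go [read_external2go()] tibble for kegg2go (external ids
#'   are KEGG identifiers).
#' @return `list(tally=, mapped_fraction=, mapped_terms=)`: a tally of
#'   KEGG identifiers reached, the fraction of unique input GO terms
#'   having at least one KEGG mapping, and the mapped unique terms.
#' @export
go_to_kegg <- function(terms, kegg2go) {
  uniq <- unique(terms)
  kegg <- unlist(lapply(uniq, function(g) {
    kegg2go$external_id[kegg2go$go_id == g]
  }), use.names = FALSE)
  mapped <- uniq[uniq %in% kegg2go$go_id]
  list(
    tally = annotation_tally(kegg),
    mapped_fraction = if (length(uniq) == 0L) 0
                      else length(mapped) / length(uniq),
    mapped_terms = mapped
  )
}
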