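#' Construct an ontology graph
#'
#' The package represents the Gene Ontology (or any toy stand-in) as a
#' directed acyclic graph of `is_a` relationships stratified into the
#' three GO domains.  Only `is_a` edges are modelled; `part_of` and other
#' relationship types are intentionally ignored.
#'
#' @param terms tibble with columns `id`, `name`, `namespace`
#'   (`biological_process`, `cellular_component` or
#'   `molecular_function`).
#' @param parents named list mapping a term id to the character vector of
#'   its direct `is_a` parents (roots map to `character(0)`).
#' @return An `ontology_graph` object (list with `terms`, `parents`,
#'   `children`, `roots`).
#' @export
ontology_graph <- function(terms, parents) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  stopifnot(all(names(parents) %in% terms$id))
  missing <- setdiff(terms$id, names(parents))
  parents[missing] <- list(character(0))
  parents <- parents[terms$id]
  children <- list()
  for (child in names(parents)) {
    for (p in parents[[child]]) {
      children[[p]] <- c(children[[p]], child)
    }
  }
  roots <- terms$id[lengths(parents) == 0L]
  structure(list(terms = terms, parents = parents,
                 children = children, roots = roots),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", nrow(x$terms), "terms,",
      sum(lengths(x$parents)), "is_a edges,",
      length(x$roots), "roots\n")
  invisible(x)
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `namespace` and `is_a`
#' tags (trailing `! comment` text is stripped); obsolete terms are
#' skipped.  Only `is_a` edges are loaded.
#'
#' @param path path to an OBO file.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  stanza_starts <- which(lines == "[Term]")
  ids <- character(); nms <- character(); ns <- character()
  parents <- list()
  bounds <- c(stanza_starts, length(lines) + 1L)
  for (i in seq_along(stanza_starts)) {
    blk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    blk <- blk[nzchar(blk) & !startsWith(blk, "[")]
    tagval <- function(tag) {
      v <- blk[startsWith(blk, paste0(tag, ":"))]
      sub("\\s*!.*$", "", sub(paste0("^", tag, ":\\s*"), "", v))
    }
    if (length(tagval("is_obsolete")) > 0L &&
        any(tagval("is_obsolete") == "true")) next
    id <- tagval("id")[1]
    if (is.na(id)) next
    ids <- c(ids, id)
    nm <- tagval("name")
    nms <- c(nms, if (length(nm) > 0L) nm[1] else NA_character_)
    nsv <- tagval("namespace")
    ns <- c(ns, if (length(nsv) > 0L) nsv[1] else NA_character_)
    parents[[id]] <- tagval("is_a")
  }
  ontology_graph(tibble(id = ids, name = nms, namespace = ns), parents)
}

#' Write an ontology graph as OBO 1.2
#'
#' @param graph an [ontology_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", graph$terms$name[i]),
             paste0("namespace: ", graph$terms$namespace[i]),
             if (length(graph$parents[[id]]) > 0L)
               paste0("is_a: ", graph$parents[[id]]) else NULL,
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' All is_a ancestors of a term
#'
#' @param term GO term id.
#' @param graph an [ontology_graph()].
#' @return Character vector of ancestor ids (the term itself excluded).
#' @export
ont_ancestors <- function(term, graph) {
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
  seen <- character(0)
  frontier <- graph$parents[[term]]
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(graph$parents[frontier], use.names = FALSE)), seen)
  }
  seen
}

#' GO-Slim (penultimate-ancestor) terms of a GO term
#'
#' Returns every term that is a direct `is_a` child of an ontology root
#' and lies on some `is_a` path from the input term to that root — the
#' "penultimate ancestors".  The ultimate ancestors (the three domain
#' roots) are excluded as uninformative; a term that is itself a root's
#' direct child returns itself, and a root returns the empty set.  Terms
#' with multiple paths to the root can contribute several slim terms.
#'
#' @param term GO term id.
#' @param graph an [ontology_graph()].
#' @return Character vector (possibly empty) of slim term ids.
#' @export
go_slim <- function(term, graph) {
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
  if (term %in% graph$roots) return(character(0))
  anc_or_self <- c(term, ont_ancestors(term, graph))
  slim_pool <- unique(unlist(graph$children[graph$roots],
                             use.names = FALSE))
  sort(intersect(anc_or_self, slim_pool))
}

#' GO-Slim rollup for a collection of terms
#'
#' @param terms character vector of GO term ids (may repeat).
#' @param graph an [ontology_graph()].
#' @param mode `"multiset"` (default) tallies one contribution per input
#'   occurrence per slim term; `"set"` deduplicates input terms first.
#' @return Tibble with columns `slim_id`, `namespace`, `count`, sorted by
#'   count descending.
#' @export
go_slim_tally <- function(terms, graph, mode = c("multiset", "set")) {
  mode <- match.arg(mode)
  if (mode == "set") terms <- unique(terms)
  slims <- unlist(lapply(terms, go_slim, graph = graph),
                  use.names = FALSE)
  if (length(slims) == 0L) {
    return(tibble(slim_id = character(), namespace = character(),
                  count = integer()))
  }
  tab <- table(slims)
  ns <- graph$terms$namespace[match(names(tab), graph$terms$id)]
  tibble(slim_id = names(tab), namespace = ns,
         count = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$slim_id)
}
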