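#' Read a tidy Ct table
#'
#' @param path TSV file with header columns `gene`, `condition`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @return Tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  as_tibble(df)
}

#' Write a Ct table as TSV
#'
#' @param ct_table Ct tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct_table, path) {
  write.table(ct_table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Delta-Ct of a gene in one biological replicate
#'
#' `deltaCt = mean(technical Cts of the gene) - mean(technical Cts
#' pooled across the endogenous control genes)`, both within the given
#' condition and biological replicate.  The controls are combined by
#' pooling their technical Ct values into a single reference mean on the
#' Ct scale.
#'
#' @param ct_table Ct tibble (see [read_ct_table()]).
#' @param gene target gene label.
#' @param condition condition label.
#' @param bio_rep biological replicate index.
#' @param controls character vector of endogenous control gene labels.
#' @return Delta-Ct in cycles.
#' @export
delta_ct <- function(ct_table, gene, condition, bio_rep, controls) {
  sel <- ct_table$condition == condition & ct_table$bio_rep == bio_rep
  g <- ct_table$ct[sel & ct_table$gene == gene]
  if (length(g) == 0L) {
    stop("no Ct values for gene ", gene, " in condition ", condition,
         ", biological replicate ", bio_rep)
  }
  for (ctl in controls) {
    if (!any(sel & ct_table$gene == ctl)) {
      stop("endogenous control ", ctl, " missing in condition ",
           condition, ", biological replicate ", bio_rep)
    }
  }
  ref <- ct_table$ct[sel & ct_table$gene %in% controls]
  mean(g) - mean(ref)
}

#' Summarize relative expression (2^-deltaCt) per gene and condition
#'
#' For every non-control gene and condition, computes the per-biological
#' replicate `2^-deltaCt` values, their mean, and the standard error of
#' the mean (`sd / sqrt(n_bio)`).
#'
#' @param ct_table Ct tibble.
#' @param controls character vector of endogenous control gene labels.
#' @return Tibble with columns `gene`, `condition`, `rel_expr` (list
#'   column of per-bio-rep values), `n_bio`, `mean`, `sem`.
#' @export
qpcr_summarize <- function(ct_table, controls) {
  genes <- setdiff(unique(ct_table$gene), controls)
  combos <- unique(ct_table[ct_table$gene %in% genes,
                            c("gene", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    g <- combos$gene[i]; cond <- combos$condition[i]
    reps <- sort(unique(ct_table$bio_rep[
      ct_table$gene == g & ct_table$condition == cond]))
    rel <- vapply(reps, function(b) {
      2^(-delta_ct(ct_table, g, cond, b, controls))
    }, numeric(1))
    tibble(gene = g, condition = cond, rel_expr = list(rel),
           n_bio = length(rel), mean = mean(rel),
           sem = stats::sd(rel) / sqrt(length(rel)))
  })
  dplyr::bind_rows(rows)
}

#' Signed fold change between two relative-expression means
#'
#' With `r = mean_infected / mean_control`: reports `+r` when `r >= 1`
#' and `-(1/r)` otherwise, matching the signed convention used for
#' qRT-PCR panels (e.g. `+427` for strong induction, `-13.2` for strong
#' repression).
#'
#' @param mean_control,mean_infected positive relative-expression means.
#' @return Signed fold (magnitude always at least 1).
#' @export
signed_fold <- function(mean_control, mean_infected) {
  if (mean_control <= 0 || mean_infected <= 0) {
    stop("relative-expression means must be positive")
  }
  r <- mean_infected / mean_control
  if (r >= 1) r else -1 / r
}

#' Signed fold changes for every gene in a qPCR summary
#'
#' @param summary [qpcr_summarize()] tibble containing two conditions.
#' @param control_label,infected_label condition labels (defaults
#'   `"control"` and `"infected"`).
#' @return Tibble with columns `gene`, `mean_control`, `mean_infected`,
#'   `signed_fold`, sorted by absolute fold descending.
#' @export
qpcr_fold_table <- function(summary, control_label = "control",
                            infected_label = "infected") {
  genes <- unique(summary$gene)
  rows <- lapply(genes, function(g) {
    mc <- summary$mean[summary$gene == g &
                       summary$condition == control_label]
    mi <- summary$mean[summary$gene == g &
                       summary$condition == infected_label]
    if (length(mc) != 1L || length(mi) != 1L) {
      stop("gene ", g, " lacks a summary row in one of the conditions")
    }
    tibble(gene = g, mean_control = mc, mean_infected = mi,
           signed_fold = signed_fold(mc, mi))
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(abs(.data$signed_fold)))
}
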