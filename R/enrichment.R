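#' Read a flat gene-category table
#'
#' @param path TSV with columns `gene_id`, `category_id` and optionally
#'   `kind` (free text, e.g. a hormone or TF-family collection name).
#' @return data.frame with those columns (`kind` filled with "category"
#'   when absent).
#' @export
read_categories <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category_id") %in% names(df)))
    stop("category table needs columns gene_id, category_id")
  if (is.null(df$kind)) df$kind <- "category"
  df[, c("gene_id", "category_id", "kind")]
}

#' Log2 odds-ratio + hypergeometric category enrichment
#'
#' For a query gene set (e.g. one domain's enriched genes) against each
#' category: `q` = query genes in the category, `k` = query size, `m` =
#' category size within the universe, `t` = universe size, and
#' `LR = log2((q/k) / (m/t))`. Significance is the upper-tail
#' hypergeometric probability `P(X >= q)` (observed count included), with
#' BH correction applied within each category kind.
#'
#' @param query character vector of gene ids (must lie in `universe`).
#' @param categories data.frame as from [read_categories()], or a named
#'   list of gene id vectors (then `kind` is "category" throughout).
#' @param universe character vector, typically all expressed genes.
#' @return data.frame per category: `category_id`, `kind`, `q`, `k`, `m`,
#'   `t`, `lr` (NA when q = 0), `pvalue`, `fdr`.
#' @export
lr_enrichment <- function(query, categories, universe) {
  if (!length(query)) stop("empty query")
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  if (is.list(categories) && !is.data.frame(categories)) {
    categories <- data.frame(
      gene_id = unlist(categories, use.names = FALSE),
      category_id = rep(names(categories), lengths(categories)),
      kind = "category", stringsAsFactors = FALSE)
  }
  k <- length(query)
  t <- length(universe)
  cats <- unique(categories[, c("category_id", "kind")])
  res <- lapply(seq_len(nrow(cats)), function(i) {
    members <- intersect(
      categories$gene_id[categories$category_id == cats$category_id[i]],
      universe)
    m <- length(members)
    q <- length(intersect(query, members))
    lr <- if (q > 0 && m > 0) log2((q / k) / (m / t)) else NA_real_
    p <- if (m == 0) 1 else
      stats::phyper(q - 1, m, t - m, k, lower.tail = FALSE)
    data.frame(category_id = cats$category_id[i], kind = cats$kind[i],
               q = q, k = k, m = m, t = t, lr = lr, pvalue = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- NA_real_
  for (kd in unique(res$kind))
    res$fdr[res$kind == kd] <- bh_adjust(res$pvalue[res$kind == kd])
  res
}

#' Module-domain association by hypergeometric overlap
#'
#' Tests every (module, domain) cell for over-representation of the
#' domain's enriched genes inside the module, within a common universe.
#' BH correction is applied across the whole matrix of cells; cells with
#' FDR < `fdr_sig` are flagged significant.
#'
#' @param modules a `module_assignment` (see [detect_modules()]) or a named
#'   list of module gene id vectors ("unassigned" entries are ignored).
#' @param enriched_sets named list of per-domain gene sets
#'   ([domain_enriched()]).
#' @param universe character vector containing all module genes.
#' @param fdr_sig significance cutoff on the BH-adjusted p (default 0.01).
#' @return data.frame per cell: `module`, `domain`, `overlap`,
#'   `module_size`, `set_size`, `pvalue`, `fdr`, `significant`.
#' @export
module_domain_association <- function(modules, enriched_sets, universe,
                                      fdr_sig = 0.01) {
  if (inherits(modules, "module_assignment")) {
    lab <- modules$labels
    modules <- split(names(lab), lab)
  }
  modules <- modules[setdiff(names(modules), "unassigned")]
  universe <- unique(universe)
  bad <- setdiff(unlist(modules), universe)
  if (length(bad)) stop("module gene(s) outside universe: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  t <- length(universe)
  cells <- expand.grid(module = names(modules),
                       domain = names(enriched_sets),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    mg <- modules[[cells$module[i]]]
    dg <- intersect(enriched_sets[[cells$domain[i]]], universe)
    q <- length(intersect(mg, dg))
    p <- stats::phyper(q - 1, length(dg), t - length(dg), length(mg),
                       lower.tail = FALSE)
    data.frame(module = cells$module[i], domain = cells$domain[i],
               overlap = q, module_size = length(mg),
               set_size = length(dg), pvalue = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$pvalue)
  res$significant <- res$fdr < fdr_sig
  res
}

#' Retain significantly enriched categories
#'
#' Keeps categories at BH-adjusted p <= `alpha` (inclusive), carrying the
#' log2 odds ratio for display.
#'
#' @param results data.frame with an `fdr` column ([lr_enrichment()]).
#' @param alpha FDR cutoff (default 0.05).
#' @return The retained rows.
#' @export
significance_filter <- function(results, alpha = 0.05) {
  if (!nrow(results)) return(results)
  if (is.null(results$fdr) || anyNA(results$fdr))
    stop("fdr must be computed before filtering")
  results[results$fdr <= alpha, , drop = FALSE]
}
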