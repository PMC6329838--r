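#' Row-wise z-score standardization
#'
#' Standardizes each gene's expression vector: `z_ij = (x_ij - mu_i) / s_i`
#' with `mu_i` the row mean and `s_i` the row standard deviation
#' (population, divide-by-n, by default, so a vector that is constant except
#' for one outlying entry scores exactly `sqrt(D - 1)` in that entry).
#' Rows with zero scatter get z = 0 everywhere so downstream set algebra
#' stays total.
#'
#' @param x numeric matrix, genes x conditions (domain means or samples).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Matrix of z-scores, same dimnames as `x`.
#' @export
zscore_matrix <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need >= 2 columns")
  mu <- rowMeans(x)
  dev <- x - mu
  denom <- if (sd_type == "population") ncol(x) else ncol(x) - 1L
  s <- sqrt(rowSums(dev^2) / denom)
  z <- dev / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Domain-level z-scores referenced to the per-sample distribution
#'
#' Standardizes every sample's RPKM per gene (mean and population sd over
#' all samples) and evaluates the score at each domain's replicate mean:
#' `z_ij = (xbar_ij - mu_i) / s_i`. Because replicate averaging shrinks
#' noise but not signal, this sample-referenced score is far less prone to
#' calling flat genes than standardizing the D domain means directly, while
#' giving the identical value (e.g. `sqrt(D - 1)` for a one-domain outlier)
#' when replicates agree. Set `z_on = "domain_means"` for the pure
#' domain-mean standardization.
#'
#' @param em an [expression_matrix()].
#' @param z_on reference scatter: `"samples"` (default) or `"domain_means"`.
#' @param sd_type passed to [zscore_matrix()] semantics.
#' @return genes x domains z matrix.
#' @export
domain_zscores <- function(em, z_on = c("samples", "domain_means"),
                           sd_type = c("population", "sample")) {
  stopifnot(inherits(em, "expression_matrix"))
  z_on <- match.arg(z_on)
  sd_type <- match.arg(sd_type)
  if (z_on == "domain_means") return(zscore_matrix(em$domain_means, sd_type))
  x <- em$rpkm
  mu <- rowMeans(x)
  denom <- if (sd_type == "population") ncol(x) else ncol(x) - 1L
  s <- sqrt(rowSums((x - mu)^2) / denom)
  z <- (em$domain_means - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Compartment-specificity (CS) score
#'
#' `CS(i, j) = 1 - max_{k != j}(EV_ik / EV_ij)`: 1 when gene i is expressed
#' exclusively in domain j, 0 when uniform, negative when another domain is
#' higher. A zero focal denominator with any other domain expressed, or an
#' all-zero gene, yields NA.
#'
#' @param domain_means genes x domains matrix of mean expression.
#' @return genes x domains matrix of CS scores (<= 1, NA where undefined).
#' @export
cs_score <- function(domain_means) {
  x <- as.matrix(domain_means)
  if (ncol(x) < 2L) stop("need >= 2 domains")
  out <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    other_max <- do.call(pmax, as.data.frame(x[, -j, drop = FALSE]))
    ev_j <- x[, j]
    cs <- 1 - other_max / ev_j
    cs[ev_j == 0] <- NA_real_          # undefined focal denominator
    cs[ev_j == 0 & other_max == 0] <- NA_real_  # all-zero gene
    out[, j] <- cs
  }
  out
}

#' Pairwise domain-specificity screen
#'
#' A gene is pairwise-specific to the focal domain when it is differentially
#' expressed, in the focal domain's favor, against every one of the other
#' D - 1 domains: `log2fc > lfc` and `fdr < fdr_max` in each contrast.
#' The Methods-style raw `P < alpha` rule is available via
#' `use = "pvalue"`.
#'
#' @param de_list named list of [pairwise_de()] results for the focal domain
#'   against each other domain (as from [de_versus_rest()]).
#' @param lfc log2 fold-change cutoff (default 1, i.e. 2-fold).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param use `"fdr"` (default) or `"pvalue"` for the significance column.
#' @param universe optional character vector; genes outside it are FALSE.
#' @return Named logical vector over the union of tested genes.
#' @export
pairwise_specific <- function(de_list, lfc = 1, fdr_max = 0.05,
                              use = c("fdr", "pvalue"), universe = NULL) {
  use <- match.arg(use)
  if (!length(de_list)) stop("no contrasts supplied")
  genes <- sort(unique(unlist(lapply(de_list, `[[`, "gene_id"))))
  ok <- rep(TRUE, length(genes)); names(ok) <- genes
  for (de in de_list) {
    sig <- if (use == "fdr") de$fdr else de$pvalue
    pass <- de$log2fc > lfc & sig < fdr_max
    hit <- stats::setNames(rep(FALSE, length(genes)), genes)
    hit[de$gene_id] <- pass           # gene untested in a contrast -> fails it
    ok <- ok & hit
  }
  if (!is.null(universe)) ok <- ok & names(ok) %in% universe
  ok
}

#' Domain-enriched gene sets (union rule)
#'
#' Union of the z-score caller (`z >= z_threshold`, which permits a gene to
#' be enriched in more than one domain) and the stringent pairwise screen.
#' Only genes expressed in at least one domain are eligible.
#'
#' @param z genes x domains z matrix ([domain_zscores()]).
#' @param pairwise list of named logical vectors per domain
#'   ([pairwise_specific()]), or NULL to use the z caller alone.
#' @param z_threshold inclusive z cutoff (default 2).
#' @param expressed per-domain expressed sets ([expressed_sets()]) defining
#'   eligibility; NULL skips the filter.
#' @return Named list per domain of enriched gene id vectors, with a
#'   `membership` attribute (logical genes x domains matrix over the z
#'   matrix's gene universe).
#' @export
domain_enriched <- function(z, pairwise = NULL, z_threshold = 2.0,
                            expressed = NULL) {
  doms <- colnames(z)
  eligible <- rownames(z)
  if (!is.null(expressed)) {
    mem <- attr(expressed, "membership")
    eligible <- intersect(eligible, rownames(mem)[rowSums(mem) > 0])
  }
  out_mem <- matrix(FALSE, nrow(z), ncol(z), dimnames = dimnames(z))
  for (d in doms) {
    hits <- rownames(z)[z[, d] >= z_threshold]
    if (!is.null(pairwise) && d %in% names(pairwise)) {
      pw <- pairwise[[d]]
      hits <- union(hits, names(pw)[pw])
    }
    out_mem[intersect(hits, eligible), d] <- TRUE
  }
  sets <- lapply(doms, function(d) rownames(out_mem)[out_mem[, d]])
  names(sets) <- doms
  attr(sets, "membership") <- out_mem
  sets
}

#' Full specificity table
#'
#' Long-format per gene x domain table combining z, CS, the pairwise flag
#' and the union enriched flag.
#'
#' @param z,cs genes x domains matrices.
#' @param pairwise list of logical vectors per domain (or NULL).
#' @param enriched result of [domain_enriched()].
#' @return data.frame with columns `gene_id`, `domain`, `z`, `cs`,
#'   `pairwise_specific`, `enriched`.
#' @export
specificity_table <- function(z, cs, pairwise, enriched) {
  mem <- attr(enriched, "membership")
  doms <- colnames(z)
  do.call(rbind, lapply(doms, function(d) {
    pw <- rep(FALSE, nrow(z))
    if (!is.null(pairwise) && d %in% names(pairwise)) {
      v <- pairwise[[d]]
      pw <- unname(v[match(rownames(z), names(v))])
      pw[is.na(pw)] <- FALSE
    }
    data.frame(gene_id = rownames(z), domain = d,
               z = unname(z[, d]), cs = unname(cs[, d]),
               pairwise_specific = pw,
               enriched = unname(mem[rownames(z), d]),
               stringsAsFactors = FALSE)
  }))
}

#' Domain-specific genes within a restricted domain subset
#'
#' Re-runs the pairwise screen among a subset of domains (e.g. the three
#' meristem domains) at the stringent threshold used for within-meristem
#' comparisons: specific to domain j iff fold change >= `fc` and
#' FDR <= `fdr_max` against every other domain of the subset, in j's favor.
#'
#' @param cm a [count_matrix()].
#' @param domains_subset character vector of >= 2 domain labels.
#' @param fc linear fold-change cutoff (default 2, inclusive).
#' @param fdr_max FDR cutoff (default 0.01, inclusive).
#' @param ... passed to [pairwise_de()].
#' @return Named list per subset domain of specific gene id vectors, plus a
#'   `"contrasts"` attribute holding the DE tables.
#' @export
sam_restricted_specific <- function(cm, domains_subset, fc = 2,
                                    fdr_max = 0.01, ...) {
  stopifnot(length(domains_subset) >= 2)
  em <- rpkm(cm)
  pairs <- utils::combn(domains_subset, 2, simplify = FALSE)
  de <- lapply(pairs, function(p) pairwise_de(cm, p[1], p[2], em = em, ...))
  names(de) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  sets <- lapply(domains_subset, function(d) {
    others <- setdiff(domains_subset, d)
    genes <- NULL
    for (o in others) {
      hit <- NULL
      for (tab in de) {
        if (tab$domain_a[1] == d && tab$domain_b[1] == o)
          hit <- tab$gene_id[tab$log2fc >= log2(fc) & tab$fdr <= fdr_max]
        if (tab$domain_a[1] == o && tab$domain_b[1] == d)
          hit <- tab$gene_id[-tab$log2fc >= log2(fc) & tab$fdr <= fdr_max]
      }
      if (is.null(hit)) stop("missing contrast ", d, " vs ", o)
      genes <- if (is.null(genes)) hit else intersect(genes, hit)
    }
    genes
  })
  names(sets) <- domains_subset
  attr(sets, "contrasts") <- de
  sets
}
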