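#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the conventional
#' defaults: RPKM > 1 gene-level expressed call (isoforms use >= 1),
#' z >= 2 enrichment, log2FC > 1 with FDR < 0.05 for the pairwise
#' specificity screen, CS > 0.3, CV >= 0.7 network filter, soft power 9,
#' eigengene merge cut 0.20, module-domain significance FDR < 0.01, and
#' the lncRNA criteria (length > 200 nt, coding gap >= 500 bp,
#' ORF <= 300 nt). Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    rpkm_threshold = 1.0,
    isoform_rpkm_threshold = 1.0,
    z_threshold = 2.0,
    lfc = 1.0,
    fdr = 0.05,
    cs_threshold = 0.3,
    pseudocount = 0.1,
    dispersion_gene_weight = 0.3,
    cv_max = 0.7,
    beta = 9,
    merge_cut = 0.20,
    min_module_size = 30,
    module_fdr = 0.01,
    lnc_min_length = 200,
    lnc_min_distance = 500,
    lnc_max_orf = 300,
    as_rule = "disagree",
    z_on = "samples",
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  stopifnot(defaults$z_threshold > 0, defaults$fdr > 0, defaults$fdr <= 1,
            defaults$beta >= 1, defaults$merge_cut > 0,
            defaults$merge_cut < 1)
  structure(defaults, class = "pipeline_config")
}

#' Run the full domain-specificity pipeline
#'
#' Chains normalization, expressed-gene calling, pairwise DE, the three
#' specificity callers, optional category enrichment, co-expression module
#' detection with module-domain association, optional isoform AS calls and
#' optional lncRNA classification, and returns all stage outputs plus a
#' summary and a machine-readable manifest. A stage failure aborts with
#' the failing stage named; stages already computed are kept in the error
#' condition's `partial` field.
#'
#' @param cm a [count_matrix()].
#' @param config a [pipeline_config()].
#' @param categories optional category table ([read_categories()] format).
#' @param isoforms optional list(em = isoform [expression_matrix()],
#'   iso2gene = named vector).
#' @param lncrna optional list(assembled, annotation, genome) for
#'   [classify_lncrna()].
#' @param pseudogene_ids optional character vector.
#' @param run_coexpression logical; skip the network stage if FALSE.
#' @param verbose print per-stage progress.
#' @return A `pipeline_result` list: `em`, `expressed`, `overlap`, `de`,
#'   `z`, `cs`, `pairwise`, `enriched`, `specificity`, `modules`,
#'   `module_domain`, `enrichment`, `as_genes`, `lncrna`, `pseudogenes`,
#'   `summary`, `manifest`.
#' @export
run_pipeline <- function(cm, config = pipeline_config(), categories = NULL,
                         isoforms = NULL, lncrna = NULL,
                         pseudogene_ids = NULL, run_coexpression = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(config, "pipeline_config"))
  res <- list()
  stage <- function(name, expr) {
    if (verbose) message("[", format(Sys.time(), "%H:%M:%S"), "] stage: ",
                         name)
    tryCatch(expr, error = function(e) {
      cond <- simpleError(paste0("pipeline stage '", name, "' failed: ",
                                 conditionMessage(e)))
      cond$partial <- res
      stop(cond)
    })
  }
  set.seed(config$seed)
  res$em <- stage("normalize", rpkm(cm))
  res$expressed <- stage("expressed",
                         expressed_sets(res$em, config$rpkm_threshold))
  res$overlap <- stage("overlap", overlap_groups(res$expressed))
  doms <- levels(cm$design$domain_id)
  res$de <- stage("de", {
    pairs <- utils::combn(doms, 2, simplify = FALSE)
    de <- lapply(pairs, function(p)
      pairwise_de(cm, p[1], p[2], pseudocount = config$pseudocount,
                  expressed_threshold = config$rpkm_threshold,
                  gene_weight = config$dispersion_gene_weight, em = res$em))
    names(de) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    de
  })
  res$z <- stage("zscore", domain_zscores(res$em, z_on = config$z_on))
  res$cs <- stage("cs", cs_score(res$em$domain_means))
  res$pairwise <- stage("pairwise_specific", {
    out <- lapply(doms, function(d) {
      de_d <- lapply(setdiff(doms, d), function(o) {
        key1 <- paste(d, o, sep = "_vs_"); key2 <- paste(o, d, sep = "_vs_")
        if (!is.null(res$de[[key1]])) res$de[[key1]]
        else { t2 <- res$de[[key2]]
               t2$log2fc <- -t2$log2fc
               t2[, c("gene_id", "log2fc", "pvalue", "fdr")] }
      })
      pairwise_specific(de_d, lfc = config$lfc, fdr_max = config$fdr,
                        universe = res$expressed[[d]])
    })
    names(out) <- doms
    out
  })
  res$enriched <- stage("enriched",
                        domain_enriched(res$z, res$pairwise,
                                        z_threshold = config$z_threshold,
                                        expressed = res$expressed))
  res$specificity <- stage("specificity_table",
                           specificity_table(res$z, res$cs, res$pairwise,
                                             res$enriched))
  if (run_coexpression) {
    res$modules <- stage("coexpression",
                         coexpression_modules(res$em, beta = config$beta,
                                              cv_max = config$cv_max,
                                              merge_cut = config$merge_cut,
                                              min_module_size =
                                                config$min_module_size))
    res$module_domain <- stage("module_domain", {
      universe <- rownames(res$em$rpkm)
      module_domain_association(res$modules, res$enriched, universe,
                                fdr_sig = config$module_fdr)
    })
  }
  if (!is.null(categories)) {
    res$enrichment <- stage("enrichment", {
      universe <- unique(unlist(res$expressed))
      out <- lapply(doms, function(d) {
        q <- intersect(res$enriched[[d]], universe)
        if (!length(q)) return(NULL)
        lr_enrichment(q, categories, universe)
      })
      names(out) <- doms
      out
    })
  }
  if (!is.null(isoforms)) {
    res$as_genes <- stage("as", domain_specific_as(
      isoforms$em, isoforms$iso2gene, z_threshold = config$z_threshold,
      expressed_threshold = config$isoform_rpkm_threshold,
      rule = config$as_rule, z_on = config$z_on))
  }
  if (!is.null(lncrna)) {
    res$lncrna <- stage("lncrna", classify_lncrna(
      lncrna$assembled, lncrna$annotation, lncrna$genome,
      min_length = config$lnc_min_length,
      min_distance = config$lnc_min_distance,
      max_orf = config$lnc_max_orf))
  }
  if (!is.null(pseudogene_ids)) {
    res$pseudogenes <- stage("pseudogenes",
                             pseudogene_profile(pseudogene_ids, res$em,
                                                threshold =
                                                  config$rpkm_threshold,
                                                z_threshold =
                                                  config$z_threshold,
                                                z_on = config$z_on))
  }
  res$summary <- stage("summary", pipeline_summary(res, doms))
  res$manifest <- list(
    package = "apexdomains",
    version = as.character(utils::packageVersion("apexdomains")),
    config = unclass(config),
    n_genes = nrow(cm$counts),
    n_samples = ncol(cm$counts),
    domains = doms)
  class(res) <- "pipeline_result"
  res
}

pipeline_summary <- function(res, doms) {
  s <- list(
    expressed_per_domain = vapply(res$expressed, length, integer(1)),
    overlap_counts = res$overlap$counts,
    enriched_per_domain = vapply(res$enriched, length, integer(1)))
  if (!is.null(res$modules)) {
    tab <- table(res$modules$labels)
    s$n_modules <- length(setdiff(names(tab), "unassigned"))
    s$module_sizes <- tab[setdiff(names(tab), "unassigned")]
    s$significant_module_domain <-
      sum(res$module_domain$significant)
  }
  if (!is.null(res$as_genes)) s$n_as_genes <- length(res$as_genes)
  if (!is.null(res$lncrna)) s$lncrna_classes <- table(res$lncrna$class)
  if (!is.null(res$pseudogenes)) {
    s$n_pseudogenes_expressed <- length(res$pseudogenes$expressed)
    s$n_pseudogenes_enriched <- length(res$pseudogenes$enriched)
  }
  s
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("apexdomains pipeline result\n")
  cat("  expressed per domain: ",
      paste(names(s$expressed_per_domain), s$expressed_per_domain,
            sep = "=", collapse = " "), "\n")
  cat("  enriched per domain:  ",
      paste(names(s$enriched_per_domain), s$enriched_per_domain,
            sep = "=", collapse = " "), "\n")
  if (!is.null(s$n_modules))
    cat("  modules:", s$n_modules, "( significant module-domain cells:",
        s$significant_module_domain, ")\n")
  if (!is.null(s$n_as_genes))
    cat("  domain-specific AS genes:", s$n_as_genes, "\n")
  if (!is.null(s$lncrna_classes)) {
    cat("  lncRNA verdicts:",
        paste(names(s$lncrna_classes), s$lncrna_classes, sep = "=",
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Write the main pipeline tables to a directory
#'
#' @param res a [run_pipeline()] result.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tables(res$em, dir)
  utils::write.table(res$specificity, file.path(dir, "specificity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(res$de))
    utils::write.table(res$de[[nm]],
                       file.path(dir, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$modules)) {
    utils::write.table(
      data.frame(gene_id = names(res$modules$labels),
                 module = unname(res$modules$labels)),
      file.path(dir, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(res$modules$eigengenes))
      write_tsv_matrix(res$modules$eigengenes,
                       file.path(dir, "eigengenes.tsv"), "module")
    utils::write.table(res$module_domain,
                       file.path(dir, "module_domain.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$lncrna))
    utils::write.table(res$lncrna, file.path(dir, "lncrna_verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  u <- unlist(res$manifest)
  writeLines(paste(names(u), u, sep = "\t"),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}
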