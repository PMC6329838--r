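#' Sample design table
#'
#' Validates and normalizes a sample design mapping sequencing libraries to
#' anatomical domains. The reference shoot-apex design has nine
#' promoter-defined domains (CLV3, WUS, UFOp, AS1, AS2, FIL, ATML1, LAS, PTL)
#' with three biological replicates each, but any design with at least two
#' domains and one replicate per domain is accepted.
#'
#' @param design data.frame with columns `sample_id`, `domain_id`,
#'   `replicate` (positive integer).
#' @return A `sample_design` data.frame with domains as a factor in first
#'   appearance order.
#' @export
sample_design <- function(design) {
  req <- c("sample_id", "domain_id", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stop("design must be a data.frame with columns sample_id, domain_id, replicate")
  design <- design[, req]
  design$sample_id <- as.character(design$sample_id)
  design$replicate <- as.integer(design$replicate)
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))
  if (any(is.na(design$replicate)) || any(design$replicate < 1L))
    stop("replicate must be a positive integer")
  design$domain_id <- factor(design$domain_id,
                             levels = unique(as.character(design$domain_id)))
  if (nlevels(design$domain_id) < 2L)
    stop("design must contain at least 2 domains")
  n_per <- table(design$domain_id)
  if (any(n_per == 0L))
    stop("domain with no samples: ", paste(names(n_per)[n_per == 0L], collapse = ", "))
  class(design) <- c("sample_design", "data.frame")
  design
}

#' @export
domains <- function(x) UseMethod("domains")

#' @export
domains.sample_design <- function(x) levels(x$domain_id)

#' Count matrix container
#'
#' Bundles a genes x samples matrix of raw read counts with per-gene
#' effective lengths (bp), per-sample library sizes and the sample design.
#' Library sizes default to column sums of the count matrix; explicit totals
#' (e.g. uniquely mapped reads from the aligner) override.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param gene_length_bp named numeric vector of per-gene effective lengths.
#' @param design a [sample_design()] (or coercible data.frame).
#' @param library_size optional named numeric vector of per-sample totals.
#' @return A `count_matrix` object (list with elements `counts`,
#'   `gene_length_bp`, `library_size`, `design`).
#' @export
count_matrix <- function(counts, gene_length_bp, design, library_size = NULL) {
  if (!inherits(design, "sample_design")) design <- sample_design(design)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  missing_in_design <- setdiff(colnames(counts), design$sample_id)
  if (length(missing_in_design))
    stop("sample(s) in counts absent from design: ",
         paste(missing_in_design, collapse = ", "))
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) stop("design/count column mismatch")
  class(design) <- c("sample_design", "data.frame")
  n_per <- table(design$domain_id)
  if (any(n_per == 0L))
    stop("domain with no samples after matching counts: ",
         paste(names(n_per)[n_per == 0L], collapse = ", "))
  gl <- gene_length_bp[rownames(counts)]
  if (anyNA(gl))
    stop("gene(s) with missing length: ",
         paste(utils::head(rownames(counts)[is.na(gl)], 10), collapse = ", "))
  if (any(gl <= 0)) stop("gene lengths must be strictly positive")
  if (is.null(library_size)) {
    library_size <- colSums(counts)
  } else {
    library_size <- library_size[colnames(counts)]
    if (anyNA(library_size)) stop("library_size missing for some samples")
  }
  if (any(library_size <= 0)) stop("library sizes must be positive")
  structure(list(counts = counts,
                 gene_length_bp = as.numeric(gl),
                 library_size = as.numeric(library_size),
                 design = design),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, %d domains\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$design$domain_id)))
  invisible(x)
}

#' Read counts, gene lengths and a sample design from TSV files
#'
#' @param counts_path TSV, first column gene id, remaining columns one per
#'   sample, header row names the samples.
#' @param lengths_path TSV with columns `gene_id`, `length_bp`.
#' @param design_path TSV with columns `sample_id`, `domain_id`, `replicate`.
#' @param library_size_path optional TSV with columns `sample_id`, `total`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, lengths_path, design_path,
                        library_size_path = NULL) {
  for (p in c(counts_path, lengths_path, design_path))
    if (!file.exists(p)) stop("file not found: ", p)
  ct <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  gene_ids <- as.character(ct[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id(s) in counts file: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  m <- as.matrix(ct[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  gl <- stats::setNames(as.numeric(len$length_bp), len$gene_id)
  des <- sample_design(utils::read.delim(design_path, stringsAsFactors = FALSE))
  ls <- NULL
  if (!is.null(library_size_path)) {
    lt <- utils::read.delim(library_size_path, stringsAsFactors = FALSE)
    ls <- stats::setNames(as.numeric(lt$total), lt$sample_id)
  }
  count_matrix(m, gl, des, library_size = ls)
}

#' RPKM normalization
#'
#' Computes reads per kilobase of transcript per million mapped reads:
#' `rpkm[g,s] = counts[g,s] * 1e9 / (gene_length_bp[g] * library_size[s])`,
#' plus the per-domain mean matrix (arithmetic mean of RPKM over each
#' domain's replicates).
#'
#' @param cm a [count_matrix()].
#' @return An `expression_matrix` object: list with `rpkm` (genes x samples),
#'   `domain_means` (genes x domains) and the `design`.
#' @export
rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$library_size <= 0)) stop("library sizes must be positive")
  r <- cm$counts * 1e9 /
    outer(cm$gene_length_bp, cm$library_size)
  dimnames(r) <- dimnames(cm$counts)
  expression_matrix(r, cm$design)
}

#' Expression matrix container
#'
#' Wraps a genes x samples expression matrix (RPKM scale) and derives the
#' genes x domains matrix of replicate means.
#'
#' @param expr non-negative numeric matrix, genes x samples.
#' @param design a [sample_design()].
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(expr, design) {
  if (!inherits(design, "sample_design")) design <- sample_design(design)
  expr <- as.matrix(expr)
  if (any(!is.finite(expr))) stop("expression values must be finite")
  design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id))
    stop("expression columns do not match the design")
  class(design) <- c("sample_design", "data.frame")
  dm <- domain_mean_matrix(expr, design)
  structure(list(rpkm = expr, domain_means = dm, design = design),
            class = "expression_matrix")
}

domain_mean_matrix <- function(expr, design) {
  doms <- levels(design$domain_id)
  dm <- vapply(doms, function(d) {
    cols <- design$sample_id[design$domain_id == d]
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  if (nrow(expr) == 1L) dm <- matrix(dm, nrow = 1L, dimnames = list(rownames(expr), doms))
  dm
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d domains)\n",
              nrow(x$rpkm), ncol(x$rpkm), ncol(x$domain_means)))
  invisible(x)
}

#' Expressed-gene sets per domain
#'
#' A gene counts as expressed in a domain when its mean RPKM over that
#' domain's replicates exceeds `threshold` (strict `>`; the conventional
#' cutoff for gene-level calls is RPKM > 1).
#'
#' @param em an [expression_matrix()].
#' @param threshold RPKM cutoff (default 1).
#' @return Named list of character vectors of gene ids, one per domain, with
#'   attributes `universe` (all gene ids) and `membership` (logical
#'   genes x domains matrix).
#' @export
expressed_sets <- function(em, threshold = 1.0) {
  stopifnot(inherits(em, "expression_matrix"))
  mem <- em$domain_means > threshold
  sets <- lapply(colnames(mem), function(d) rownames(mem)[mem[, d]])
  names(sets) <- colnames(mem)
  attr(sets, "universe") <- rownames(mem)
  attr(sets, "membership") <- mem
  sets
}

#' Multi-domain overlap tally
#'
#' Counts genes expressed in exactly k domains for k = 0..D, and reports the
#' set expressed in every domain.
#'
#' @param expressed list of per-domain gene sets as from [expressed_sets()];
#'   if the `universe` attribute is absent the union of the sets is used.
#' @return List with `counts` (named integer vector, k = 0..D),
#'   `all_domains` (character vector of genes in every set) and
#'   `n_domains_per_gene` (named integer vector).
#' @export
overlap_groups <- function(expressed) {
  universe <- attr(expressed, "universe")
  if (is.null(universe)) universe <- unique(unlist(expressed))
  D <- length(expressed)
  k <- rowSums(vapply(expressed, function(s) universe %in% s,
                      logical(length(universe))))
  counts <- vapply(0:D, function(i) sum(k == i), integer(1))
  names(counts) <- as.character(0:D)
  stopifnot(sum(counts) == length(universe))
  list(counts = counts,
       all_domains = universe[k == D],
       n_domains_per_gene = stats::setNames(as.integer(k), universe))
}

#' Write an expression matrix and derived tables to TSV
#'
#' @param em an [expression_matrix()].
#' @param dir output directory (created if needed).
#' @param threshold expressed-call RPKM cutoff passed to [expressed_sets()].
#' @return Invisibly, the paths written.
#' @export
write_expression_tables <- function(em, dir, threshold = 1.0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("rpkm.tsv", "domain_means.tsv",
                            "expressed.tsv", "overlap_groups.tsv"))
  write_tsv_matrix(em$rpkm, paths[1], "gene_id")
  write_tsv_matrix(em$domain_means, paths[2], "gene_id")
  sets <- expressed_sets(em, threshold)
  write_tsv_matrix(attr(sets, "membership") * 1L, paths[3], "gene_id")
  og <- overlap_groups(sets)
  utils::write.table(data.frame(n_domains = names(og$counts),
                                n_genes = as.integer(og$counts)),
                     paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

write_tsv_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
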