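#' Coefficient-of-variation filter
#'
#' Retains genes with high relative variation across domains:
#' `CV = sd / mean` computed on domain-mean RPKM with the sample
#' (divide-by-n-1) standard deviation. Genes with `CV < cv_max` (default
#' 0.7) or zero mean are dropped; network construction then proceeds on the
#' retained genes.
#'
#' @param em an [expression_matrix()].
#' @param cv_max retention cutoff: keep genes with CV >= `cv_max`.
#' @return Character vector of retained gene ids, with a `cv` attribute
#'   holding every gene's CV.
#' @export
cv_filter <- function(em, cv_max = 0.7) {
  stopifnot(inherits(em, "expression_matrix"))
  x <- em$domain_means
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  keep <- rownames(x)[!is.na(cv) & cv >= cv_max]
  attr(keep, "cv") <- stats::setNames(cv, rownames(x))
  keep
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted network adjacency `a_ij = |cor(i, j)|^beta` on
#' log2-transformed expression (`log2(RPKM + epsilon)`), Pearson
#' correlation across samples. The diagonal is set to 0 so that
#' connectivity is `k_i = sum_{j != i} a_ij`.
#'
#' @param log_expr numeric matrix, genes x samples, already on log scale.
#' @param beta soft-threshold power (default 9).
#' @return Symmetric genes x genes adjacency matrix in `[0, 1]`, diag 0.
#' @export
adjacency <- function(log_expr, beta = 9) {
  if (ncol(log_expr) < 3L) stop("need >= 3 samples")
  v <- apply(log_expr, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(log_expr)[v == 0], 5), collapse = ", "))
  a <- abs(stats::cor(t(log_expr)))^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit
#'
#' Bins the connectivity distribution and regresses `log10(frequency)` on
#' `log10(mean k)` per bin; returns R^2 signed by the slope (positive for
#' the decreasing tail expected of scale-free networks), used to choose the
#' soft-threshold power.
#'
#' @param adj adjacency matrix (or a precomputed connectivity vector).
#' @param n_bins number of connectivity bins (default 10).
#' @return Signed R^2 in `[-1, 1]`, or NA for degenerate (single-bin) input.
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  k <- if (is.matrix(adj)) rowSums(adj) else adj
  if (length(k) < 30L) stop("need >= 30 genes")
  k <- k[k > 0]
  br <- unique(seq(min(k), max(k), length.out = n_bins + 1))
  if (length(br) < 3L) return(NA_real_)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length) / length(k)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(ok) < 3L) return(NA_real_)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  sign_slope <- -sign(stats::coef(fit)[2])  # decreasing tail -> positive
  unname(sign_slope * r2)
}

#' Candidate-power scale-free table
#'
#' @param log_expr genes x samples log expression.
#' @param powers integer vector of candidate soft thresholds.
#' @return data.frame with `power`, `r_squared`, `mean_k`.
#' @export
pick_soft_threshold <- function(log_expr, powers = c(1:10, 12, 14, 16)) {
  rows <- lapply(powers, function(b) {
    a <- adjacency(log_expr, beta = b)
    data.frame(power = b, r_squared = scale_free_fit(a),
               mean_k = mean(rowSums(a)))
  })
  do.call(rbind, rows)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `TOM_ii = 1`; measures how much two genes share network neighbors
#' in addition to their direct connection. Bounded in `[0, 1]` for
#' adjacency in `[0, 1]`.
#'
#' @param adj symmetric adjacency in `[0, 1]` with zero diagonal.
#' @return Symmetric TOM matrix.
#' @export
tom <- function(adj) {
  a <- as.matrix(adj)
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  t_mat <- (l + a) / denom
  diag(t_mat) <- 1
  dimnames(t_mat) <- dimnames(a)
  t_mat
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix,
#' sign-oriented so the mean gene-eigengene correlation is non-negative;
#' one value per sample, unit-normalized.
#'
#' @param log_expr genes x samples log expression restricted to the module
#'   (>= 2 genes).
#' @return Numeric vector, one entry per sample, with attribute
#'   `var_explained` (proportion of module variance carried by the PC).
#' @export
module_eigengene <- function(log_expr) {
  x <- as.matrix(log_expr)
  if (nrow(x) < 2L) stop("module must have >= 2 genes")
  xs <- t(scale(t(x)))  # standardize each gene
  xs[!is.finite(xs)] <- 0
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  r <- stats::cor(t(xs), e)
  if (mean(r, na.rm = TRUE) < 0) e <- -e
  attr(e, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  stats::setNames(e, colnames(x))
}

# candidate cut heights between consecutive merge heights of an hclust tree
candidate_cut_heights <- function(hc, max_candidates = 60L) {
  h <- sort(unique(hc$height))
  if (length(h) < 2L) return(h)
  mids <- (h[-1] + h[-length(h)]) / 2
  if (length(mids) > max_candidates)
    mids <- unique(stats::quantile(mids, seq(0, 1, length.out = max_candidates),
                                   names = FALSE))
  mids
}

# clusters at a given cut that satisfy size and eigengene-cohesion floors
valid_clusters_at <- function(hc, height, log_expr, min_module_size,
                              min_cohesion) {
  cl <- stats::cutree(hc, h = height)
  keep <- character(0)
  for (lab in unique(cl)) {
    genes <- names(cl)[cl == lab]
    if (length(genes) < min_module_size) next
    e <- module_eigengene(log_expr[genes, , drop = FALSE])
    kme2 <- stats::cor(t(log_expr[genes, , drop = FALSE]), e)^2
    if (mean(kme2, na.rm = TRUE) >= min_cohesion)
      keep <- c(keep, lab)
  }
  list(clusters = cl, valid = keep)
}

#' Module detection by adaptive tree cut and eigengene merging
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, followed by an
#' adaptive branch cut: candidate cut heights (midpoints between merge
#' heights) are scanned and the height producing the largest number of
#' valid modules is chosen, where a valid module has at least
#' `min_module_size` genes and a coherent eigengene (mean squared
#' gene-eigengene correlation >= `min_cohesion`; random clusters of this
#' size sit well below that bound, so shapeless branches are rejected and a
#' pure-noise input yields no modules). Genes stranded above the chosen cut
#' are then assigned to the module whose eigengene they track most closely
#' (|kME| >= sqrt(`min_cohesion`)). Modules whose eigengenes are closer
#' than `merge_cut` in correlation dissimilarity (`1 - cor < merge_cut`)
#' are then merged iteratively, closest pair first, until stable.
#'
#' @param tom_mat TOM (or any similarity in `[0, 1]` with unit diagonal).
#' @param log_expr genes x samples log expression for eigengene
#'   computation; rownames must cover the TOM genes.
#' @param min_module_size smallest admissible module (default 30).
#' @param merge_cut eigengene dissimilarity below which modules merge
#'   (default 0.20, i.e. eigengene correlation > 0.80).
#' @param min_cohesion eigengene variance-explained floor (default 0.25).
#' @return A `module_assignment`: list with `labels` (named character
#'   vector, "M1".."Mk" or "unassigned"), `eigengenes` (modules x samples
#'   matrix), `merge_history` (data.frame), `cut_height`.
#' @export
detect_modules <- function(tom_mat, log_expr, min_module_size = 30,
                           merge_cut = 0.20, min_cohesion = 0.25) {
  genes <- rownames(tom_mat)
  if (is.null(genes)) genes <- rownames(log_expr)[seq_len(nrow(tom_mat))]
  dimnames(tom_mat) <- list(genes, genes)
  log_expr <- log_expr[genes, , drop = FALSE]
  empty <- function(msg) {
    warning(msg)
    structure(list(labels = stats::setNames(rep("unassigned", length(genes)),
                                            genes),
                   eigengenes = NULL,
                   merge_history = data.frame(),
                   cut_height = NA_real_),
              class = "module_assignment")
  }
  if (length(genes) < min_module_size)
    return(empty("fewer genes than min_module_size; nothing assigned"))
  hc <- stats::hclust(stats::as.dist(1 - tom_mat), method = "average")
  best <- NULL; best_h <- NA_real_
  for (h in candidate_cut_heights(hc)) {
    cand <- valid_clusters_at(hc, h, log_expr, min_module_size, min_cohesion)
    if (is.null(best) ||
        length(cand$valid) > length(best$valid) ||
        (length(cand$valid) == length(best$valid) && length(cand$valid) > 0 &&
         sum(cand$clusters %in% cand$valid) > sum(best$clusters %in% best$valid))) {
      best <- cand; best_h <- h
    }
  }
  if (is.null(best) || !length(best$valid))
    return(empty("no module satisfied the size and cohesion floors"))
  labels <- stats::setNames(rep("unassigned", length(genes)), genes)
  mods <- split(names(best$clusters), best$clusters)[best$valid]
  # membership refinement: a single global cut strands genes whose branch
  # joins slightly above it, so unassigned genes with a strong eigengene
  # correlation (|kME| >= sqrt of the cohesion floor) join the closest
  # module, in the manner of the dynamic hybrid PAM stage
  loose <- setdiff(genes, unlist(mods))
  if (length(loose) && length(mods)) {
    me0 <- vapply(mods, function(g)
      as.numeric(module_eigengene(log_expr[g, , drop = FALSE])),
      numeric(ncol(log_expr)))
    kme <- abs(stats::cor(t(log_expr[loose, , drop = FALSE]), me0))
    pick <- max.col(kme, ties.method = "first")
    ok <- kme[cbind(seq_along(loose), pick)] >= sqrt(min_cohesion)
    for (i in which(ok))
      mods[[pick[i]]] <- c(mods[[pick[i]]], loose[i])
  }
  # merge eigengene-similar modules, closest pair first
  history <- data.frame(step = integer(), merged = character(),
                        into = character(), dissim = numeric())
  repeat {
    if (length(mods) < 2L) break
    me <- vapply(mods, function(g)
      as.numeric(module_eigengene(log_expr[g, , drop = FALSE])),
      numeric(ncol(log_expr)))
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[ij[1], ij[2]] >= merge_cut) break
    i <- ij[1]; j <- ij[2]
    history <- rbind(history, data.frame(
      step = nrow(history) + 1L,
      merged = names(mods)[j], into = names(mods)[i],
      dissim = d[i, j]))
    mods[[i]] <- c(mods[[i]], mods[[j]])
    mods <- mods[-j]
  }
  # relabel by decreasing size
  mods <- mods[order(-lengths(mods))]
  names(mods) <- paste0("M", seq_along(mods))
  for (m in names(mods)) labels[mods[[m]]] <- m
  me <- t(vapply(mods, function(g)
    as.numeric(module_eigengene(log_expr[g, , drop = FALSE])),
    numeric(ncol(log_expr))))
  colnames(me) <- colnames(log_expr)
  structure(list(labels = labels, eigengenes = me,
                 merge_history = history, cut_height = best_h),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(x$labels)
  mods <- setdiff(names(tab), "unassigned")
  cat(sprintf("module_assignment: %d modules over %d genes (%d unassigned)\n",
              length(mods), length(x$labels),
              sum(x$labels == "unassigned")))
  if (length(mods)) print(tab[mods])
  invisible(x)
}

#' Full co-expression workflow
#'
#' CV filter, log2 transform, adjacency at the chosen power, TOM, module
#' detection and eigengene merging in one call.
#'
#' @param em an [expression_matrix()].
#' @param beta soft power (default 9).
#' @param cv_max CV retention cutoff (default 0.7).
#' @param epsilon RPKM offset before log2 (default 1).
#' @param ... passed to [detect_modules()].
#' @return The [detect_modules()] result with extra elements `genes_used`
#'   and `beta`.
#' @export
coexpression_modules <- function(em, beta = 9, cv_max = 0.7, epsilon = 1,
                                 ...) {
  keep <- cv_filter(em, cv_max)
  if (!length(keep)) stop("CV filter removed every gene")
  lx <- log2(em$rpkm[keep, , drop = FALSE] + epsilon)
  a <- adjacency(lx, beta = beta)
  ma <- detect_modules(tom(a), lx, ...)
  ma$genes_used <- keep
  ma$beta <- beta
  ma
}

#' Export a thresholded network edge list
#'
#' @param tom_mat TOM matrix.
#' @param path output TSV path.
#' @param threshold minimum TOM weight to flag an edge (default 0.1);
#'   all pairs above `write_min` are written.
#' @param write_min smallest weight written at all (default `threshold`).
#' @return Invisibly, the path.
#' @export
write_edge_list <- function(tom_mat, path, threshold = 0.1,
                            write_min = threshold) {
  idx <- which(upper.tri(tom_mat) & tom_mat >= write_min, arr.ind = TRUE)
  df <- data.frame(node_a = rownames(tom_mat)[idx[, 1]],
                   node_b = colnames(tom_mat)[idx[, 2]],
                   weight = tom_mat[idx],
                   above_threshold = tom_mat[idx] >= threshold)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
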