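#' Simulation configuration
#'
#' Defaults emulate the reference shoot-apex TRAP-seq design: 9 domains x 3
#' replicates, negative-binomial counts at sequencing depth ~1e6 with
#' dispersion 0.1, 50 planted domain-specific genes per domain at 8-fold,
#' and 5 planted co-expression modules of 100 genes driven by per-sample
#' latent factors (loading 0.8, amplitude 3 log2 units so module genes pass
#' the CV >= 0.7 network filter, as the high-CV gene set used for network
#' construction does in real data).
#'
#' @param n_domains number of domains.
#' @param domain_labels domain names (defaults to the nine shoot-apex
#'   reporter domains).
#' @param n_reps replicates per domain.
#' @param n_genes total genes.
#' @param n_specific_per_domain planted specific genes per domain.
#' @param fold_change planted fold change (> 1).
#' @param dispersion NB dispersion phi (0 = Poisson).
#' @param library_size_mean,library_size_jitter per-sample depth and
#'   relative uniform jitter.
#' @param n_modules,module_size,module_loading,module_amplitude planted
#'   module structure (loading in (0, 1]; amplitude in log2 units).
#' @param n_isoform_genes genes in the isoform-level simulation.
#' @param seed RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_domains = 9,
                              domain_labels = c("CLV3", "WUS", "UFOp", "AS1",
                                                "AS2", "FIL", "ATML1", "LAS",
                                                "PTL")[seq_len(n_domains)],
                              n_reps = 3, n_genes = 2000,
                              n_specific_per_domain = 50, fold_change = 8,
                              dispersion = 0.1,
                              library_size_mean = 1e6,
                              library_size_jitter = 0.1,
                              n_modules = 5, module_size = 100,
                              module_loading = 0.8, module_amplitude = 3,
                              n_isoform_genes = 200, seed = 1) {
  if (length(domain_labels) != n_domains)
    stop("domain_labels must have n_domains entries")
  if (fold_change <= 1) stop("fold_change must exceed 1")
  if (module_loading <= 0 || module_loading > 1)
    stop("module_loading must lie in (0, 1]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  n_planted <- n_domains * n_specific_per_domain + n_modules * module_size
  if (n_planted > n_genes)
    stop("more planted genes (", n_planted, ") than genes (", n_genes, ")")
  cfg <- as.list(environment())
  cfg$n_planted <- NULL
  structure(cfg, class = "simulation_config")
}

#' Simulate a TRAP-seq style count matrix with planted truth
#'
#' Baseline per-gene abundances are log-normal; planted domain-specific
#' genes are multiplied by `fold_change` in their domain; module genes add
#' `amplitude * (loading * f + sqrt(1 - loading^2) * e)` on the log2 scale,
#' with `f` a per-sample module factor and `e` idiosyncratic. Expected
#' counts are proportional to abundance x gene length, column-normalized to
#' the jittered library size, and counts are drawn NB (Poisson at phi = 0).
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return List with `cm` (a [count_matrix()]) and `truth` (data.frame:
#'   `gene_id`, `planted_domain` (NA = none), `planted_module` (NA =
#'   none)).
#' @export
simulate_counts <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  D <- cfg$n_domains; R <- cfg$n_reps
  n_samples <- D * R
  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  design <- sample_design(data.frame(
    sample_id = paste(rep(cfg$domain_labels, each = R),
                      rep(seq_len(R), D), sep = "_r"),
    domain_id = rep(cfg$domain_labels, each = R),
    replicate = rep(seq_len(R), D)))
  planted_domain <- rep(NA_character_, cfg$n_genes)
  idx <- 0
  for (d in cfg$domain_labels) {
    planted_domain[idx + seq_len(cfg$n_specific_per_domain)] <- d
    idx <- idx + cfg$n_specific_per_domain
  }
  planted_module <- rep(NA_character_, cfg$n_genes)
  for (m in seq_len(cfg$n_modules)) {
    planted_module[idx + seq_len(cfg$module_size)] <- paste0("sim", m)
    idx <- idx + cfg$module_size
  }
  w <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1.5)
  len <- round(stats::runif(cfg$n_genes, 500, 5000))
  names(len) <- gene_ids
  lib <- round(cfg$library_size_mean *
                 (1 + stats::runif(n_samples, -cfg$library_size_jitter,
                                   cfg$library_size_jitter)))
  rel <- matrix(w * len, cfg$n_genes, n_samples)
  for (g in which(!is.na(planted_domain))) {
    cols <- which(design$domain_id == planted_domain[g])
    rel[g, cols] <- rel[g, cols] * cfg$fold_change
  }
  lam <- cfg$module_loading
  for (m in unique(stats::na.omit(planted_module))) {
    f <- stats::rnorm(n_samples)
    gs <- which(planted_module == m)
    e <- matrix(stats::rnorm(length(gs) * n_samples), length(gs))
    shift <- cfg$module_amplitude *
      (lam * matrix(f, length(gs), n_samples, byrow = TRUE) +
         sqrt(1 - lam^2) * e)
    rel[gs, ] <- rel[gs, ] * 2^shift
  }
  mu <- sweep(rel, 2, colSums(rel), `/`)
  mu <- sweep(mu, 2, lib, `*`)
  counts <- if (cfg$dispersion < 1e-12) {
    matrix(stats::rpois(length(mu), mu), nrow(mu))
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
           nrow(mu))
  }
  dimnames(counts) <- list(gene_ids, design$sample_id)
  list(cm = count_matrix(counts, len, design),
       truth = data.frame(gene_id = gene_ids,
                          planted_domain = planted_domain,
                          planted_module = planted_module,
                          stringsAsFactors = FALSE))
}

#' Simulate an isoform-level RPKM matrix with planted splicing truth
#'
#' Each gene carries two isoforms. A third of the genes are planted with
#' disagreeing isoform patterns (isoform 1 enriched in one domain at the
#' configured fold change, isoform 2 flat), a third with both isoforms
#' enriched in the same domain, and a third flat; multiplicative log-normal
#' replicate noise throughout. Under the disagreement rule only the first
#' class is a true domain-specific AS gene.
#'
#' @param cfg a [simulation_config()].
#' @param noise_sd log-scale replicate noise sd (default 0.25).
#' @return List with `em` (isoform [expression_matrix()]), `iso2gene`
#'   (named vector), `truth` (data.frame: `gene_id`, `class`, `as_gene`).
#' @export
simulate_isoforms <- function(cfg = simulation_config(), noise_sd = 0.25) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_isoform_genes
  genes <- sprintf("isogene_%03d", seq_len(n))
  classes <- rep(c("as_disagree", "as_same", "flat"), length.out = n)
  design <- sample_design(data.frame(
    sample_id = paste(rep(cfg$domain_labels, each = cfg$n_reps),
                      rep(seq_len(cfg$n_reps), cfg$n_domains), sep = "_r"),
    domain_id = rep(cfg$domain_labels, each = cfg$n_reps),
    replicate = rep(seq_len(cfg$n_reps), cfg$n_domains)))
  iso_ids <- c(paste0(genes, ".1"), paste0(genes, ".2"))
  iso2gene <- stats::setNames(rep(genes, 2), iso_ids)
  base <- stats::rlnorm(2 * n, meanlog = log(20), sdlog = 0.5)
  rel <- matrix(base, 2 * n, nrow(design))
  target <- sample(cfg$domain_labels, n, replace = TRUE)
  for (i in seq_len(n)) {
    cols <- which(design$domain_id == target[i])
    if (classes[i] == "as_disagree") {
      rel[i, cols] <- rel[i, cols] * cfg$fold_change
    } else if (classes[i] == "as_same") {
      rel[i, cols] <- rel[i, cols] * cfg$fold_change
      rel[n + i, cols] <- rel[n + i, cols] * cfg$fold_change
    }
  }
  noise <- matrix(exp(stats::rnorm(length(rel), 0, noise_sd)), nrow(rel))
  expr <- rel * noise
  dimnames(expr) <- list(iso_ids, design$sample_id)
  list(em = expression_matrix(expr, design),
       iso2gene = iso2gene,
       truth = data.frame(gene_id = genes, class = classes,
                          as_gene = classes == "as_disagree",
                          stringsAsFactors = FALSE))
}

# random sequence free of ATG (so the background contributes no ORF)
rand_seq_no_atg <- function(n) {
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  while (grepl("ATG", s, fixed = TRUE))
    s <- gsub("ATG", "ATT", s, fixed = TRUE)
  s
}

# complete ORF of exactly `len` nt (ATG + neutral codons + TAA), no internal
# ATG or stop
planted_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  paste0("ATG", strrep("CCT", len / 3 - 2), "TAA")
}

write_into <- function(seq, at, piece) {
  paste0(substr(seq, 1, at - 1), piece,
         substr(seq, at + nchar(piece), nchar(seq)))
}

#' Toy genome and transcript fixture for the lncRNA classifier
#'
#' Builds an ~85 kb synthetic chromosome with two annotated coding genes, a
#' known two-exon lncRNA, a transposon and a pseudogene, plus an assembled
#' transcript set enumerating every verdict class and every decision
#' boundary: exact known match, 5'-extended known, coding overlap, spliced
#' length exactly 200 (rejected) and 201 (novel), coding-gene gap exactly
#' 499 (rejected) and 500 (novel), longest ORF exactly 300 (novel) and 303
#' (rejected), and a transposon overlap. The background sequence contains
#' no ATG, so ORFs exist only where planted.
#'
#' @param seed RNG seed for the background sequence.
#' @return List with `genome` (DNAStringSet), `annotation` and `assembled`
#'   ([transcript_models()]), and `truth` (data.frame: `transcript_id`,
#'   `class`, `reject_reason`).
#' @export
simulate_genome <- function(seed = 1) {
  set.seed(seed)
  n <- 85000
  chrom <- rand_seq_no_atg(n)
  # trailing CC spacer prevents the piece/background junction from creating
  # a fresh ATG that would extend past the planted stop
  chrom <- write_into(chrom, 75051, paste0(planted_orf(300), "CC"))  # t_novel
  chrom <- write_into(chrom, 78051, paste0(planted_orf(303), "CC"))  # t_orf303
  ex <- function(tx, gene, bt, starts, ends)
    data.frame(transcript_id = tx, gene_id = gene, chrom = "chrS",
               strand = "+", start = starts, end = ends, biotype = bt,
               stringsAsFactors = FALSE)
  annotation <- transcript_models(rbind(
    ex("codingA.1", "codingA", "coding", c(1000, 2200), c(1800, 3000)),
    ex("codingB.1", "codingB", "coding", 20000, 22000),
    ex("lncK.1", "lncK", "lncRNA_known", c(40001, 40601), c(40400, 40800)),
    ex("te1", "te1", "transposon", 60001, 61000),
    ex("pseudo1.1", "pseudo1", "pseudogene", 65001, 65600)))
  assembled <- transcript_models(rbind(
    ex("t_overlaps_coding", "t_overlaps_coding", "assembled", 2500, 2900),
    ex("t_known", "t_known", "assembled", c(40001, 40601), c(40400, 40800)),
    ex("t_known_ext", "t_known_ext", "assembled",
       c(39951, 40601), c(40400, 40800)),
    ex("t_short200", "t_short200", "assembled", 70001, 70200),
    ex("t_len201", "t_len201", "assembled", 71001, 71201),
    ex("t_near499", "t_near499", "assembled", 22500, 22800),
    ex("t_near500", "t_near500", "assembled", 22501, 22801),
    ex("t_te_overlap", "t_te_overlap", "assembled", 60500, 60900),
    ex("t_novel_orf300", "t_novel_orf300", "assembled", 75001, 75400),
    ex("t_orf303", "t_orf303", "assembled", 78001, 78400)))
  truth <- data.frame(
    transcript_id = c("t_overlaps_coding", "t_known", "t_known_ext",
                      "t_short200", "t_len201", "t_near499", "t_near500",
                      "t_te_overlap", "t_novel_orf300", "t_orf303"),
    class = c("rejected", "known", "known_extended", "rejected", "novel",
              "rejected", "novel", "rejected", "novel", "rejected"),
    reject_reason = c("overlaps_coding", "none", "none", "too_short",
                      "none", "near_coding", "none", "transposon_overlap",
                      "none", "long_orf"),
    stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chrS"
  list(genome = genome, annotation = annotation, assembled = assembled,
       truth = truth)
}

#' Write the count-simulation outputs in pipeline input format
#'
#' @param sim result of [simulate_counts()].
#' @param dir output directory.
#' @return Invisibly, the paths written (counts.tsv, lengths.tsv,
#'   design.tsv, truth.tsv).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "lengths.tsv", "design.tsv",
                            "truth.tsv"))
  write_tsv_matrix(sim$cm$counts, paths[1], "gene_id")
  utils::write.table(
    data.frame(gene_id = rownames(sim$cm$counts),
               length_bp = sim$cm$gene_length_bp),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$cm$design), paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
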