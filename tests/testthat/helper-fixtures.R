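# Shared fixtures; the expensive ones are computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default study-condition simulation (9 domains x 3 reps, 2000 genes,
# 50 planted/domain at 8x, phi = 0.1, 5 modules) and its full pipeline run
default_sim <- function() cached("sim", simulate_counts(simulation_config()))

default_run <- function() cached("run", run_pipeline(default_sim()$cm))

null_sim <- function() cached("null_sim", simulate_counts(
  simulation_config(n_specific_per_domain = 0, n_modules = 0, seed = 11)))

null_contrast <- function() cached("null_de",
                                   pairwise_de(null_sim()$cm, "CLV3", "WUS"))

lnc_fixture <- function() cached("lnc", simulate_genome(seed = 3))

# tiny deterministic count fixture: 3 genes x 6 samples, 2 domains
tiny_cm <- function() {
  counts <- matrix(c(100, 200, 0,
                     120, 180, 0,
                     90, 210, 3,
                     10, 400, 0,
                     12, 380, 1,
                     8, 420, 0),
                   nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"),
                                   paste0("s", 1:6)))
  design <- data.frame(sample_id = paste0("s", 1:6),
                       domain_id = rep(c("A", "B"), each = 3),
                       replicate = rep(1:3, 2))
  count_matrix(counts, c(g1 = 1000, g2 = 2000, g3 = 500), design,
               library_size = setNames(rep(1e6, 6), paste0("s", 1:6)))
}

# small expression_matrix straight from a domain-mean specification:
# each domain value is replicated across `reps` samples (no noise)
em_from_domain_means <- function(dm, reps = 3) {
  doms <- colnames(dm)
  expr <- dm[, rep(seq_along(doms), each = reps), drop = FALSE]
  colnames(expr) <- paste0(rep(doms, each = reps), "_r", rep(seq_len(reps),
                                                             length(doms)))
  design <- data.frame(sample_id = colnames(expr),
                       domain_id = rep(doms, each = reps),
                       replicate = rep(seq_len(reps), length(doms)))
  expression_matrix(expr, design)
}

write_tiny_input_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE)
  cm <- tiny_cm()
  counts <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                       check.names = FALSE)
  write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = rownames(cm$counts),
                         length_bp = cm$gene_length_bp),
              file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(cm$design), file.path(dir, "design.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dir
}
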