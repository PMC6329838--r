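test_that("CV filter drops flat genes and keeps variable ones", {
  dm <- rbind(constant = rep(4, 9),
              spike = c(rep(1, 8), 10),
              mild = c(rep(4, 8), 5))
  colnames(dm) <- paste0("D", 1:9)
  em <- em_from_domain_means(dm)
  keep <- cv_filter(em)
  cv <- attr(keep, "cv")
  expect_false("constant" %in% keep)
  expect_true("spike" %in% keep)
  expect_equal(unname(cv["spike"]), 3 / 2)  # mean 2, sample sd 3
  expect_false("mild" %in% keep)
  # membership matches direct evaluation for random matrices
  set.seed(41)
  dm2 <- matrix(rlnorm(9 * 60, log(5), 1), 60, 9,
                dimnames = list(sprintf("g%02d", 1:60), paste0("D", 1:9)))
  keep2 <- cv_filter(em_from_domain_means(dm2))
  brute <- rownames(dm2)[apply(dm2, 1, sd) / rowMeans(dm2) >= 0.7]
  expect_setequal(keep2, brute)
})

test_that("adjacency is |cor|^beta with zero diagonal", {
  s <- seq_len(10)
  x <- rbind(up = s, up2 = 2 * s + 3, down = -s,
             half = NA)
  set.seed(42)
  # construct a pair with known correlation 0.5 via orthogonal components
  a1 <- scale(rnorm(10))[, 1]; a2 <- scale(residuals(lm(rnorm(10) ~ a1)))[, 1]
  x["half", ] <- 0.5 * a1 + sqrt(0.75) * a2
  x <- rbind(x, base = a1)
  adj <- adjacency(x, beta = 9)
  expect_equal(adj["up", "up2"], 1)            # cor +1
  expect_equal(adj["up", "down"], 1)           # cor -1, unsigned
  expect_equal(adj["base", "half"], 0.5^9, tolerance = 1e-9)
  expect_true(all(diag(adj) == 0))
  x_const <- rbind(x, flat = rep(1, 10))
  expect_error(adjacency(x_const), "flat")
})

test_that("scale-free fit separates power-law from uniform degree sequences", {
  set.seed(43)
  k_pl <- (1 - runif(2000))^(-1 / 1.5)      # Pareto tail, alpha ~ 2.5
  expect_gt(scale_free_fit(k_pl), 0.95)
  k_unif <- runif(2000, 0.5, 1.5)
  expect_lt(scale_free_fit(k_unif), scale_free_fit(k_pl))
  expect_error(scale_free_fit(runif(10)), ">= 30")
})

test_that("soft-threshold table reports one row per candidate power", {
  set.seed(44)
  x <- matrix(rnorm(40 * 12), 40)
  rownames(x) <- sprintf("g%02d", 1:40)
  tab <- pick_soft_threshold(x, powers = c(2, 6))
  expect_equal(tab$power, c(2, 6))
  expect_true(all(is.na(tab$r_squared) | abs(tab$r_squared) <= 1))
  expect_true(all(diff(tab$mean_k) < 0))  # connectivity shrinks with power
})

test_that("TOM matches its definition, bounds and special cases", {
  # unit triangle: TOM = (1 + 1) / (2 + 1 - 1) = 1
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_true(all(tom(tri) == 1))
  # empty graph
  none <- matrix(0, 4, 4)
  expect_true(all(tom(none)[upper.tri(none)] == 0))
  # binary adjacency with no shared neighbors reduces to
  # a_ij / (min(k_i, k_j) + 1 - a_ij)
  chain <- matrix(0, 4, 4)
  chain[1, 2] <- chain[2, 1] <- 1
  chain[3, 4] <- chain[4, 3] <- 1
  tt <- tom(chain)
  expect_equal(tt[1, 2], 1 / (1 + 1 - 1))
  expect_equal(tt[1, 3], 0)
  # random adjacency equals the brute-force triple loop and stays in [0,1]
  set.seed(45)
  a <- matrix(runif(400), 20); a <- (a + t(a)) / 2; diag(a) <- 0
  got <- tom(a)
  expect_equal(got, tom_brute(a), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(got >= 0 & got <= 1 + 1e-12))
})

test_that("module eigengene is the oriented first PC", {
  set.seed(46)
  prof <- rnorm(12)
  x <- matrix(rep(prof, each = 5), 5, byrow = FALSE) +
    matrix(rnorm(60, sd = 1e-8), 5)
  rownames(x) <- paste0("g", 1:5); colnames(x) <- paste0("s", 1:12)
  e <- module_eigengene(x)
  # identical genes: eigengene is the standardized common profile
  expect_equal(abs(cor(e, prof)), 1, tolerance = 1e-6)
  expect_gte(mean(cor(t(x), e)), 0)
  # flipping every gene leaves the orientation rule's output usable
  e_flip <- module_eigengene(-x)
  expect_gte(mean(cor(t(-x), e_flip)), 0)
  # 2-gene module: eigengene equally correlated (in magnitude) with both
  x2 <- rbind(a = rnorm(12), b = rnorm(12))
  e2 <- module_eigengene(x2)
  r <- cor(t(x2), e2)
  expect_equal(abs(r[1]), abs(r[2]), tolerance = 1e-9)
  expect_error(module_eigengene(x2[1, , drop = FALSE]), ">= 2")
})

# factor-model expression: block loadings on shared factors plus noise
make_blocks <- function(n_per_block, loadings, n_samples, noise_sd = 1,
                        shared = NULL) {
  blocks <- length(n_per_block)
  f <- matrix(rnorm(blocks * n_samples), blocks)
  if (!is.null(shared)) f <- f + matrix(shared, blocks, n_samples,
                                        byrow = TRUE)
  x <- do.call(rbind, lapply(seq_len(blocks), function(b) {
    matrix(rep(f[b, ], each = n_per_block[b]), n_per_block[b]) *
      loadings[b] +
      matrix(rnorm(n_per_block[b] * n_samples, sd = noise_sd),
             n_per_block[b])
  }))
  rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  x
}

test_that("two planted correlation blocks are recovered as two modules", {
  set.seed(47)
  x <- make_blocks(c(100, 100), loadings = c(2, 2), n_samples = 27)
  ma <- detect_modules(tom(adjacency(x, 9)), x, min_module_size = 30)
  mods <- setdiff(unique(ma$labels), "unassigned")
  expect_equal(length(mods), 2L)
  truth <- rep(c("b1", "b2"), each = 100)
  expect_gte(adjusted_rand(ma$labels, truth), 0.95)
})

test_that("blocks driven by one latent factor merge at the eigengene step", {
  set.seed(48)
  shared <- rnorm(27) * 1.0
  # block-specific factors are weak relative to the shared one:
  # eigengene correlation > 0.8 -> dissimilarity < 0.20 -> merged
  f1 <- rnorm(27) * 0.45; f2 <- rnorm(27) * 0.45
  x <- rbind(
    matrix(rep(shared + f1, each = 60), 60) + matrix(rnorm(60 * 27, sd = 0.4), 60),
    matrix(rep(shared + f2, each = 60), 60) + matrix(rnorm(60 * 27, sd = 0.4), 60))
  rownames(x) <- sprintf("g%03d", 1:120); colnames(x) <- sprintf("s%02d", 1:27)
  ma <- detect_modules(tom(adjacency(x, 9)), x, min_module_size = 30,
                       merge_cut = 0.20)
  mods <- setdiff(unique(ma$labels), "unassigned")
  expect_equal(length(mods), 1L)
  ma_nomerge <- detect_modules(tom(adjacency(x, 9)), x, min_module_size = 30,
                               merge_cut = 1e-6)
  expect_gte(length(setdiff(unique(ma_nomerge$labels), "unassigned")), 2L)
})

test_that("pure noise yields no modules and detection is order-equivariant", {
  set.seed(49)
  x <- matrix(rnorm(200 * 27), 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:27)))
  expect_warning(ma <- detect_modules(tom(adjacency(x, 9)), x,
                                      min_module_size = 30),
                 "no module")
  expect_true(all(ma$labels == "unassigned"))

  # permuting gene order only permutes labels (ARI = 1), and reruns are
  # deterministic
  set.seed(50)
  xb <- make_blocks(c(60, 60), loadings = c(2, 2), n_samples = 20,
                    noise_sd = 1)
  tomb <- tom(adjacency(xb, 9))
  m1 <- detect_modules(tomb, xb)
  m2 <- detect_modules(tomb, xb)
  expect_identical(m1$labels, m2$labels)
  perm <- sample(nrow(xb))
  m3 <- detect_modules(tomb[perm, perm], xb[perm, ])
  expect_equal(adjusted_rand(m1$labels[rownames(xb)[perm]], m3$labels), 1)
})
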