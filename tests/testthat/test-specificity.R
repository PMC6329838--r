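test_that("z-scores: sigma-zero rule, one-outlier closed form, formula match", {
  # equal expression across all 9 domains -> z = 0 everywhere
  flat <- matrix(5, 2, 9, dimnames = list(c("g1", "g2"), paste0("D", 1:9)))
  expect_true(all(zscore_matrix(flat) == 0))

  # one outlier among 9: z = sqrt(8) in the outlying domain, regardless of
  # the two values
  for (vals in list(c(3, 7), c(0.1, 500), c(10, 11))) {
    x <- matrix(vals[1], 1, 9)
    x[9] <- vals[2]
    z <- zscore_matrix(x)
    expect_equal(z[1, 9], sqrt(8), tolerance = 1e-9)
  }

  # random vectors match direct evaluation of (x - mu) / sigma_pop
  set.seed(21)
  x <- matrix(rlnorm(9 * 50), 50, 9)
  z <- zscore_matrix(x)
  for (i in c(1, 17, 50)) {
    mu <- mean(x[i, ]); s <- sqrt(mean((x[i, ] - mu)^2))
    expect_equal(z[i, ], (x[i, ] - mu) / s, tolerance = 1e-12)
  }
  # rows sum to zero with unit population sd
  expect_lt(max(abs(rowSums(z))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(z^2)) - 1)), 1e-9)
})

test_that("sample-referenced domain z equals the domain-mean z when replicates agree", {
  dm <- matrix(rlnorm(9 * 20, log(10), 1), 20, 9,
               dimnames = list(sprintf("g%02d", 1:20), paste0("D", 1:9)))
  em <- em_from_domain_means(dm)  # replicates identical by construction
  expect_equal(domain_zscores(em, z_on = "samples"),
               domain_zscores(em, z_on = "domain_means"), tolerance = 1e-9)
  expect_equal(unname(domain_zscores(em)[1, ]),
               unname(zscore_matrix(dm)[1, ]), tolerance = 1e-9)
})

test_that("CS score: exclusivity, uniformity, ratio formula, undefined cases", {
  dm <- rbind(exclusive = c(0, 0, 0, 4),
              uniform = c(3, 3, 3, 3),
              zero = c(0, 0, 0, 0))
  colnames(dm) <- paste0("D", 1:4)
  cs <- cs_score(dm)
  expect_equal(cs["exclusive", "D4"], 1)
  expect_true(all(is.na(cs["exclusive", 1:3])))  # zero focal denominator
  expect_equal(unname(cs["uniform", ]), rep(0, 4))
  expect_true(all(is.na(cs["zero", ])))

  nine <- matrix(c(rep(2, 8), 10), 1, dimnames = list("g", paste0("D", 1:9)))
  expect_equal(cs_score(nine)["g", "D9"], 1 - 2 / 10)
  expect_equal(cs_score(nine)["g", "D1"], 1 - 10 / 2)
  expect_true(all(cs_score(nine) <= 1))
})

test_that("the argmax domain maximizes both z and CS", {
  set.seed(22)
  dm <- matrix(rlnorm(9 * 100, log(5), 1.2), 100, 9,
               dimnames = list(sprintf("g%03d", 1:100), paste0("D", 1:9)))
  z <- zscore_matrix(dm)
  cs <- cs_score(dm)
  for (i in seq_len(nrow(dm))) {
    am <- which.max(dm[i, ])
    expect_equal(which.max(z[i, ]), am)
    expect_equal(which.max(cs[i, ]), am)
  }
})

test_that("pairwise specificity requires every contrast to pass", {
  mk_de <- function(lfc, fdr)
    data.frame(gene_id = c("gA", "gB", "gflat"), log2fc = lfc,
               pvalue = fdr / 2, fdr = fdr)
  # gA passes all 8, gB passes 7 of 8, gflat none
  de_list <- lapply(1:8, function(i)
    mk_de(lfc = c(3, if (i == 8) 0.2 else 3, 0),
          fdr = c(1e-4, if (i == 8) 0.8 else 1e-4, 0.9)))
  ps <- pairwise_specific(de_list)
  expect_true(ps[["gA"]])
  expect_false(ps[["gB"]])
  expect_false(ps[["gflat"]])
  expect_error(pairwise_specific(list()), "no contrasts")

  # the Methods-style raw-p variant is available
  ps_p <- pairwise_specific(de_list, use = "pvalue")
  expect_true(ps_p[["gA"]])
})

test_that("domain enrichment is the union of the two callers, z boundary inclusive", {
  z <- matrix(c(2.0, -1,
                1.0, 2.5,
                2.4, 2.1,
                0.0, 0.0), 4, 2, byrow = TRUE,
              dimnames = list(c("boundary", "zhit", "both_domains", "pw_only"),
                              c("A", "B")))
  pw <- list(A = c(boundary = FALSE, zhit = FALSE, both_domains = FALSE,
                   pw_only = TRUE),
             B = c(boundary = FALSE, zhit = FALSE, both_domains = FALSE,
                   pw_only = FALSE))
  enr <- domain_enriched(z, pw)
  expect_true("boundary" %in% enr$A)        # z exactly 2 counts
  expect_false("boundary" %in% enr$B)
  expect_true(all(c("both_domains") %in% enr$A) &&
                "both_domains" %in% enr$B)  # multi-domain enrichment allowed
  expect_true("pw_only" %in% enr$A)         # pairwise caller alone suffices
  # union equals the two component calls computed independently
  for (d in c("A", "B")) {
    z_call <- rownames(z)[z[, d] >= 2]
    expect_setequal(enr[[d]], union(z_call, names(pw[[d]])[pw[[d]]]))
  }
})

test_that("restricted meristem comparison applies the two-contrast rule", {
  set.seed(23)
  n <- 120
  base <- rlnorm(n, log(400), 0.8)
  mk <- function(mult) sapply(base * mult, function(m) rpois(3, m))
  # planted: g1 8x in CLV3 vs both others; g2 8x vs WUS only; rest flat
  mult_clv3 <- rep(1, n); mult_clv3[1:5] <- 8; mult_clv3[6:10] <- 8
  mult_wus <- rep(1, n)
  mult_ufo <- rep(1, n); mult_ufo[6:10] <- 8  # g6..g10 equal in UFOp
  counts <- cbind(t(mk(mult_clv3)), t(mk(mult_wus)), t(mk(mult_ufo)))
  dimnames(counts) <- list(sprintf("g%03d", 1:n), paste0("s", 1:9))
  design <- data.frame(sample_id = paste0("s", 1:9),
                       domain_id = rep(c("CLV3", "WUS", "UFOp"), each = 3),
                       replicate = rep(1:3, 3))
  cm <- count_matrix(counts, setNames(rep(1000, n), rownames(counts)), design)
  sets <- sam_restricted_specific(cm, c("CLV3", "WUS", "UFOp"))
  expect_true(all(sprintf("g%03d", 1:5) %in% sets$CLV3))
  # genes up vs one domain only sit in the overlap, not the specific set
  expect_false(any(sprintf("g%03d", 6:10) %in% sets$CLV3))
  # brute-force check of the rule on the returned contrast tables
  de <- attr(sets, "contrasts")
  pass <- function(tab, d, o) {
    s <- if (tab$domain_a[1] == d) tab$log2fc else -tab$log2fc
    tab$gene_id[s >= 1 & tab$fdr <= 0.01]
  }
  brute <- intersect(pass(de$CLV3_vs_WUS, "CLV3"),
                     pass(de$CLV3_vs_UFOp, "CLV3"))
  expect_setequal(sets$CLV3, brute)

  # flat fixture: all sets empty
  counts_flat <- cbind(t(mk(rep(1, n))), t(mk(rep(1, n))), t(mk(rep(1, n))))
  dimnames(counts_flat) <- dimnames(counts)
  cm_flat <- count_matrix(counts_flat,
                          setNames(rep(1000, n), rownames(counts)), design)
  sets_flat <- sam_restricted_specific(cm_flat, c("CLV3", "WUS", "UFOp"))
  expect_equal(lengths(sets_flat), c(CLV3 = 0L, WUS = 0L, UFOp = 0L))
})
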