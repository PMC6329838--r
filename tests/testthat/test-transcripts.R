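test_that("longest ORF follows the codon-scan definition", {
  expect_equal(longest_orf("ATGAAATAG"), 9L)
  expect_equal(longest_orf("CCCCCCCCAACCTTT"), 0L)   # no ATG
  expect_equal(longest_orf("ATGAAACCC"), 0L)          # no stop: incomplete
  expect_equal(longest_orf("atgaaatag"), 9L)          # case-insensitive
  # random sequences against the quadratic oracle
  set.seed(51)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    expect_equal(longest_orf(s), orf_brute(s))
  }
  # appending ATG-free 3' UTR after the last stop cannot change the result
  s <- "ATGAAATAGCC"
  utr <- "CCTTCCTTCCAA"
  expect_equal(longest_orf(paste0(s, utr)), longest_orf(s))
})

test_that("spliced sequence concatenates exons and honors strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAATTTGGGCCC"))
  tm <- transcript_models(data.frame(
    transcript_id = c("plus", "plus", "minus"),
    chrom = "chr1", strand = c("+", "+", "-"),
    start = c(1, 7, 4), end = c(3, 9, 6)))
  expect_equal(spliced_sequence(tm, "plus", genome), "AAAGGG")
  expect_equal(spliced_sequence(tm, "minus", genome), "AAA")  # revcomp(TTT)
  expect_error(spliced_sequence(
    transcript_models(data.frame(transcript_id = "x", chrom = "chr9",
                                 strand = "+", start = 1, end = 3)),
    "x", genome), "chr9")
  expect_error(transcript_models(data.frame(
    transcript_id = c("bad", "bad"), chrom = "chr1", strand = "+",
    start = c(1, 3), end = c(5, 8))), "overlapping exons")
})

test_that("lncRNA classifier reproduces the fixture truth at every boundary", {
  fx <- lnc_fixture()
  v <- classify_lncrna(fx$assembled, fx$annotation, fx$genome)
  got <- v[match(fx$truth$transcript_id, v$transcript_id), ]
  expect_equal(got$class, fx$truth$class)
  expect_equal(got$reject_reason, fx$truth$reject_reason)
  # the boundary cases carry exactly the boundary measurements
  expect_equal(got$length[got$transcript_id == "t_short200"], 200)
  expect_equal(got$length[got$transcript_id == "t_len201"], 201)
  expect_equal(got$distance[got$transcript_id == "t_near499"], 499L)
  expect_equal(got$distance[got$transcript_id == "t_near500"], 500L)
  expect_equal(got$longest_orf[got$transcript_id == "t_novel_orf300"], 300L)
  expect_equal(got$longest_orf[got$transcript_id == "t_orf303"], 303L)
})

test_that("classifier verdicts are independent of transcript order", {
  fx <- lnc_fixture()
  set.seed(52)
  ord <- sample(unique(fx$assembled$transcript_id))
  shuffled <- do.call(rbind, lapply(ord, function(tx)
    fx$assembled[fx$assembled$transcript_id == tx, ]))
  v1 <- classify_lncrna(fx$assembled, fx$annotation, fx$genome)
  v2 <- classify_lncrna(transcript_models(shuffled), fx$annotation,
                        fx$genome)
  v2 <- v2[match(v1$transcript_id, v2$transcript_id), ]
  expect_equal(v1$class, v2$class)
  expect_equal(v1$reject_reason, v2$reject_reason)
})

test_that("GTF round trip preserves transcript structure", {
  fx <- lnc_fixture()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts_gtf(fx$annotation, path)
  back <- read_transcripts_gtf(path)
  expect_setequal(back$transcript_id, fx$annotation$transcript_id)
  for (tx in unique(fx$annotation$transcript_id)) {
    a <- fx$annotation[fx$annotation$transcript_id == tx, ]
    b <- back[back$transcript_id == tx, ]
    expect_equal(b$start, a$start)
    expect_equal(b$end, a$end)
    expect_equal(b$biotype, a$biotype)
  }
})

test_that("multi-isoform gene calls use the inclusive isoform cutoff", {
  dm <- rbind("gA.1" = c(5, 5, 5),
              "gA.2" = c(0.2, 0.2, 0.2),   # silent second isoform
              "gB.1" = c(1.0, 0.5, 0.5),   # max exactly 1: expressed (>=)
              "gB.2" = c(3, 1, 1),
              "gC.1" = c(4, 4, 4),
              "orphan" = c(9, 9, 9))
  colnames(dm) <- c("D1", "D2", "D3")
  em <- em_from_domain_means(dm)
  iso2gene <- c("gA.1" = "gA", "gA.2" = "gA", "gB.1" = "gB", "gB.2" = "gB",
                "gC.1" = "gC")
  expect_warning(mig <- multi_isoform_genes(em, iso2gene), "without gene")
  expect_setequal(mig, "gB")
  # enumeration over a larger random fixture
  set.seed(53)
  n <- 10
  ids <- as.vector(outer(paste0("x", 1:n), 1:2, paste, sep = "."))
  dm2 <- matrix(rlnorm(length(ids) * 3, log(1), 1), length(ids), 3,
                dimnames = list(ids, c("D1", "D2", "D3")))
  em2 <- em_from_domain_means(dm2)
  map2 <- setNames(sub("\\..$", "", ids), ids)
  mig2 <- multi_isoform_genes(em2, map2)
  brute <- names(which(table(map2[apply(dm2, 1, max) >= 1]) >= 2))
  expect_setequal(mig2, brute)
})

test_that("AS calls require isoform disagreement under the default rule", {
  doms <- paste0("D", 1:9)
  flat <- rep(10, 9)
  spike <- function(d, fc = 8) { v <- rep(10, 9); v[d] <- 10 * fc; v }
  # high in three domains with one dominating (intron-retention-like)
  ir_profile <- rep(10, 9); ir_profile[c(1, 2, 9)] <- c(300, 60, 40)
  dm <- rbind("same.1" = spike(1), "same.2" = spike(1),
              "dis.1" = spike(2), "dis.2" = flat,
              "ir.1" = ir_profile, "ir.2" = flat,
              "none.1" = flat, "none.2" = flat)
  colnames(dm) <- doms
  em <- em_from_domain_means(dm)
  map <- setNames(sub("\\..$", "", rownames(dm)), rownames(dm))
  called <- domain_specific_as(em, map)
  expect_false("same" %in% called)   # identical patterns: negative case
  expect_true("dis" %in% called)     # one enriched + one flat isoform
  expect_true("ir" %in% called)      # intron-retention-like multi-domain
  expect_false("none" %in% called)
  detail <- attr(called, "detail")
  ir_doms <- detail$enriched_domains[detail$isoform_id == "ir.1"]
  expect_true("D1" %in% strsplit(ir_doms, ",")[[1]])
  # the permissive rule also accepts agreeing enriched isoforms
  called_any <- domain_specific_as(em, map, rule = "any")
  expect_true(all(c("same", "dis", "ir") %in% called_any))
})

test_that("pseudogene profile reuses the expressed and z machinery", {
  expect_equal(pseudogene_profile(character(0),
                                  rpkm(tiny_cm()))$expressed, character(0))
  doms <- paste0("D", 1:9)
  dm <- rbind(ps_spec = c(rep(2, 8), 30),
              ps_flat = rep(5, 9),
              ps_silent = rep(0.1, 9),
              other = rep(7, 9))
  colnames(dm) <- doms
  em <- em_from_domain_means(dm)
  prof <- pseudogene_profile(c("ps_spec", "ps_flat", "ps_silent"), em)
  expect_setequal(prof$expressed, c("ps_spec", "ps_flat"))
  expect_equal(prof$enriched, "ps_spec")
  expect_true("ps_spec" %in% prof$per_domain$D9)
  expect_false("ps_flat" %in% unlist(prof$per_domain))
})
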