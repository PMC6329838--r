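#' Transcript models from an exon table
#'
#' @param exons data.frame with columns `transcript_id`, `chrom`, `strand`
#'   (+/-), `start`, `end` (1-based closed), and optionally `gene_id` and
#'   `biotype` (one of coding, lncRNA_known, transposon, pseudogene,
#'   assembled).
#' @return A `transcript_models` data.frame, exons sorted within transcript.
#' @export
transcript_models <- function(exons) {
  req <- c("transcript_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(exons)))
    stop("exon table needs columns ", paste(req, collapse = ", "))
  if (is.null(exons$gene_id)) exons$gene_id <- exons$transcript_id
  if (is.null(exons$biotype)) exons$biotype <- "assembled"
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be + or -")
  if (any(exons$end < exons$start)) stop("exon end < start")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, ]
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", tx)
    if (length(unique(e$chrom)) > 1L || length(unique(e$strand)) > 1L)
      stop("transcript ", tx, " spans chromosomes/strands")
  }
  rownames(exons) <- NULL
  class(exons) <- c("transcript_models", "data.frame")
  exons
}

#' Read transcript models from a GTF file
#'
#' Exon records are kept; `biotype` is taken from a `biotype` or
#' `gene_biotype`/`transcript_biotype` attribute when present, else
#' "assembled".
#'
#' @param path GTF file.
#' @return A [transcript_models()] data.frame.
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  bt <- gr$biotype
  if (is.null(bt)) bt <- gr$transcript_biotype
  if (is.null(bt)) bt <- gr$gene_biotype
  if (is.null(bt)) bt <- rep("assembled", length(gr))
  bt[is.na(bt)] <- "assembled"
  gid <- gr$gene_id
  if (is.null(gid)) gid <- gr$transcript_id
  transcript_models(data.frame(
    transcript_id = gr$transcript_id,
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    biotype = bt,
    stringsAsFactors = FALSE))
}

#' Write transcript models to GTF
#'
#' @param tm a [transcript_models()] data.frame.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_transcripts_gtf <- function(tm, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = tm$chrom,
    ranges = IRanges::IRanges(tm$start, tm$end),
    strand = tm$strand,
    type = "exon",
    source = "apexdomains",
    transcript_id = tm$transcript_id,
    gene_id = tm$gene_id,
    biotype = tm$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

tx_granges <- function(tm, biotypes = NULL) {
  if (!is.null(biotypes)) tm <- tm[tm$biotype %in% biotypes, , drop = FALSE]
  GenomicRanges::GRanges(tm$chrom, IRanges::IRanges(tm$start, tm$end),
                         strand = tm$strand, transcript_id = tm$transcript_id,
                         gene_id = tm$gene_id)
}

tx_span <- function(tm, ids = unique(tm$transcript_id)) {
  spans <- lapply(ids, function(tx) {
    e <- tm[tm$transcript_id == tx, ]
    GenomicRanges::GRanges(e$chrom[1], IRanges::IRanges(min(e$start), max(e$end)),
                           strand = e$strand[1])
  })
  gr <- do.call(c, spans)
  names(gr) <- ids
  gr
}

spliced_length <- function(tm, tx) {
  e <- tm[tm$transcript_id == tx, ]
  sum(e$end - e$start + 1)
}

intron_key <- function(e) {
  if (nrow(e) < 2L) return(character(0))
  paste(e$end[-nrow(e)] + 1L, e$start[-1] - 1L, sep = "-")
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences 5' to 3' (reverse-complemented for minus-
#' strand transcripts).
#'
#' @param tm a [transcript_models()] data.frame.
#' @param tx transcript id.
#' @param genome a `DNAStringSet` (e.g. from
#'   [Biostrings::readDNAStringSet()]) named by chromosome.
#' @return Character string of the sense-strand sequence.
#' @export
spliced_sequence <- function(tm, tx, genome) {
  e <- tm[tm$transcript_id == tx, ]
  if (!e$chrom[1] %in% names(genome))
    stop("chromosome ", e$chrom[1], " absent from the genome FASTA")
  chr <- genome[[e$chrom[1]]]
  parts <- vapply(seq_len(nrow(e)), function(i)
    as.character(Biostrings::subseq(chr, e$start[i], e$end[i])), character(1))
  s <- paste(parts, collapse = "")
  if (e$strand[1] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Longest sense-strand open reading frame
#'
#' Scans the three sense-strand frames for ATG..stop (TAA/TAG/TGA) and
#' returns the longest ORF length in nucleotides, counted from the A of the
#' start codon through the stop codon inclusive; 0 when no complete ORF
#' exists.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @return Integer ORF length in nt.
#' @export
longest_orf <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 6L) return(0L)
  best <- 0L
  for (f in 1:3) {
    starts <- seq(f, n - 2L, by = 3L)
    if (!length(starts)) next
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(atg) || !length(stp)) next
    # for each ATG, first stop at an index >= ATG index
    nxt <- stp[findInterval(atg - 1L, stp) + 1L]
    ok <- !is.na(nxt)
    if (any(ok))
      best <- max(best, max((nxt[ok] - atg[ok] + 1L) * 3L))
  }
  as.integer(best)
}

#' Classify assembled transcripts as lncRNA candidates
#'
#' Decision pipeline: (i) any exon overlap with an annotated coding gene
#' (any strand) rejects the transcript; (ii) transcripts matching a known
#' lncRNA exactly are `known`, those with identical internal splice
#' structure that extend the known model at the 5' and/or 3' end are
#' `known_extended`; (iii) the remainder are `novel` when spliced length
#' > `min_length`, the genomic gap to the nearest coding gene is
#' >= `min_distance`, no exon overlaps a transposon, and the longest
#' sense-strand ORF is <= `max_orf`; otherwise they are rejected with the
#' first failing criterion.
#'
#' @param assembled [transcript_models()] of assembled transcripts.
#' @param annotation [transcript_models()] carrying biotypes `coding`,
#'   `lncRNA_known` and `transposon`.
#' @param genome `DNAStringSet` named by chromosome.
#' @param min_length spliced-length cutoff, strict `>` (default 200 nt).
#' @param min_distance coding-gene gap cutoff, inclusive (default 500 bp).
#' @param max_orf ORF cutoff, inclusive (default 300 nt).
#' @return data.frame per transcript: `transcript_id`, `class` (known /
#'   known_extended / novel / rejected), `reject_reason` (overlaps_coding /
#'   too_short / near_coding / transposon_overlap / long_orf / none),
#'   `length`, `distance`, `longest_orf`.
#' @export
classify_lncrna <- function(assembled, annotation, genome,
                            min_length = 200, min_distance = 500,
                            max_orf = 300) {
  txs <- unique(assembled$transcript_id)
  miss <- setdiff(unique(assembled$chrom), names(genome))
  if (length(miss))
    stop("chromosome(s) absent from FASTA: ", paste(miss, collapse = ", "))
  coding_ex <- tx_granges(annotation, "coding")
  known_tm <- annotation[annotation$biotype == "lncRNA_known", , drop = FALSE]
  te_ex <- tx_granges(annotation, "transposon")
  coding_spans <- if (length(coding_ex))
    tx_span(annotation[annotation$biotype == "coding", , drop = FALSE])
  else GenomicRanges::GRanges()
  rows <- lapply(txs, function(tx) {
    e <- assembled[assembled$transcript_id == tx, ]
    ex_gr <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end))
    len <- sum(e$end - e$start + 1)
    span <- GenomicRanges::GRanges(e$chrom[1],
                                   IRanges::IRanges(min(e$start), max(e$end)))
    dist <- if (length(coding_spans)) {
      d <- GenomicRanges::distanceToNearest(span, coding_spans,
                                            ignore.strand = TRUE)
      if (length(d)) S4Vectors::mcols(d)$distance else NA_integer_
    } else NA_integer_
    orf <- longest_orf(spliced_sequence(assembled, tx, genome))
    verdict <- function(class, reason)
      data.frame(transcript_id = tx, class = class, reject_reason = reason,
                 length = len,
                 distance = ifelse(is.na(dist), NA_integer_, as.integer(dist)),
                 longest_orf = orf, stringsAsFactors = FALSE)
    if (length(coding_ex) &&
        length(GenomicRanges::findOverlaps(ex_gr, coding_ex,
                                           ignore.strand = TRUE)))
      return(verdict("rejected", "overlaps_coding"))
    # known-lncRNA comparison: identical introns, same or extended span
    for (kx in unique(known_tm$transcript_id)) {
      k <- known_tm[known_tm$transcript_id == kx, ]
      if (k$chrom[1] != e$chrom[1] || k$strand[1] != e$strand[1]) next
      if (!length(GenomicRanges::findOverlaps(
        ex_gr, GenomicRanges::GRanges(k$chrom, IRanges::IRanges(k$start, k$end)),
        ignore.strand = TRUE))) next
      if (!identical(intron_key(e), intron_key(k))) next
      same <- min(e$start) == min(k$start) && max(e$end) == max(k$end)
      covers <- min(e$start) <= min(k$start) && max(e$end) >= max(k$end)
      if (same) return(verdict("known", "none"))
      if (covers) return(verdict("known_extended", "none"))
    }
    if (len <= min_length) return(verdict("rejected", "too_short"))
    if (!is.na(dist) && dist < min_distance)
      return(verdict("rejected", "near_coding"))
    if (length(te_ex) &&
        length(GenomicRanges::findOverlaps(ex_gr, te_ex,
                                           ignore.strand = TRUE)))
      return(verdict("rejected", "transposon_overlap"))
    if (orf > max_orf) return(verdict("rejected", "long_orf"))
    verdict("novel", "none")
  })
  do.call(rbind, rows)
}

#' Genes with multiple expressed isoforms
#'
#' @param iso_em [expression_matrix()] at isoform level.
#' @param iso2gene named character vector mapping isoform id to gene id.
#' @param threshold expressed cutoff on the max domain-mean RPKM,
#'   inclusive (isoform-level convention RPKM >= 1).
#' @return Character vector of gene ids with >= 2 expressed isoforms, with
#'   attribute `expressed_isoforms` (named list gene -> isoform ids).
#' @export
multi_isoform_genes <- function(iso_em, iso2gene, threshold = 1.0) {
  stopifnot(inherits(iso_em, "expression_matrix"))
  isos <- rownames(iso_em$domain_means)
  unmapped <- isos[!isos %in% names(iso2gene)]
  if (length(unmapped)) {
    warning(length(unmapped), " isoform(s) without gene mapping excluded")
    isos <- setdiff(isos, unmapped)
  }
  expressed <- isos[apply(iso_em$domain_means[isos, , drop = FALSE], 1, max)
                    >= threshold]
  by_gene <- split(expressed, iso2gene[expressed])
  by_gene <- by_gene[lengths(by_gene) >= 2L]
  out <- names(by_gene)
  attr(out, "expressed_isoforms") <- by_gene
  out
}

#' Domain-specific alternative-splicing calls
#'
#' Among genes with >= 2 expressed isoforms, a gene is called when at least
#' one expressed isoform is enriched somewhere (z >= `z_threshold`) and, by
#' the default disagreement rule, the sets of enriched domains differ
#' between at least two of its expressed isoforms (isoforms sharing one
#' expression pattern are the negative case). `rule = "any"` relaxes this
#' to a single enriched isoform.
#'
#' @param iso_em [expression_matrix()] at isoform level.
#' @param iso2gene named character vector isoform -> gene.
#' @param z_threshold inclusive z cutoff (default 2).
#' @param expressed_threshold isoform expressed cutoff (default 1,
#'   inclusive).
#' @param rule `"disagree"` (default) or `"any"`.
#' @param z_on passed to [domain_zscores()].
#' @return Character vector of called gene ids with attribute `detail`: a
#'   data.frame of (gene_id, isoform_id, enriched_domains).
#' @export
domain_specific_as <- function(iso_em, iso2gene, z_threshold = 2.0,
                               expressed_threshold = 1.0,
                               rule = c("disagree", "any"),
                               z_on = c("samples", "domain_means")) {
  rule <- match.arg(rule)
  z_on <- match.arg(z_on)
  mig <- multi_isoform_genes(iso_em, iso2gene, expressed_threshold)
  z <- domain_zscores(iso_em, z_on = z_on)
  by_gene <- attr(mig, "expressed_isoforms")
  detail <- list(); called <- character(0)
  for (g in mig) {
    isos <- by_gene[[g]]
    dom_sets <- lapply(isos, function(i) {
      colnames(z)[z[i, ] >= z_threshold]
    })
    names(dom_sets) <- isos
    any_enriched <- any(lengths(dom_sets) > 0)
    disagree <- length(unique(lapply(dom_sets, sort))) > 1L
    hit <- any_enriched && (rule == "any" || disagree)
    if (hit) {
      called <- c(called, g)
      detail[[g]] <- data.frame(
        gene_id = g, isoform_id = isos,
        enriched_domains = vapply(dom_sets, paste, character(1),
                                  collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  attr(called, "detail") <- if (length(detail)) do.call(rbind, detail)
    else data.frame(gene_id = character(), isoform_id = character(),
                    enriched_domains = character())
  called
}

#' Pseudogene expression and specificity profile
#'
#' Restricts the expressed-gene and z-score machinery to an annotated
#' pseudogene list: reports pseudogenes expressed in at least one domain
#' and the subset with a domain-enriched (z >= `z_threshold`) pattern.
#'
#' @param pseudogene_ids character vector of pseudogene ids.
#' @param em an [expression_matrix()] containing them (ids absent from the
#'   matrix are ignored).
#' @param threshold expressed cutoff (strict >, default 1).
#' @param z_threshold inclusive z cutoff (default 2).
#' @param z_on passed to [domain_zscores()].
#' @return List with `expressed` (ids), `enriched` (ids), and
#'   `per_domain` (named list of enriched ids per domain).
#' @export
pseudogene_profile <- function(pseudogene_ids, em, threshold = 1.0,
                               z_threshold = 2.0,
                               z_on = c("samples", "domain_means")) {
  z_on <- match.arg(z_on)
  ids <- intersect(pseudogene_ids, rownames(em$domain_means))
  if (!length(ids))
    return(list(expressed = character(0), enriched = character(0),
                per_domain = list()))
  dm <- em$domain_means[ids, , drop = FALSE]
  expressed <- ids[apply(dm, 1, max) > threshold]
  z <- domain_zscores(em, z_on = z_on)[ids, , drop = FALSE]
  per_domain <- lapply(colnames(z), function(d)
    intersect(expressed, rownames(z)[z[, d] >= z_threshold]))
  names(per_domain) <- colnames(z)
  list(expressed = expressed,
       enriched = sort(unique(unlist(per_domain))),
       per_domain = per_domain)
}
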