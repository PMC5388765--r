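# Promoter extraction, IUPAC motif scanning, presence annotation and
# hypergeometric module enrichment.

test_that("promoters are cut upstream with strand awareness and truncation", {
  chrom <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  genes <- data.frame(
    id = c("plus", "minus", "edge"), chrom = "chr1",
    start = c(1000, 1000, 50), end = c(2000, 2000, 300),
    strand = c("+", "-", "+"), kind = "gene")
  expect_warning(p <- extract_promoters(genes, genome, length = 200),
                 "truncated")
  # + strand: the 200 bp ending at the gene start
  expect_equal(as.character(p[["plus"]]), substr(chrom, 801, 1000))
  # - strand: reverse complement of the 200 bp after the gene end
  expect_equal(as.character(p[["minus"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chrom, 2001, 2200)))))
  # chromosome edge: truncated to the available 50 bp
  expect_equal(as.character(p[["edge"]]), substr(chrom, 1, 50))

  bad <- genes
  bad$chrom <- "chrMissing"
  expect_error(extract_promoters(bad, genome, 200), "absent from")
})

test_that("CCWACC matches exactly its two W-resolutions", {
  p <- Biostrings::DNAStringSet(c(a = "TTCCAACCTT", t = "TTCCTACCTT",
                                  g = "TTCCGACCTT"))
  hits <- scan_motif(p, "CCWACC")
  fwd <- hits[hits$strand == "+", ]
  expect_setequal(fwd$gene_id, c("a", "t"))
  expect_equal(unique(fwd$position), 2L)
  expect_error(scan_motif(p, "CCJACC"), "invalid character")
})

test_that("both strands are scanned and overlapping matches all reported", {
  # reverse complement of CCWACC is GGTWGG
  p <- Biostrings::DNAStringSet(c(g1 = "AAGGTAGGAA"))
  hits <- scan_motif(p, "CCWACC")
  expect_equal(hits$strand, "-")
  expect_equal(hits$position, 2L)
  # overlapping AA-run matches of a degenerate motif
  p2 <- Biostrings::DNAStringSet(c(g2 = "AAAAAA"))
  h2 <- scan_motif(p2, "AAAA")
  expect_equal(sum(h2$strand == "+"), 3)
})

test_that("scanning matches the brute-force IUPAC oracle on both strands", {
  set.seed(21)
  motifs <- c("CCWACC", "TTGACY", "CANNTG", "RRYNGG")
  for (i in 1:6) {
    seqs <- setNames(vapply(1:4, function(j) {
      paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    }, character(1)), paste0("g", 1:4))
    p <- Biostrings::DNAStringSet(seqs)
    for (motif in motifs) {
      hits <- scan_motif(p, motif)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
      for (g in names(seqs)) {
        expect_equal(hits$position[hits$gene_id == g & hits$strand == "+"],
                     oracle_iupac_starts(seqs[[g]], motif))
        expect_equal(hits$position[hits$gene_id == g & hits$strand == "-"],
                     oracle_iupac_starts(seqs[[g]], rc))
      }
    }
  }
})

test_that("strand consistency: revcomp promoter = revcomp motif, mapped", {
  set.seed(22)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  p <- Biostrings::DNAStringSet(c(g = seq))
  prc <- Biostrings::reverseComplement(p)
  names(prc) <- "g"
  motif <- "CCWACC"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  a <- scan_motif(p, motif)
  b <- scan_motif(prc, rc)
  L <- nchar(motif)
  n <- nchar(seq)
  # + hits on the original equal mapped - hits on the reverse complement
  expect_setequal(a$position[a$strand == "+"],
                  n - L - b$position[b$strand == "-"])
  expect_setequal(a$position[a$strand == "-"],
                  n - L - b$position[b$strand == "+"])
})

test_that("presence annotation is boolean over the scanned universe", {
  p <- Biostrings::DNAStringSet(c(hit = "AACCAACCAACCAACC", none = "AAAAAAAAAAAAAAAA"))
  hits <- scan_motif(p, "CCWACC")
  pres <- annotate_presence(hits, names(p))
  expect_true(pres["hit", "CCWACC"])
  expect_false(pres["none", "CCWACC"])
  expect_equal(dim(annotate_presence(hits[0, ], character(0))), c(0L, 0L))
})

test_that("hypergeometric enrichment matches the closed form", {
  # module of 5, all carriers, 5 carriers among 100 genes:
  # p = C(5,5) C(95,0) / C(100,5)
  universe <- sprintf("g%03d", 1:100)
  pres <- matrix(FALSE, 100, 1, dimnames = list(universe, "M"))
  pres[1:5, "M"] <- TRUE
  res <- enrich_modules(pres, list(mod = universe[1:5]))
  expect_equal(res$p_value, choose(5, 5) * choose(95, 0) / choose(100, 5),
               tolerance = 1e-12)
  expect_equal(res$k, 5)

  # k = 0 -> P(X >= 0) = 1
  res0 <- enrich_modules(pres, list(mod = universe[6:10]))
  expect_equal(res0$p_value, 1)
  # module = background -> P(X >= K) = 1
  resall <- enrich_modules(pres, list(mod = universe))
  expect_equal(resall$p_value, 1)
})

test_that("BH adjustment preserves the p-value ordering", {
  set.seed(23)
  universe <- sprintf("g%03d", 1:60)
  pres <- matrix(runif(60 * 4) < 0.3, 60, 4,
                 dimnames = list(universe, paste0("m", 1:4)))
  mods <- list(a = universe[1:10], b = universe[11:30], c = universe[31:60])
  res <- enrich_modules(pres, mods)
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  expect_true(all(res$fdr <= 1))
  # sorted by p-value; fdr monotone non-decreasing along that order
  expect_true(!is.unsorted(res$p_value))
  expect_true(!is.unsorted(res$fdr))
  expect_equal(res$fdr, p.adjust(res$p_value, "BH"))
})

test_that("module genes without promoters are excluded with a warning", {
  universe <- sprintf("g%02d", 1:20)
  pres <- matrix(TRUE, 20, 1, dimnames = list(universe, "M"))
  expect_warning(
    res <- enrich_modules(pres, list(mod = c(universe[1:5], "ghost"))),
    "without a scanned promoter")
  expect_equal(res$n, 5)
})

test_that("the planted motif attains the smallest FDR across seeds", {
  motifs <- default_motifs()
  wins <- 0L
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    mod_ids <- sprintf("mod%02d", 1:15)
    bg_ids <- sprintf("bg%02d", 1:45)
    pm <- simulate_promoters(mod_ids, "CCWACC", planted_fraction = 0.8,
                             promoter_length = 300, seed = seed)
    pb <- simulate_promoters(bg_ids, "CCWACC", planted_fraction = 0.1,
                             promoter_length = 300, seed = seed + 1000)
    promoters <- c(pm, pb)
    hits <- scan_motifs(promoters, motifs)
    pres <- annotate_presence(hits, names(promoters))
    res <- enrich_modules(pres, list(module = mod_ids))
    best <- res$motif_name[which.min(res$fdr)]
    if (best == "MYB_CCWACC") wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.95)
})
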