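# Synthetic-data generators: planted structure, documented rounding rules,
# reproducibility, and round-tripping through the package's own readers.

test_that("planted expression modules realise the requested correlations", {
  # identical noiseless profiles -> r = 1; exact negation -> r = -1
  d <- simulation_design(
    modules = list(planted_module(c("a", "b", "c"), "ripening_up",
                                  sign = c(1, 1, -1))),
    n_background = 0, noise_sd = 0, seed = 1)
  m <- simulate_expression(d)
  r <- compute_pcc_matrix(m)
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), -1)

  # 5 cultivars x 4 stages x 1 replicate -> 20 sample columns
  expect_equal(ncol(m), 20)
  expect_true(all(m >= 0))
  expect_match(colnames(m)[1], "^cultivar1_stage1_rep1$")
})

test_that("within_module_r calibrates the expected pairwise correlation", {
  d <- simulation_design(
    replicates_per_cell = 40,
    modules = list(planted_module(sprintf("g%02d", 1:6), "ripening_up",
                                  within_module_r = 0.7)),
    n_background = 0, noise_sd = 0, seed = 42)
  r <- compute_pcc_matrix(simulate_expression(d))
  off <- r[upper.tri(r)]
  expect_true(abs(mean(off) - 0.7) < 0.05)
})

test_that("overlapping module gene ids are rejected naming the duplicate", {
  expect_error(
    simulation_design(modules = list(planted_module(c("a", "b")),
                                     planted_module(c("b", "c")))),
    "more than one module.*b")
})

test_that("identical seeds give byte-identical expression tables", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(simulate_expression(default_design(seed = 9)), f1)
  write_expression(simulate_expression(default_design(seed = 9)), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the emitted table round-trips through the package's own reader
  m <- simulate_expression(default_design(seed = 9))
  m2 <- load_expression(f1)
  expect_equal(unclass(m2), unclass(m)[rownames(m2), ],
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("simulated genome realises the tandem cluster and antisense pair", {
  gen <- simulate_genome(genome_spec(), seed = 2)
  feats <- gen$features
  lnc <- feats[feats$id == "lnc_sts", ]
  genes <- feats[feats$kind == "gene", ]
  sts <- genes[grepl("^sts", genes$id), ]

  # hand interval arithmetic: every cluster gene within the 100 kb window
  expect_equal(nrow(sts), 9)
  expect_true(all(sts$start < lnc$end + 100000 & sts$end > lnc$start - 100000))
  # consecutive, same strand, gaps below the window
  ord <- sts[order(sts$start), ]
  gaps <- ord$start[-1] - ord$end[-nrow(ord)]
  expect_true(all(gaps > 0 & gaps < 100000))
  expect_length(unique(ord$strand), 1)

  # antisense pair: overlapping intervals, opposite strands
  asl <- feats[feats$id == "lnc_as", ]
  g <- feats[feats$id == "ggt01", ]
  expect_true(asl$start < g$end && asl$end > g$start)
  expect_true(asl$strand != g$strand)

  # sequences match the declared chromosome lengths
  expect_equal(unname(Biostrings::width(gen$genome)),
               unname(genome_spec()$chromosomes)[
                 match(names(gen$genome), names(genome_spec()$chromosomes))])
})

test_that("genome emissions parse back with the package's own reader", {
  dir <- withr::local_tempdir()
  gen <- simulate_genome(genome_spec(), seed = 3, dir = dir)
  reread <- parse_features(gen$gff_path)
  orig <- gen$features[order(gen$features$id), ]
  back <- reread[order(reread$id), ]
  rownames(orig) <- rownames(back) <- NULL
  expect_equal(back[, c("id", "chrom", "start", "end", "strand", "kind")],
               orig[, c("id", "chrom", "start", "end", "strand", "kind")])
})

test_that("degenerate and invalid genome layouts are handled", {
  empty <- genome_spec(tandem_cluster = NULL, antisense_pair = NULL)
  dir <- withr::local_tempdir()
  gen <- simulate_genome(empty, seed = 1, dir = dir)
  expect_equal(nrow(gen$features), 0)
  expect_equal(readLines(gen$gff_path)[1], "##gff-version 3")

  too_big <- genome_spec(chromosomes = c(chr01 = 250000, chr03 = 50000,
                                         chr10 = 60000))
  expect_error(simulate_genome(too_big, seed = 1), "exceeds chromosome")
})

test_that("promoter planting hits the documented round-half-up count", {
  p <- simulate_promoters(sprintf("g%d", 1:10), "CCWACC",
                          planted_fraction = 1, promoter_length = 300,
                          seed = 1)
  hits <- scan_motif(p, "CCWACC")
  expect_setequal(unique(hits$gene_id), sprintf("g%d", 1:10))

  p0 <- simulate_promoters(sprintf("g%d", 1:10), "CCWACC",
                           planted_fraction = 0, promoter_length = 300,
                           seed = 1)
  expect_equal(nrow(scan_motif(p0, "CCWACC")), 0)

  # n = 7, fraction = 0.5 -> 4 planted (round half up)
  p7 <- simulate_promoters(sprintf("g%d", 1:7), "CCWACC",
                           planted_fraction = 0.5, promoter_length = 300,
                           seed = 2)
  carriers <- unique(scan_motif(p7, "CCWACC")$gene_id)
  expect_length(carriers, 4)
  expect_setequal(carriers, names(which(attr(p7, "planted"))))

  expect_error(simulate_promoters("g1", "CCWACC", 1, promoter_length = 4),
               "longer than")
})

test_that("miRNA pair generator reproduces its own truth expectations", {
  set.seed(77)
  tx <- setNames(paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                       collapse = ""), "tx1")
  perfect <- simulate_mirna_pairs(tx, 1, mismatches = 0, wobbles = 0,
                                  seed = 1)
  expect_equal(perfect$truth$expectation, 0)
  # the emitted miRNA really is the reverse complement of the window
  ws <- perfect$truth$window_start
  window <- substr(tx, ws + 1, ws + 21)
  expect_equal(chartr("U", "T", as.character(perfect$mirnas[[1]])),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(window))))

  # hand application of the penalty rules to the recorded positions
  for (s in list(list(mm = 1, wo = 0), list(mm = 0, wo = 1),
                 list(mm = 2, wo = 2))) {
    pair <- simulate_mirna_pairs(tx, 1, mismatches = s$mm, wobbles = s$wo,
                                 seed = 3)
    tr <- pair$truth
    pos_of <- function(x) if (nzchar(x)) as.integer(strsplit(x, ",")[[1]]) else integer(0)
    core_mult <- function(p) ifelse(p >= 2 & p <= 13, 2, 1)
    expected <- sum(1 * core_mult(pos_of(tr$mismatch_pos))) +
      sum(0.5 * core_mult(pos_of(tr$wobble_pos)))
    expect_equal(tr$expectation, expected)
    # and the scorer agrees with the generator's bookkeeping
    ws <- tr$window_start
    window <- substr(tx, ws + 1, ws + 21)
    sc <- score_duplex(as.character(pair$mirnas[[1]]), window)
    expect_equal(sc$expectation, tr$expectation)
  }
})

test_that("transcripts shorter than the miRNA are skipped with a warning", {
  tx <- c(short = "ACGAUG", long = paste(rep("ACGT", 20), collapse = ""))
  expect_warning(res <- simulate_mirna_pairs(tx, 1, seed = 1),
                 "shorter than")
  expect_equal(res$truth$transcript_id, "long")
  expect_error(
    suppressWarnings(simulate_mirna_pairs(c(s = "ACG"), 1, seed = 1)),
    "no transcript")
})
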