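# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths (and cor()) where
# the point is to verify them.

# Textbook Pearson correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  if (den == 0) return(NA_real_)
  num / den
}

# Edge set by double loop over all unordered gene pairs of a raw abundance
# matrix, thresholding |r| strictly on log2(x + 1) values.
oracle_edges <- function(m, threshold = 0.8) {
  x <- log2(m + 1)
  ids <- rownames(m)
  out <- list()
  for (i in seq_len(nrow(x) - 1)) {
    for (j in (i + 1):nrow(x)) {
      r <- oracle_pearson(x[i, ], x[j, ])
      if (!is.na(r) && abs(r) > threshold) {
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        out[[length(out) + 1]] <- data.frame(
          gene_a = a, gene_b = b, r = r,
          sign = if (r > 0) "positive" else "negative",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0), sign = character(0)))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive all-pairs interval check: genes whose [start, end) intersects
# the lncRNA interval widened by w on both sides (half-open arithmetic).
oracle_colocated <- function(lnc, genes, w) {
  hits <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != lnc$chrom || g$id == lnc$id) next
    lo <- max(lnc$start - w, g$start)
    hi <- min(lnc$end + w, g$end)
    if (lo < hi) hits <- c(hits, g$id)
  }
  sort(hits)
}

# Position-by-position IUPAC matcher (single strand, 0-based starts).
oracle_iupac_starts <- function(seq, motif) {
  code <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
            S = "GC", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
            H = "ACT", V = "ACG", N = "ACGT")
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  L <- length(m)
  starts <- integer(0)
  for (p in seq_len(length(s) - L + 1)) {
    ok <- TRUE
    for (i in seq_len(L)) {
      allowed <- strsplit(code[[m[i]]], "")[[1]]
      if (!s[p + i - 1] %in% allowed) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, p - 1L)
  }
  starts
}

# Rescore one duplex window from first principles (antiparallel ungapped
# pairing with G:U wobble and core-region doubling).
oracle_duplex_score <- function(mirna, window, scheme = scoring_scheme()) {
  norm <- function(x) chartr("Uu", "Tt", toupper(x))
  mi <- strsplit(norm(mirna), "")[[1]]
  tg <- rev(strsplit(norm(window), "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  total <- 0
  for (i in seq_along(mi)) {
    pen <- if (comp[[mi[i]]] == tg[i]) {
      0
    } else if ((mi[i] == "G" && tg[i] == "T") ||
               (mi[i] == "T" && tg[i] == "G")) {
      scheme$wobble_penalty
    } else {
      scheme$mismatch_penalty
    }
    if (i >= scheme$core_start && i <= scheme$core_end) {
      pen <- pen * scheme$core_multiplier
    }
    total <- total + pen
  }
  total
}

# One shared end-to-end study fixture per test run (generation + pipeline
# are deterministic, so caching only saves time).
.study_cache <- new.env(parent = emptyenv())
cached_study <- function() {
  if (is.null(.study_cache$res)) {
    dir <- file.path(tempdir(), "phenolnet-study-fixture")
    .study_cache$st <- simulate_study(dir, seed = 11)
    .study_cache$res <- run_pipeline(.study_cache$st$config)
  }
  list(st = .study_cache$st, res = .study_cache$res)
}

# Random feature table spread over a couple of chromosomes.
random_features <- function(n, seed, chroms = c("chrA", "chrB"),
                            span = 5e5) {
  set.seed(seed)
  start <- sample.int(span, n)
  len <- sample(500:20000, n, replace = TRUE)
  data.frame(id = sprintf("f%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             kind = "gene", stringsAsFactors = FALSE)
}
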