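# Signed gene co-expression network (GCN) construction by Pearson
# correlation thresholding on a genes-by-samples abundance matrix.

#' Network construction parameters
#'
#' @param pcc_threshold Absolute Pearson correlation cutoff in `(0, 1]`;
#'   an edge requires `|r|` strictly greater than this (default 0.8).
#' @param min_variance Genes whose per-gene variance (after transform) is
#'   at or below this are excluded from edges (default 0).
#' @param transform `"log2"` (correlate `log2(x + 1)`, the default for
#'   RNA-Seq-like abundances) or `"raw"`.
#' @return A `network_config` list.
#' @export
network_config <- function(pcc_threshold = 0.8, min_variance = 0,
                           transform = c("log2", "raw")) {
  if (!.is_scalar_num(pcc_threshold) ||
      pcc_threshold <= 0 || pcc_threshold > 1) {
    .stopf("pcc_threshold must be in (0, 1]")
  }
  stopifnot(min_variance >= 0)
  structure(list(pcc_threshold = pcc_threshold,
                 min_variance = min_variance,
                 transform = match.arg(transform)),
            class = "network_config")
}

#' Parse sample design labels of the form cultivarX_stageY_repZ
#'
#' @param sample_ids Character vector of sample column names.
#' @return Data frame with columns sample_id, cultivar, stage, rep, or
#'   `NULL` if the labels do not follow the convention.
#' @export
parse_sample_design <- function(sample_ids) {
  pat <- "^cultivar([0-9]+)_stage([0-9]+)_rep([0-9]+)$"
  if (!all(grepl(pat, sample_ids))) return(NULL)
  data.frame(
    sample_id = sample_ids,
    cultivar = as.integer(sub(pat, "\\1", sample_ids)),
    stage = as.integer(sub(pat, "\\2", sample_ids)),
    rep = as.integer(sub(pat, "\\3", sample_ids)),
    stringsAsFactors = FALSE)
}

#' Load a genes-by-samples expression table
#'
#' Reads a TSV/CSV with a header row and gene identifiers in the first
#' column, validates it (no duplicate gene ids, all cells numeric, at
#' least 3 finite values per gene) and attaches the sample design parsed
#' from the column names when they follow `cultivarX_stageY_repZ`.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"csv"`; `"auto"` guesses from the
#'   file extension.
#' @return Numeric matrix, genes in rows, with a `design` attribute when
#'   the sample labels are parseable.
#' @export
load_expression <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stopf("expression table needs gene ids plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    .stopf("duplicate gene id in %s: %s", path, ids[duplicated(ids)][1])
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad)) {
        .stopf("non-numeric value at row %d (gene %s), column '%s'",
               bad[1], ids[bad[1]], names(vals)[j])
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  low <- rowSums(is.finite(m)) < 3
  if (any(low)) {
    .stopf("gene %s has fewer than 3 finite values", ids[low][1])
  }
  attr(m, "design") <- parse_sample_design(colnames(m))
  m
}

#' Restrict an expression matrix to developmentally dynamic genes
#'
#' The network is intended to be built on genes that change over the
#' developmental series.  Three selection rules are supported:
#' \describe{
#'   \item{`list(type = "genes", ids = ...)`}{Explicit gene list (the
#'     default style of use, e.g. a curated pathway set).}
#'   \item{`list(type = "fold_change", min_fold = f)`}{Keep genes whose
#'     max/min stage-mean ratio (on `x + 1` pseudocounted abundances) is at
#'     least `f`; requires parseable sample design labels.}
#'   \item{`list(type = "cv", min_cv = c)`}{Keep genes with coefficient of
#'     variation across samples at least `c`.}
#' }
#'
#' @param m Genes-by-samples matrix.
#' @param rule A list as above.
#' @return The filtered submatrix; the applied rule is recorded in
#'   attribute `filter_rule`.  An empty result gives a warning, not an
#'   error.
#' @export
filter_dynamic_genes <- function(m, rule) {
  stopifnot(is.list(rule), !is.null(rule$type))
  keep <- switch(rule$type,
    genes = {
      missing <- setdiff(rule$ids, rownames(m))
      if (length(missing)) {
        .warnf("%d listed gene(s) absent from the matrix (e.g. %s)",
               length(missing), missing[1])
      }
      rownames(m) %in% rule$ids
    },
    fold_change = {
      design <- attr(m, "design") %||% parse_sample_design(colnames(m))
      if (is.null(design)) {
        .stopf("fold_change rule needs cultivarX_stageY_repZ sample labels")
      }
      stage_means <- t(apply(m + 1, 1, function(x) {
        tapply(x, design$stage, mean)
      }))
      apply(stage_means, 1, max) / apply(stage_means, 1, min) >=
        rule$min_fold
    },
    cv = {
      mu <- rowMeans(m)
      sds <- apply(m, 1, stats::sd)
      ifelse(mu > 0, sds / mu, 0) >= rule$min_cv
    },
    .stopf("unknown filter rule type: %s", rule$type)
  )
  if (!any(keep)) .warnf("filter removed every gene")
  out <- m[keep, , drop = FALSE]
  attr(out, "design") <- attr(m, "design")
  attr(out, "filter_rule") <- rule
  out
}

#' Pearson correlation matrix over genes
#'
#' Correlates every unordered gene pair across samples, by default on
#' `log2(x + 1)`-transformed abundances.  Missing values are handled
#' pairwise-complete; pairs sharing fewer than 3 finite samples get `NA`
#' (and therefore never form an edge).  Zero-variance genes are flagged in
#' attribute `zero_variance` and their correlations set to `NA`.
#'
#' @param m Genes-by-samples matrix (>= 3 samples).
#' @param config A [network_config()]; governs the transform.
#' @return Symmetric genes-by-genes correlation matrix with unit diagonal
#'   for included genes.
#' @export
compute_pcc_matrix <- function(m, config = network_config()) {
  if (ncol(m) < 3) .stopf("need at least 3 samples to correlate")
  x <- if (config$transform == "log2") log2(m + 1) else m
  xt <- t(x)
  r <- suppressWarnings(cor(xt, use = "pairwise.complete.obs",
                            method = "pearson"))
  if (anyNA(x)) {
    shared <- crossprod(!is.na(xt))
    r[shared < 3] <- NA
  }
  v <- apply(x, 1, function(row) stats::var(row, na.rm = TRUE))
  zero <- !is.na(v) & v <= config$min_variance | v == 0
  zero[is.na(zero)] <- TRUE
  if (any(zero)) {
    r[zero, ] <- NA
    r[, zero] <- NA
  }
  diag(r)[!zero] <- 1
  attr(r, "zero_variance") <- rownames(m)[zero]
  r
}

#' Threshold a correlation matrix into a signed edge list
#'
#' An edge joins an unordered gene pair iff `|r|` is strictly greater than
#' the cutoff; the edge keeps `r` and its sign.  Self-pairs and `NA`
#' correlations never form edges.
#'
#' @param corr Symmetric correlation matrix (row/col names = gene ids).
#' @param config A [network_config()]; `pcc_threshold` is the cutoff.
#' @return Data frame with columns gene_a, gene_b, r, sign
#'   (`"positive"`/`"negative"`), each unordered pair once
#'   (`gene_a < gene_b` lexicographically), ordered by (gene_a, gene_b).
#' @export
build_network <- function(corr, config = network_config()) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  th <- config$pcc_threshold
  ids <- rownames(corr)
  keep <- !is.na(corr) & abs(corr) > th & upper.tri(corr)
  idx <- which(keep, arr.ind = TRUE)
  a <- ids[idx[, 1]]
  b <- ids[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  r <- corr[idx]
  out <- data.frame(gene_a = a, gene_b = b, r = r,
                    sign = c("negative", "positive")[(r > 0) + 1L],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a co-expression edge table
#'
#' @param edges Edge data frame from [build_network()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
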