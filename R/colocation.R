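# lncRNA-gene candidate regulation from genomic proximity plus
# co-expression, and antisense/intergenic lncRNA classification.
#
# All internal coordinates are 0-based half-open; GFF3 (1-based inclusive)
# and BED (0-based half-open) inputs are converted on parsing.

#' Co-location parameters
#'
#' @param window_bp Nonnegative flanking window in bp around the lncRNA
#'   interval (default 100000, i.e. within 100 kb of the lncRNA position).
#' @param pcc_threshold Absolute co-expression cutoff for retained
#'   lncRNA-gene pairs (default 0.8).
#' @return A `colocation_config` list.
#' @export
colocation_config <- function(window_bp = 100000L, pcc_threshold = 0.8) {
  stopifnot(.is_count(window_bp, min = 0))
  if (!.is_scalar_num(pcc_threshold) ||
      pcc_threshold <= 0 || pcc_threshold > 1) {
    .stopf("pcc_threshold must be in (0, 1]")
  }
  structure(list(window_bp = as.integer(window_bp),
                 pcc_threshold = pcc_threshold),
            class = "colocation_config")
}

#' Parse genomic features from GFF3 or BED into the internal convention
#'
#' GFF3 records (1-based inclusive) and BED records (0-based half-open)
#' are unified to 0-based half-open intervals.  Feature kind is `"lncRNA"`
#' for GFF3 types `lnc_RNA`/`lncRNA`/`ncRNA` or `biotype=lncRNA`
#' attributes, and for BED names containing `"lnc"` (case-insensitive);
#' everything of type `gene` (or any other BED line) is `"gene"`.  GFF3
#' records other than gene/lncRNA (exons, mRNAs, ...) are dropped.
#'
#' @param path GFF3 or BED file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return Data frame: id, chrom, start, end, strand (`+`/`-`/`.`), kind.
#' @export
parse_features <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) {
      "bed"
    } else {
      "gff3"
    }
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3")
  mc <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    type <- as.character(mc$type)
    biotype <- if ("biotype" %in% names(mc)) as.character(mc$biotype) else NA
    is_lnc <- type %in% c("lnc_RNA", "lncRNA", "ncRNA") |
      (!is.na(biotype) & biotype == "lncRNA")
    keep <- is_lnc | type == "gene"
    gr <- gr[keep]
    mc <- S4Vectors::mcols(gr)
    kind <- ifelse(is_lnc[keep], "lncRNA", "gene")
    id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
    if (anyNA(id) && "Name" %in% names(mc)) {
      id[is.na(id)] <- as.character(mc$Name)[is.na(id)]
    }
    if (anyNA(id)) .stopf("GFF3 record without ID or Name attribute")
  } else {
    id <- if ("name" %in% names(mc)) as.character(mc$name) else NA_character_
    if (anyNA(id)) .stopf("BED record without a name field")
    kind <- ifelse(grepl("lnc", id, ignore.case = TRUE), "lncRNA", "gene")
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  out <- data.frame(
    id = id, chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr),
    strand = strand, kind = kind, stringsAsFactors = FALSE)
  bad <- out$end <= out$start
  if (any(bad)) .stopf("record %s has end <= start", out$id[bad][1])
  attr(out, "source_format") <- format
  out
}

.check_feature_df <- function(features) {
  need <- c("id", "chrom", "start", "end", "strand")
  missing <- setdiff(need, names(features))
  if (length(missing)) {
    .stopf("feature table lacks column(s): %s",
           paste(missing, collapse = ", "))
  }
  bad <- !features$strand %in% c("+", "-", ".")
  if (any(bad)) {
    .stopf("feature %s has unknown strand '%s'",
           features$id[bad][1], features$strand[bad][1])
  }
  invisible(features)
}

# gap between two 0-based half-open intervals; 0 on overlap
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2))
}

#' Genes co-located with a lncRNA
#'
#' A gene is co-located when it lies on the same chromosome and its
#' interval intersects the lncRNA interval extended by `window_bp` on both
#' sides (half-open arithmetic, so a gene whose gap from the lncRNA is
#' exactly `window_bp` is excluded).  Strand is ignored for proximity.
#'
#' @param lncrna Single-row feature (data frame row or list) for the lncRNA.
#' @param genes Feature data frame of candidate genes.
#' @param config A [colocation_config()].
#' @return Data frame: gene_id, distance_bp (0 on overlap, else gap),
#'   ordered by (distance_bp, gene_id).  May be empty.
#' @export
colocated_genes <- function(lncrna, genes, config = colocation_config()) {
  .check_feature_df(genes)
  w <- config$window_bp
  ls <- lncrna$start - w
  le <- lncrna$end + w
  hit <- genes$chrom == lncrna$chrom &
    genes$start < le & genes$end > ls &
    genes$id != lncrna$id
  g <- genes[hit, , drop = FALSE]
  d <- .interval_gap(lncrna$start, lncrna$end, g$start, g$end)
  out <- data.frame(gene_id = g$id, distance_bp = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance_bp, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a lncRNA as antisense, intergenic or sense-overlapping
#'
#' Antisense: the lncRNA overlaps at least one gene on the opposite
#' strand.  Intergenic: it overlaps no gene.  A lncRNA overlapping only
#' same-strand genes is labelled `"sense_overlapping"` (an extension
#' beyond the antisense/intergenic dichotomy).  A strand-`"."` lncRNA
#' that overlaps a gene cannot be assigned an orientation and is labelled
#' `"overlapping_unstranded"`.
#'
#' @param lncrna Single-row feature for the lncRNA.
#' @param genes Feature data frame of genes.
#' @return One of `"antisense"`, `"intergenic"`, `"sense_overlapping"`,
#'   `"overlapping_unstranded"`.
#' @export
classify_lncrna <- function(lncrna, genes) {
  .check_feature_df(genes)
  ov <- genes$chrom == lncrna$chrom &
    genes$start < lncrna$end & genes$end > lncrna$start &
    genes$id != lncrna$id
  if (!any(ov)) return("intergenic")
  if (lncrna$strand == ".") return("overlapping_unstranded")
  strands <- genes$strand[ov]
  opposite <- strands %in% c("+", "-") & strands != lncrna$strand
  if (any(opposite)) "antisense" else "sense_overlapping"
}

#' Build lncRNA-gene edges from co-location plus co-expression
#'
#' For every lncRNA in the feature table, finds its co-located genes
#' ([colocated_genes()]), keeps pairs whose expression correlation exceeds
#' the cutoff in absolute value, and records the lncRNA's classification.
#' lncRNAs absent from the correlation matrix are dropped with a warning.
#'
#' @param features Feature data frame holding genes and lncRNAs
#'   (kind column distinguishes them).
#' @param corr Correlation matrix over gene and lncRNA ids (from
#'   [compute_pcc_matrix()] on a matrix that includes lncRNA rows).
#' @param config A [colocation_config()].
#' @return Data frame: lncrna_id, gene_id, distance_bp, relation, r.
#' @export
lncrna_edges <- function(features, corr, config = colocation_config()) {
  .check_feature_df(features)
  if (!"kind" %in% names(features)) .stopf("feature table lacks 'kind'")
  lncs <- features[features$kind == "lncRNA", , drop = FALSE]
  genes <- features[features$kind == "gene", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(lncs))) {
    l <- lncs[i, , drop = FALSE]
    if (!l$id %in% rownames(corr)) {
      .warnf("lncRNA %s absent from the expression matrix; dropped", l$id)
      next
    }
    relation <- classify_lncrna(l, genes)
    near <- colocated_genes(l, genes, config)
    if (nrow(near) == 0) next
    have_expr <- near$gene_id %in% colnames(corr)
    near <- near[have_expr, , drop = FALSE]
    if (nrow(near) == 0) next
    r <- corr[l$id, near$gene_id]
    keep <- !is.na(r) & abs(r) > config$pcc_threshold
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      lncrna_id = l$id, gene_id = near$gene_id[keep],
      distance_bp = near$distance_bp[keep], relation = relation,
      r = unname(r[keep]), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance_bp = integer(0), relation = character(0),
                      r = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
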