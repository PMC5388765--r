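# Promoter extraction, IUPAC motif scanning, presence annotation and
# per-module hypergeometric enrichment of cis-regulatory elements (CREs).

#' Bundled default TF-binding-site motif set
#'
#' IUPAC consensi for the TF families most often implicated in
#' phenylpropanoid regulation.  `MYB_CCWACC` is the R2R3-MYB site; the
#' WRKY W-box, AP2/ERF GCC-box, bHLH E-box and bZIP G-box are standard
#' literature consensi supplied as replaceable defaults (users can load
#' their own set with [read_motifs()]).
#'
#' @return Data frame: name, iupac, tf_family.
#' @export
default_motifs <- function() {
  data.frame(
    name = c("MYB_CCWACC", "WRKY_Wbox", "ERF_GCCbox", "bHLH_Ebox",
             "bZIP_Gbox"),
    iupac = c("CCWACC", "TTGACY", "GCCGCC", "CANNTG", "CACGTG"),
    tf_family = c("R2R3-MYB", "WRKY", "AP2/ERF", "bHLH", "bZIP"),
    stringsAsFactors = FALSE)
}

#' Read / write a motif table (TSV: name, iupac, tf_family)
#'
#' @param path TSV file.
#' @return Data frame with validated IUPAC strings.
#' @export
read_motifs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "iupac")
  if (!all(need %in% names(df))) {
    .stopf("motif table needs columns: %s", paste(need, collapse = ", "))
  }
  if (is.null(df$tf_family)) df$tf_family <- "other"
  for (m in df$iupac) .iupac_allowed(m)
  df
}

#' @rdname read_motifs
#' @param motifs Motif data frame.
#' @export
write_motifs <- function(motifs, path) {
  write.table(motifs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract promoter sequences upstream of genes
#'
#' For a `+`-strand gene the promoter is the `length` bp immediately
#' upstream of its start; for a `-`-strand gene, the reverse complement of
#' the `length` bp immediately downstream of its end.  Unstranded (`.`)
#' features are treated as `+`.  Promoters running off a chromosome edge
#' are truncated with a warning.
#'
#' @param genes Feature data frame (0-based half-open coordinates).
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param length Promoter length in bp (default 2000).
#' @return A [Biostrings::DNAStringSet] named by gene id.
#' @export
extract_promoters <- function(genes, genome, length = 2000L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  # FASTA headers may carry descriptions after the first token
  names(genome) <- sub("\\s.*$", "", names(genome))
  .check_feature_df(genes)
  missing <- setdiff(genes$chrom, names(genome))
  if (length(missing) > 0) {
    .stopf("chromosome %s absent from the genome FASTA", missing[1])
  }
  out <- character(nrow(genes))
  truncated <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    clen <- Biostrings::width(genome[g$chrom])
    if (g$strand == "-") {
      from <- g$end
      to <- min(g$end + length, clen)
      if (to - from < length) truncated <- c(truncated, g$id)
      s <- Biostrings::subseq(genome[[g$chrom]], from + 1, to)
      out[i] <- as.character(Biostrings::reverseComplement(s))
    } else {
      from <- max(0, g$start - length)
      to <- g$start
      if (to - from < length) truncated <- c(truncated, g$id)
      out[i] <- as.character(
        Biostrings::subseq(genome[[g$chrom]], from + 1, to))
    }
  }
  if (length(truncated) > 0) {
    .warnf("%d promoter(s) truncated at a chromosome edge (e.g. %s)",
           length(truncated), truncated[1])
  }
  Biostrings::DNAStringSet(setNames(out, genes$id))
}

#' Scan promoters for an IUPAC motif on both strands
#'
#' Reports every occurrence of the degenerate motif on the forward strand
#' and every occurrence of its reverse complement (reported as strand
#' `-`).  Overlapping matches are all reported.  Positions are 0-based
#' offsets of the match start within the promoter (forward-strand
#' coordinates for both strands).
#'
#' @param promoters A [Biostrings::DNAStringSet] (or FASTA path) named by
#'   gene id.
#' @param motif An IUPAC string, or a row/list with `name` and `iupac`.
#' @return Data frame: gene_id, motif_name, position, strand; ordered by
#'   (gene_id, position, strand).
#' @export
#' @examples
#' p <- Biostrings::DNAStringSet(c(g1 = "TTCCAACCTT"))
#' scan_motif(p, "CCWACC")
scan_motif <- function(promoters, motif) {
  if (is.character(promoters) && length(promoters) == 1 &&
      file.exists(promoters)) {
    promoters <- Biostrings::readDNAStringSet(promoters)
  }
  if (is.character(promoters)) {
    promoters <- Biostrings::DNAStringSet(promoters)
  }
  if (is.character(motif) && is.null(names(motif))) {
    motif <- list(name = motif, iupac = motif)
  }
  .iupac_allowed(motif$iupac)  # errors on invalid IUPAC characters
  fwd <- Biostrings::vmatchPattern(motif$iupac, promoters, fixed = FALSE)
  rev <- Biostrings::vmatchPattern(.revcomp(motif$iupac), promoters,
                                   fixed = FALSE)
  one_strand <- function(hits, strand) {
    starts <- BiocGenerics::start(hits)
    n <- lengths(starts)
    if (sum(n) == 0) {
      return(data.frame(gene_id = character(0), motif_name = character(0),
                        position = integer(0), strand = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(gene_id = rep(names(promoters), n),
               motif_name = motif$name,
               position = unlist(starts, use.names = FALSE) - 1L,
               strand = strand, stringsAsFactors = FALSE)
  }
  out <- rbind(one_strand(fwd, "+"), one_strand(rev, "-"))
  out <- out[order(out$gene_id, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan promoters for a whole motif set
#'
#' @param promoters As in [scan_motif()].
#' @param motifs Motif data frame (name, iupac, ...).
#' @return Row-bound hit table over all motifs.
#' @export
scan_motifs <- function(promoters, motifs) {
  hits <- lapply(seq_len(nrow(motifs)), function(i) {
    scan_motif(promoters, motifs[i, ])
  })
  do.call(rbind, hits)
}

#' Motif presence matrix over a gene universe
#'
#' @param hits Hit table from [scan_motif()]/[scan_motifs()].
#' @param universe Character vector of gene ids (the promoters scanned).
#' @return Logical genes-by-motifs matrix; `TRUE` iff the gene's promoter
#'   has at least one hit for that motif.
#' @export
annotate_presence <- function(hits, universe) {
  motif_names <- sort(unique(hits$motif_name))
  m <- matrix(FALSE, nrow = length(universe), ncol = length(motif_names),
              dimnames = list(universe, motif_names))
  keep <- hits$gene_id %in% universe
  if (any(keep)) {
    m[cbind(hits$gene_id[keep], hits$motif_name[keep])] <- TRUE
  }
  m
}

#' Per-module motif enrichment (one-sided hypergeometric + BH)
#'
#' For each (module, motif) pair, tests whether motif presence is
#' over-represented in the module relative to the background universe
#' with the hypergeometric upper tail `P(X >= k)` for `k` motif-carrying
#' genes in a module of size `n`, given `K` carriers among `N` background
#' genes.  p-values are Benjamini-Hochberg adjusted across all tests.
#'
#' @param presence Logical genes-by-motifs matrix ([annotate_presence()]).
#' @param modules Named list of gene-id character vectors.
#' @param background Character vector of background gene ids (default all
#'   rows of `presence`).  Module genes outside the background or without
#'   a scanned promoter are excluded from `n` with a warning.
#' @return Data frame: module_id, motif_name, k, n, K, N, p_value, fdr.
#' @export
enrich_modules <- function(presence, modules,
                           background = rownames(presence)) {
  background <- intersect(background, rownames(presence))
  N <- length(background)
  bg <- presence[background, , drop = FALSE]
  rows <- list()
  for (mod in names(modules)) {
    ids <- modules[[mod]]
    usable <- intersect(ids, background)
    if (length(usable) < length(ids)) {
      .warnf("module %s: %d gene(s) without a scanned promoter excluded",
             mod, length(ids) - length(usable))
    }
    n <- length(usable)
    for (motif in colnames(presence)) {
      K <- sum(bg[, motif])
      k <- sum(presence[usable, motif])
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module_id = mod, motif_name = motif, k = k, n = n, K = K, N = N,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(module_id = character(0), motif_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$module_id, out$motif_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
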