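# Synthetic-data generators: expression compendium, genome features,
# promoters and miRNA/target pairs with planted, recoverable structure.

#' Stage expression profile templates
#'
#' Named developmental profiles on a 0-1 scale across ordered stages.
#' `"ripening_up"` rises sharply at the midpoint of development (the
#' veraison-like pivot), `"early_up"` is its mirror image (high early, then
#' down-regulated), `"mid_peak"` peaks at mid-development and is orthogonal
#' to the other two, and `"flat"` is constant (background).
#'
#' @param name One of `"ripening_up"`, `"early_up"`, `"mid_peak"`, `"flat"`.
#' @param n_stages Number of ordered developmental stages (>= 2).
#' @return Numeric vector of length `n_stages` in `[0, 1]`.
#' @export
#' @examples
#' stage_profile("ripening_up", 4)
stage_profile <- function(name, n_stages = 4) {
  stopifnot(.is_count(n_stages, min = 2))
  t <- seq(0, 1, length.out = n_stages)
  p <- switch(match.arg(name, c("ripening_up", "early_up", "mid_peak", "flat")),
    ripening_up = stats::plogis(12 * (t - 0.5)),
    early_up    = stats::plogis(-12 * (t - 0.5)),
    mid_peak    = sin(pi * t),
    flat        = rep(0.5, n_stages)
  )
  if (diff(range(p)) > 0) p <- (p - min(p)) / (max(p) - min(p))
  p
}

#' Define a planted co-expression module
#'
#' @param gene_ids Character vector of member gene identifiers.
#' @param base_profile Either a template name understood by
#'   [stage_profile()] or a numeric vector over stages (0-1 scale).
#' @param sign `+1` or `-1` per gene (recycled); `-1` members follow the
#'   negated (anti-correlated) profile, as in the antagonism between
#'   ripening-specific and early-stage gene clusters.
#' @param within_module_r Target within-module Pearson correlation in
#'   `[0, 1]`; `1` means members share the profile exactly (before global
#'   noise), smaller values add gene-specific variation calibrated so the
#'   expected pairwise correlation equals the target.
#' @return A `planted_module` list.
#' @export
planted_module <- function(gene_ids, base_profile = "ripening_up",
                           sign = 1L, within_module_r = 1) {
  stopifnot(is.character(gene_ids), length(gene_ids) > 0)
  if (anyDuplicated(gene_ids)) {
    .stopf("duplicated gene id within module: %s",
           gene_ids[duplicated(gene_ids)][1])
  }
  sign <- rep_len(as.integer(sign), length(gene_ids))
  if (!all(sign %in% c(-1L, 1L))) .stopf("sign must be +1 or -1")
  if (!.is_scalar_num(within_module_r) ||
      within_module_r < 0 || within_module_r > 1) {
    .stopf("within_module_r must be in [0, 1]")
  }
  structure(list(gene_ids = gene_ids, base_profile = base_profile,
                 sign = sign, within_module_r = within_module_r),
            class = "planted_module")
}

#' Define a simulated expression study design
#'
#' Emulates a multi-cultivar developmental series: `n_cultivars` genotypes
#' sampled at `n_stages` ordered stages with `replicates_per_cell`
#' replicates, giving `n_cultivars * n_stages * replicates_per_cell` sample
#' columns.  Planted modules carry stage-driven profiles; background genes
#' are flat plus noise.
#'
#' Abundances are generated on a log2 scale
#' (`baseline + amplitude * sign * (profile - 0.5) + noise`) and emitted as
#' `2^z - 1`, so the default log2(x+1) transform of the network stage
#' recovers the planted correlation structure exactly.
#'
#' @param n_cultivars,n_stages,replicates_per_cell Design counts
#'   (`n_cultivars >= 1`, `n_stages >= 2`, `replicates_per_cell >= 1`).
#' @param modules List of [planted_module()] objects with disjoint gene ids.
#' @param n_background Number of uncorrelated background genes appended.
#' @param baseline,amplitude Log2-scale location and dynamic range of the
#'   planted profiles (units of log2 abundance).
#' @param noise_sd Log2-scale i.i.d. Gaussian noise standard deviation
#'   (>= 0); the study-condition default is 20% of `amplitude`.
#' @param seed Integer seed.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_cultivars = 5, n_stages = 4,
                              replicates_per_cell = 1,
                              modules = list(),
                              n_background = 30,
                              baseline = 5, amplitude = 4,
                              noise_sd = 0.2 * amplitude,
                              seed = 1L) {
  stopifnot(.is_count(n_cultivars), .is_count(n_stages, min = 2),
            .is_count(replicates_per_cell), .is_count(n_background, min = 0))
  if (!.is_scalar_num(noise_sd) || noise_sd < 0) {
    .stopf("noise_sd must be a nonnegative number")
  }
  for (m in modules) {
    if (!inherits(m, "planted_module")) {
      .stopf("modules must be a list of planted_module objects")
    }
  }
  all_ids <- unlist(lapply(modules, `[[`, "gene_ids"))
  if (anyDuplicated(all_ids)) {
    .stopf("gene id assigned to more than one module: %s",
           all_ids[duplicated(all_ids)][1])
  }
  structure(list(n_cultivars = n_cultivars, n_stages = n_stages,
                 replicates_per_cell = replicates_per_cell,
                 modules = modules, n_background = n_background,
                 baseline = baseline, amplitude = amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Default three-module study design
#'
#' Five cultivars by four stages, one replicate per cell; three planted
#' 10-gene modules (ripening-specific, early-stage, mid-peak) and 30
#' background genes, with noise at 20% of the profile amplitude.
#'
#' @param seed Integer seed.
#' @inheritParams simulation_design
#' @return A `simulation_design`.
#' @export
default_design <- function(seed = 1L, noise_sd = 0.8) {
  simulation_design(
    modules = list(
      planted_module(sprintf("ripe_g%02d", 1:10), "ripening_up"),
      planted_module(sprintf("early_g%02d", 1:10), "early_up"),
      planted_module(sprintf("mid_g%02d", 1:10), "mid_peak")
    ),
    n_background = 30, noise_sd = noise_sd, seed = seed
  )
}

.resolve_profile <- function(base_profile, n_stages) {
  if (is.character(base_profile)) {
    stage_profile(base_profile, n_stages)
  } else {
    if (length(base_profile) != n_stages) {
      .stopf("base_profile length (%d) != n_stages (%d)",
             length(base_profile), n_stages)
    }
    as.numeric(base_profile)
  }
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' @param design A [simulation_design()].
#' @return Numeric genes-by-samples matrix of nonnegative abundances.
#'   Column names follow `cultivarX_stageY_repZ`; attributes `design`
#'   (sample design data frame) and `modules` (named list of planted member
#'   ids, `background` included) carry the ground truth.
#' @export
#' @examples
#' m <- simulate_expression(default_design(seed = 7))
#' dim(m)
simulate_expression <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  samp <- expand.grid(rep = seq_len(d$replicates_per_cell),
                      stage = seq_len(d$n_stages),
                      cultivar = seq_len(d$n_cultivars))
  samp <- samp[, c("cultivar", "stage", "rep")]
  samp <- samp[order(samp$cultivar, samp$stage, samp$rep), , drop = FALSE]
  rownames(samp) <- NULL
  sample_ids <- sprintf("cultivar%d_stage%d_rep%d",
                        samp$cultivar, samp$stage, samp$rep)
  n_samples <- nrow(samp)

  module_ids <- lapply(d$modules, `[[`, "gene_ids")
  names(module_ids) <- if (length(d$modules)) {
    paste0("module", seq_along(d$modules))
  } else {
    character(0)
  }
  bg_ids <- if (d$n_background > 0) {
    sprintf("bg_g%03d", seq_len(d$n_background))
  } else {
    character(0)
  }
  dup <- intersect(unlist(module_ids), bg_ids)
  if (length(dup)) .stopf("background id collides with module gene: %s", dup[1])
  gene_ids <- c(unlist(module_ids, use.names = FALSE), bg_ids)

  z <- .with_seed(d$seed, {
    z <- matrix(0, nrow = length(gene_ids), ncol = n_samples,
                dimnames = list(gene_ids, sample_ids))
    for (m in d$modules) {
      prof <- .resolve_profile(m$base_profile, d$n_stages)
      centred <- d$amplitude * (prof[samp$stage] - 0.5)
      v_prof <- stats::var(centred)
      rho <- m$within_module_r
      tau <- if (rho > 0 && rho < 1 && v_prof > 0) {
        sqrt(v_prof * (1 - rho) / rho)
      } else if (rho == 0) {
        # uncorrelated members: drop the shared profile entirely
        NA_real_
      } else {
        0
      }
      for (i in seq_along(m$gene_ids)) {
        base <- if (is.na(tau)) rep(0, n_samples) else m$sign[i] * centred
        extra <- if (is.na(tau)) {
          rnorm(n_samples, 0, sqrt(max(v_prof, 1)))
        } else if (tau > 0) {
          rnorm(n_samples, 0, tau)
        } else {
          0
        }
        z[m$gene_ids[i], ] <- d$baseline + base + extra
      }
    }
    for (g in bg_ids) z[g, ] <- d$baseline
    z + matrix(rnorm(length(z), 0, d$noise_sd), nrow = nrow(z))
  })
  x <- pmax(2^z - 1, 0)
  truth <- module_ids
  truth$background <- bg_ids
  attr(x, "design") <- data.frame(sample_id = sample_ids, samp,
                                  stringsAsFactors = FALSE)
  attr(x, "modules") <- truth
  x
}

#' Write / read an expression table
#'
#' Plain TSV, genes in rows, first column `gene_id`, remaining columns one
#' per sample named `cultivarX_stageY_repZ`.
#'
#' @param m Genes-by-samples numeric matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Genome simulation

#' Specify a synthetic genome layout
#'
#' The default layout realises the two genomic motifs the co-location stage
#' is designed to detect: a tandem cluster of nine same-strand paralogs with
#' an adjacent intergenic lncRNA 20 kb upstream (emulating a stilbene
#' synthase-like tandem array), and an antisense lncRNA overlapping a gene
#' on the opposite strand.  Additional genes can be placed at regular
#' spacing on a filler chromosome.
#'
#' All coordinates in the specification and in the returned feature table
#' are 0-based half-open; emitted GFF3 is 1-based inclusive.
#'
#' @param chromosomes Named numeric vector of chromosome lengths (bp).
#' @param tandem_cluster List: `chrom`, `gene_ids` (consecutive, same
#'   strand), `lncrna_id`, `gene_length`, `gap` (between consecutive genes,
#'   must stay below the co-location window), `cluster_start`,
#'   `lncrna_length`, `lncrna_upstream` (distance from lncRNA start to the
#'   first gene start), `strand`.
#' @param antisense_pair List: `chrom`, `gene_id`, `lncrna_id`,
#'   `gene_start`, `gene_length`, `lncrna_offset` (within the gene),
#'   `lncrna_length`; gene on `+`, lncRNA on `-`.
#' @param other_genes List: `chrom`, `gene_ids`, `start`, `spacing`,
#'   `gene_length` for filler genes.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(chromosomes = c(chr01 = 250000, chr03 = 50000,
                                        chr10 = 150000),
                        tandem_cluster = list(
                          chrom = "chr10",
                          gene_ids = sprintf("sts%02d", 1:9),
                          lncrna_id = "lnc_sts",
                          gene_length = 2000, gap = 5000,
                          cluster_start = 50000,
                          lncrna_length = 1000, lncrna_upstream = 20000,
                          strand = "+"),
                        antisense_pair = list(
                          chrom = "chr03",
                          gene_id = "ggt01", lncrna_id = "lnc_as",
                          gene_start = 10000, gene_length = 3000,
                          lncrna_offset = 1000, lncrna_length = 1000),
                        other_genes = list(
                          chrom = "chr01", gene_ids = character(0),
                          start = 5000, spacing = 3000, gene_length = 1500)) {
  structure(list(chromosomes = chromosomes, tandem_cluster = tandem_cluster,
                 antisense_pair = antisense_pair, other_genes = other_genes),
            class = "genome_spec")
}

.feature_row <- function(id, chrom, start, end, strand, kind) {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, kind = kind, stringsAsFactors = FALSE)
}

#' Simulate chromosome sequences and gene/lncRNA annotations
#'
#' Generates random chromosome sequences and a feature table realising the
#' layout of a [genome_spec()]; optionally writes GFF3 and FASTA.  When
#' `promoter_motif` is given, the `region` bp upstream of every gene is
#' scrubbed of exact motif matches (either strand) and one motif instance
#' is planted upstream of each gene in `planted_gene_ids`, giving the CRE
#' enrichment stage a controlled signal.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#' @param dir Optional output directory; if given, writes `genome.fa` and
#'   `features.gff3`.
#' @param promoter_motif Optional list with `iupac`, `planted_gene_ids`,
#'   `region` (upstream bp, default 1000).
#' @return List with `features` (0-based half-open data frame: id, chrom,
#'   start, end, strand, kind), `genome` (a [Biostrings::DNAStringSet]),
#'   and when `dir` is given `fasta_path` / `gff_path`.
#' @export
simulate_genome <- function(spec = genome_spec(), seed = 1L, dir = NULL,
                            promoter_motif = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  tc <- spec$tandem_cluster
  ap <- spec$antisense_pair
  og <- spec$other_genes
  chrom_len <- spec$chromosomes

  feats <- list()
  if (!is.null(tc) && length(tc$gene_ids)) {
    step <- tc$gene_length + tc$gap
    starts <- tc$cluster_start + step * (seq_along(tc$gene_ids) - 1)
    feats[[length(feats) + 1]] <- .feature_row(
      tc$gene_ids, tc$chrom, starts, starts + tc$gene_length,
      tc$strand, "gene")
    lnc_start <- tc$cluster_start - tc$lncrna_upstream
    feats[[length(feats) + 1]] <- .feature_row(
      tc$lncrna_id, tc$chrom, lnc_start, lnc_start + tc$lncrna_length,
      "+", "lncRNA")
  }
  if (!is.null(ap)) {
    feats[[length(feats) + 1]] <- .feature_row(
      ap$gene_id, ap$chrom, ap$gene_start,
      ap$gene_start + ap$gene_length, "+", "gene")
    lnc_start <- ap$gene_start + ap$lncrna_offset
    feats[[length(feats) + 1]] <- .feature_row(
      ap$lncrna_id, ap$chrom, lnc_start, lnc_start + ap$lncrna_length,
      "-", "lncRNA")
  }
  if (!is.null(og) && length(og$gene_ids)) {
    step <- og$gene_length + og$spacing
    starts <- og$start + step * (seq_along(og$gene_ids) - 1)
    feats[[length(feats) + 1]] <- .feature_row(
      og$gene_ids, og$chrom, starts, starts + og$gene_length, "+", "gene")
  }
  features <- if (length(feats)) {
    do.call(rbind, feats)
  } else {
    .feature_row(character(0), character(0), integer(0), integer(0),
                 character(0), character(0))
  }
  rownames(features) <- NULL

  bad_chrom <- setdiff(features$chrom, names(chrom_len))
  if (length(bad_chrom)) .stopf("unknown chromosome: %s", bad_chrom[1])
  over <- features$end > chrom_len[features$chrom] | features$start < 0
  if (any(over)) {
    .stopf("feature exceeds chromosome bounds: %s", features$id[over][1])
  }
  if (anyDuplicated(features$id)) {
    .stopf("duplicate feature id: %s",
           features$id[duplicated(features$id)][1])
  }

  genome <- .with_seed(seed, {
    seqs <- vapply(chrom_len, .random_dna, character(1))
    if (!is.null(promoter_motif)) {
      region <- promoter_motif$region %||% 1000L
      motif <- promoter_motif$iupac
      genes <- features[features$kind == "gene", , drop = FALSE]
      for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        win <- if (g$strand == "-") {
          c(g$end, min(g$end + region, chrom_len[[g$chrom]]))
        } else {
          c(max(0, g$start - region), g$start)
        }
        if (win[2] - win[1] < nchar(motif)) next
        slice <- substr(seqs[[g$chrom]], win[1] + 1, win[2])
        slice <- .scrub_motif(slice, motif)
        if (g$id %in% (promoter_motif$planted_gene_ids %||% character(0))) {
          slice <- .plant_motif(slice, motif)
        }
        substr(seqs[[g$chrom]], win[1] + 1, win[2]) <- slice
      }
    }
    seqs
  })
  genome <- Biostrings::DNAStringSet(genome)

  out <- list(features = features, genome = genome)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$fasta_path <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, out$fasta_path)
    out$gff_path <- file.path(dir, "features.gff3")
    write_features_gff3(features, out$gff_path, seqlengths = chrom_len)
  }
  out
}

#' Write a feature table as GFF3
#'
#' Internal coordinates are 0-based half-open; the emitted GFF3 is 1-based
#' inclusive.  Genes are written with type `gene`, lncRNAs with type
#' `lnc_RNA` and attribute `biotype=lncRNA`.
#'
#' @param features Feature data frame (id, chrom, start, end, strand, kind).
#' @param path Output file.
#' @param seqlengths Optional named chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path, seqlengths = NULL) {
  if (nrow(features) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1, end = features$end),
    strand = ifelse(features$strand == ".", "*", features$strand))
  S4Vectors::mcols(gr)$type <- ifelse(features$kind == "lncRNA",
                                      "lnc_RNA", "gene")
  S4Vectors::mcols(gr)$ID <- features$id
  S4Vectors::mcols(gr)$biotype <- ifelse(features$kind == "lncRNA",
                                         "lncRNA", "protein_coding")
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlengths(gr) <-
      seqlengths[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# IUPAC helpers for planting/scrubbing motifs (plain matcher, generator-side)

.iupac_allowed <- function(motif) {
  chars <- .seq_chars(motif, allowed = names(Biostrings::IUPAC_CODE_MAP),
                      what = "IUPAC motif")
  lapply(chars, function(ch) {
    strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "", fixed = TRUE)[[1]]
  })
}

# 0-based start positions where `motif` (IUPAC) matches `chars` (A/C/G/T).
.iupac_starts <- function(chars, motif) {
  allowed <- .iupac_allowed(motif)
  L <- length(allowed)
  n <- length(chars)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1)
  for (i in seq_len(L)) {
    ok <- ok & chars[i:(n - L + i)] %in% allowed[[i]]
  }
  which(ok) - 1L
}

# Remove every match of motif (both strands) from a sequence string by point
# mutation; used so non-planted promoters are exactly motif-free.
.scrub_motif <- function(seq, motif) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  rc <- .revcomp(motif)
  L <- nchar(motif)
  for (iter in 1:100) {
    hits <- c(.iupac_starts(chars, motif), .iupac_starts(chars, rc))
    if (!length(hits)) return(paste(chars, collapse = ""))
    for (h in hits) {
      pos <- h + sample.int(L, 1)
      chars[pos] <- sample(DNA_BASES, 1)
    }
  }
  .stopf("failed to scrub motif %s after 100 rounds", motif)
}

# Instantiate the IUPAC motif (random choice at degenerate positions) and
# overwrite a random window of the sequence with it.
.plant_motif <- function(seq, motif) {
  allowed <- .iupac_allowed(motif)
  inst <- vapply(allowed, function(a) sample(a, 1), character(1))
  L <- length(inst)
  n <- nchar(seq)
  if (n < L) .stopf("sequence shorter than motif")
  at <- sample.int(n - L + 1, 1)
  substr(seq, at, at + L - 1) <- paste(inst, collapse = "")
  seq
}

#' Simulate promoter sequences with a planted motif at a set frequency
#'
#' One uniform-random sequence per gene; exactly `round(planted_fraction *
#' n)` of them (round half up) carry at least one instance of the motif,
#' the remainder are rejection-scrubbed so they contain no match on either
#' strand.
#'
#' @param gene_ids Character vector naming the promoters.
#' @param motif IUPAC motif string (default the MYB site `CCWACC`).
#' @param planted_fraction Fraction of promoters carrying the motif, in
#'   `[0, 1]`.
#' @param promoter_length Length of each promoter (bp); must be at least
#'   the motif length.
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] named by `gene_ids`, with attribute
#'   `planted`: logical vector marking the motif-carrying promoters.
#' @export
simulate_promoters <- function(gene_ids, motif = "CCWACC",
                               planted_fraction = 0.5,
                               promoter_length = 2000, seed = 1L) {
  stopifnot(is.character(gene_ids), length(gene_ids) > 0)
  if (!.is_scalar_num(planted_fraction) ||
      planted_fraction < 0 || planted_fraction > 1) {
    .stopf("planted_fraction must be in [0, 1]")
  }
  .iupac_allowed(motif)  # validates characters
  if (nchar(motif) > promoter_length) {
    .stopf("motif (%d bp) longer than promoter_length (%d bp)",
           nchar(motif), promoter_length)
  }
  n <- length(gene_ids)
  k <- .round_half_up(planted_fraction * n)
  .with_seed(seed, {
    planted <- rep(FALSE, n)
    planted[sample.int(n, k)] <- TRUE
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- .scrub_motif(.random_dna(promoter_length), motif)
      if (planted[i]) s <- .plant_motif(s, motif)
      seqs[i] <- s
    }
    out <- Biostrings::DNAStringSet(setNames(seqs, gene_ids))
    attr(out, "planted") <- setNames(planted, gene_ids)
    out
  })
}

# ---------------------------------------------------------------------------
# miRNA/target pair simulation

#' Simulate miRNAs with controlled complementarity to given transcripts
#'
#' Each miRNA is the reverse complement of a random window of its target
#' transcript, into which exactly `mismatches` mismatching and `wobbles`
#' G:U-wobble positions are introduced at recorded miRNA positions.  The
#' returned truth table carries the window start and the expectation score
#' implied by the penalty scheme, for use as ground truth when testing the
#' target-prediction stage.
#'
#' @param transcripts Named character vector or [Biostrings::DNAStringSet]
#'   of transcript sequences. Transcripts shorter than `mirna_length` are
#'   skipped with a warning.
#' @param n_pairs Number of miRNA/target pairs to emit (targets are cycled).
#' @param mismatches,wobbles Nonnegative counts of perturbed positions per
#'   duplex.
#' @param seed Integer seed.
#' @param mirna_length miRNA length in nt (default 21).
#' @param scheme [scoring_scheme()] used to compute truth expectations.
#' @return List with `mirnas` (an [Biostrings::RNAStringSet]) and `truth`,
#'   a data frame with columns mirna_id, transcript_id, window_start
#'   (0-based), mismatch_pos, wobble_pos (comma-separated miRNA positions,
#'   5' to 3'), expectation.
#' @export
simulate_mirna_pairs <- function(transcripts, n_pairs = 2L,
                                 mismatches = 0L, wobbles = 0L, seed = 1L,
                                 mirna_length = 21L,
                                 scheme = scoring_scheme()) {
  stopifnot(mismatches >= 0, wobbles >= 0,
            mismatches + wobbles <= mirna_length)
  if (methods::is(transcripts, "XStringSet")) {
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  }
  if (is.null(names(transcripts)) || any(!nzchar(names(transcripts)))) {
    .stopf("transcripts must be named")
  }
  usable <- nchar(transcripts) >= mirna_length
  if (any(!usable)) {
    .warnf("skipping %d transcript(s) shorter than the miRNA length",
           sum(!usable))
  }
  transcripts <- transcripts[usable]
  if (!length(transcripts)) .stopf("no transcript long enough")

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wobble_partner <- c(G = "T", T = "G")  # miRNA base -> target base

  .with_seed(seed, {
    rows <- vector("list", n_pairs)
    mirnas <- character(n_pairs)
    mirna_ids <- sprintf("mir_%02d", seq_len(n_pairs))
    for (p in seq_len(n_pairs)) {
      t_idx <- ((p - 1) %% length(transcripts)) + 1
      tseq <- .seq_chars(transcripts[[t_idx]], what = "transcript")
      ws <- sample.int(length(tseq) - mirna_length + 1, 1) - 1L
      window <- tseq[(ws + 1):(ws + mirna_length)]
      # miRNA position i (5'->3') pairs with window position L - i + 1
      target_at <- rev(window)
      mi <- unname(comp[target_at])

      # wobble-able positions: target base T (miRNA -> G) or G (miRNA -> U)
      elig_w <- which(target_at %in% c("T", "G"))
      if (length(elig_w) < wobbles) {
        .stopf("window admits only %d wobble position(s), %d requested",
               length(elig_w), wobbles)
      }
      wpos <- sort(sample(elig_w, wobbles))
      remaining <- setdiff(seq_len(mirna_length), wpos)
      mpos <- sort(sample(remaining, mismatches))
      for (i in wpos) {
        mi[i] <- names(wobble_partner)[wobble_partner == target_at[i]]
      }
      for (i in mpos) {
        forbidden <- c(comp[[target_at[i]]],
                       names(wobble_partner)[wobble_partner == target_at[i]])
        mi[i] <- sample(setdiff(DNA_BASES, forbidden), 1)
      }
      # truth expectation from the recorded positions, by direct arithmetic
      in_core <- function(i) i >= scheme$core_start & i <= scheme$core_end
      mult <- function(i) ifelse(in_core(i), scheme$core_multiplier, 1)
      expectation <- sum(scheme$mismatch_penalty * mult(mpos)) +
        sum(scheme$wobble_penalty * mult(wpos))

      mirnas[p] <- chartr("T", "U", paste(mi, collapse = ""))
      rows[[p]] <- data.frame(
        mirna_id = mirna_ids[p],
        transcript_id = names(transcripts)[t_idx],
        window_start = ws,
        mismatch_pos = paste(mpos, collapse = ","),
        wobble_pos = paste(wpos, collapse = ","),
        expectation = expectation,
        stringsAsFactors = FALSE)
    }
    list(mirnas = Biostrings::RNAStringSet(setNames(mirnas, mirna_ids)),
         truth = do.call(rbind, rows))
  })
}
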