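# One-shot pipeline: chains GCN -> co-location -> miRNA targets -> CRE
# enrichment -> integration from a single validated configuration, and
# writes a run manifest with parameter and file checksums.

#' Pipeline configuration
#'
#' Collects all stage inputs and parameters.  Input paths are validated
#' by [validate_config()] before any stage runs.  A single global seed is
#' fanned out to per-stage seeds by fixed offsets so stages are
#' independently reproducible.
#'
#' @param expression Expression TSV (genes x samples; lncRNA rows
#'   included so the co-location stage can correlate them).
#' @param features GFF3/BED with gene and lncRNA coordinates.
#' @param genome Chromosome FASTA.
#' @param transcripts Transcript FASTA (miRNA target search space).
#' @param mirnas Mature miRNA FASTA.
#' @param transcript_map TSV: transcript_id, gene_id.
#' @param motifs Motif TSV (name, iupac, tf_family).
#' @param tf_list Plain-text file, one TF gene id per line.
#' @param pathway_genes Plain-text file, one pathway gene id per line.
#' @param out_dir Output directory (created if needed).
#' @param pcc_threshold Gene-gene co-expression cutoff (default 0.8).
#' @param tf_pcc_threshold TF-gene co-expression cutoff; defaults to
#'   `pcc_threshold`.
#' @param window_bp lncRNA co-location window (default 100000).
#' @param promoter_length Promoter window (bp upstream, default 2000).
#' @param scheme A [scoring_scheme()].
#' @param module_method `"components"` or `"greedy"`.
#' @param min_module_size Smallest module tested for CRE enrichment
#'   (default 3).
#' @param gene_filter Optional rule for [filter_dynamic_genes()] applied
#'   to gene rows (lncRNA rows are always retained for correlation).
#' @param transform `"log2"` or `"raw"` for the correlation stage.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, features, genome, transcripts,
                            mirnas, transcript_map, motifs, tf_list,
                            pathway_genes, out_dir,
                            pcc_threshold = 0.8, tf_pcc_threshold = NULL,
                            window_bp = 100000L, promoter_length = 2000L,
                            scheme = scoring_scheme(),
                            module_method = "components",
                            min_module_size = 3L,
                            gene_filter = NULL,
                            transform = "log2", seed = 1L) {
  structure(list(
    expression = expression, features = features, genome = genome,
    transcripts = transcripts, mirnas = mirnas,
    transcript_map = transcript_map, motifs = motifs, tf_list = tf_list,
    pathway_genes = pathway_genes, out_dir = out_dir,
    pcc_threshold = pcc_threshold,
    tf_pcc_threshold = tf_pcc_threshold %||% pcc_threshold,
    window_bp = as.integer(window_bp),
    promoter_length = as.integer(promoter_length),
    scheme = scheme, module_method = module_method,
    min_module_size = as.integer(min_module_size),
    gene_filter = gene_filter, transform = transform,
    seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Relative input paths are resolved against the YAML file's directory.
#' Scoring-scheme fields may be given under a `scheme:` mapping.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_fields <- c("expression", "features", "genome", "transcripts",
                   "mirnas", "transcript_map", "motifs", "tf_list",
                   "pathway_genes", "out_dir")
  for (f in path_fields) {
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]])) {
      y[[f]] <- file.path(base, y[[f]])
    }
  }
  if (!is.null(y$scheme)) y$scheme <- do.call(scoring_scheme, y$scheme)
  do.call(pipeline_config, y)
}

#' Validate a pipeline configuration
#'
#' Checks that every referenced input file exists and that parameters are
#' in range; errors (condition class `phenolnet_validation_error`) before
#' any stage runs.
#'
#' @param config A `pipeline_config`.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  fail <- function(msg) {
    stop(structure(class = c("phenolnet_validation_error", "error",
                             "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  for (f in c("expression", "features", "genome", "transcripts", "mirnas",
              "transcript_map", "motifs", "tf_list", "pathway_genes")) {
    if (!file.exists(config[[f]])) {
      fail(sprintf("input file for '%s' not found: %s", f, config[[f]]))
    }
  }
  if (config$pcc_threshold <= 0 || config$pcc_threshold > 1) {
    fail("pcc_threshold must be in (0, 1]")
  }
  if (config$window_bp < 0) fail("window_bp must be >= 0")
  if (!config$module_method %in% c("components", "greedy")) {
    fail(sprintf("unknown module method: %s", config$module_method))
  }
  invisible(config)
}

.read_id_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids) & !startsWith(ids, "#")]
}

#' Run the full multilayer-network pipeline
#'
#' Executes, in order: co-expression network construction, lncRNA
#' co-location, miRNA target prediction, promoter CRE scanning and
#' module enrichment, and multilayer integration with pathway subnetwork
#' extraction.  All stage outputs and a JSON run manifest (package
#' version, parameters, input and output MD5 checksums) are written to
#' `config$out_dir`; reruns with identical inputs and seed are
#' byte-identical.  Any stage failure halts with the stage name.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return Invisibly, a list with the in-memory stage results
#'   (`gcn_edges`, `lnc_edges`, `mir_edges`, `enrichment`, `modules`,
#'   `network`, `subnetwork`, `centrality`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  tf_ids <- .read_id_list(config$tf_list)
  pathway <- .read_id_list(config$pathway_genes)
  outputs <- character(0)
  emit <- function(obj, file, writer = write_edges) {
    p <- file.path(out_dir, file)
    writer(obj, p)
    outputs <<- c(outputs, p)
    p
  }

  features <- stage("colocation", parse_features(config$features))
  lnc_ids <- features$id[features$kind == "lncRNA"]

  ## stage 1: co-expression network -------------------------------------
  res <- stage("gcn", {
    m <- load_expression(config$expression)
    if (!is.null(config$gene_filter)) {
      gene_rows <- !rownames(m) %in% lnc_ids
      kept <- filter_dynamic_genes(m[gene_rows, , drop = FALSE],
                                   config$gene_filter)
      m <- rbind(kept, m[!gene_rows, , drop = FALSE])
    }
    ncfg <- network_config(
      pcc_threshold = min(config$pcc_threshold, config$tf_pcc_threshold),
      transform = config$transform)
    corr <- compute_pcc_matrix(m, ncfg)
    edges <- build_network(corr, ncfg)
    # gene-gene layer: drop pairs involving lncRNAs (they live in the
    # co-location layer) and apply the per-class thresholds strictly
    is_lnc <- edges$gene_a %in% lnc_ids | edges$gene_b %in% lnc_ids
    edges <- edges[!is_lnc, , drop = FALSE]
    one_tf <- xor(edges$gene_a %in% tf_ids, edges$gene_b %in% tf_ids)
    th <- ifelse(one_tf, config$tf_pcc_threshold, config$pcc_threshold)
    edges <- edges[abs(edges$r) > th, , drop = FALSE]
    rownames(edges) <- NULL
    list(corr = corr, edges = edges)
  })
  gcn_edges <- res$edges
  corr <- res$corr
  emit(gcn_edges, "gcn_edges.tsv")

  ## stage 2: lncRNA co-location ----------------------------------------
  lnc_e <- stage("colocation", {
    lncrna_edges(features, corr,
                 colocation_config(config$window_bp, config$pcc_threshold))
  })
  emit(lnc_e, "lncrna_edges.tsv")

  ## stage 3: miRNA targets ----------------------------------------------
  mir <- stage("mirna_target", {
    duplexes <- predict_targets(config$mirnas, config$transcripts,
                                config$scheme)
    map <- read.delim(config$transcript_map, stringsAsFactors = FALSE)
    list(duplexes = duplexes, edges = mirna_edges(duplexes, map))
  })
  emit(mir$duplexes, "mirna_duplexes.tsv")
  emit(mir$edges, "mirna_edges.tsv")

  ## stage 4: promoter CREs ----------------------------------------------
  cre <- stage("cre_enrichment", {
    genes <- features[features$kind == "gene", , drop = FALSE]
    promoters <- extract_promoters(genes, config$genome,
                                   config$promoter_length)
    motifs <- read_motifs(config$motifs)
    hits <- scan_motifs(promoters, motifs)
    presence <- annotate_presence(hits, names(promoters))
    net0 <- assemble_network(gcn_edges, tf_ids)
    partition <- detect_modules(net0, config$module_method,
                                seed = config$seed + 40L)
    mods <- split(names(partition), unname(partition))
    mods <- mods[lengths(mods) >= config$min_module_size]
    enrichment <- enrich_modules(presence, mods)
    list(promoters = promoters, hits = hits, presence = presence,
         partition = partition, enrichment = enrichment)
  })
  emit(cre$promoters, "promoters.fa",
       function(x, p) Biostrings::writeXStringSet(x, p))
  emit(cre$hits, "motif_hits.tsv")
  emit(data.frame(gene_id = rownames(cre$presence), cre$presence,
                  check.names = FALSE), "motif_presence.tsv")
  emit(cre$enrichment, "enrichment.tsv")
  emit(data.frame(id = names(cre$partition),
                  module = unname(cre$partition)), "modules.tsv")

  ## stage 5: integration ------------------------------------------------
  net <- stage("integrate", {
    assemble_network(gcn_edges, tf_ids, lnc_e, mir$edges,
                     annotations = list(motif_presence = cre$presence,
                                        pathway_genes = pathway))
  })
  subnet <- stage("integrate",
                  extract_subnetwork(net, pathway,
                                     include_regulators = TRUE))
  centrality <- centrality_report(net)
  emit(net, "network.graphml", function(x, p) export_network(x, p, "graphml"))
  emit(net, "network.sif", function(x, p) export_network(x, p, "sif"))
  emit(net, "network", function(x, p) export_network(x, p, "tsv"))
  outputs <- c(setdiff(outputs, file.path(out_dir, "network")),
               file.path(out_dir, c("network_nodes.tsv",
                                    "network_edges.tsv")))
  emit(subnet, "subnetwork.graphml",
       function(x, p) export_network(x, p, "graphml"))
  emit(centrality, "centrality.tsv")

  ## manifest -------------------------------------------------------------
  input_files <- unlist(config[c("expression", "features", "genome",
                                 "transcripts", "mirnas", "transcript_map",
                                 "motifs", "tf_list", "pathway_genes")])
  manifest <- list(
    package = "phenolnet",
    version = as.character(utils::packageVersion("phenolnet")),
    stages = c("gcn", "colocation", "mirna_target", "cre_enrichment",
               "integrate"),
    parameters = list(
      pcc_threshold = config$pcc_threshold,
      tf_pcc_threshold = config$tf_pcc_threshold,
      window_bp = config$window_bp,
      promoter_length = config$promoter_length,
      scheme = unclass(config$scheme),
      module_method = config$module_method,
      min_module_size = config$min_module_size,
      transform = config$transform,
      seed = config$seed),
    inputs = setNames(as.vector(tools::md5sum(input_files)),
                      basename(input_files)),
    outputs = setNames(as.vector(tools::md5sum(sort(outputs))),
                       basename(sort(outputs))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(gcn_edges = gcn_edges, lnc_edges = lnc_e,
                 duplexes = mir$duplexes, mir_edges = mir$edges,
                 promoters = cre$promoters, presence = cre$presence,
                 enrichment = cre$enrichment, modules = cre$partition,
                 network = net, subnetwork = subnet,
                 centrality = centrality, manifest = manifest,
                 out_dir = out_dir))
}
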