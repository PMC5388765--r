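# End-to-end synthetic study: one call writes every pipeline input with
# known planted structure, plus a ready-to-run pipeline.yaml and a truth
# table, emulating the multi-cultivar berry ripening design, a tandem
# paralog cluster with its adjacent intergenic lncRNA, an antisense
# lncRNA/gene pair, planted promoter motifs and miRNA/target pairs.

#' Generate the full synthetic study fixture suite
#'
#' Writes into `dir`:
#' \itemize{
#'   \item `expression.tsv`: 5 cultivars x 4 stages; three planted
#'     modules — a ripening-specific module holding the nine tandem
#'     paralogs (`sts01`..`sts09`), two TFs and the adjacent intergenic
#'     lncRNA `lnc_sts`; an early-stage module holding `ggt01` (the
#'     antisense-paired gene), `fla02`..`fla10` and the antisense lncRNA
#'     `lnc_as`; a mid-peak module `mid01`..`mid08` — plus 20 background
#'     genes.  Noise is 10% of the profile amplitude, emulating the
#'     strong co-regulation the co-location layer is designed to pick up.
#'   \item `genome.fa` / `features.gff3`: the tandem cluster on chr10
#'     with `lnc_sts` 20 kb upstream, `ggt01`/`lnc_as` overlapping
#'     antisense on chr03, all remaining genes spaced along chr01; the
#'     MYB site CCWACC is scrubbed from every promoter region and planted
#'     upstream of the nine `sts` genes and two background genes.
#'   \item `transcripts.fa`, `transcript_map.tsv`: one random transcript
#'     per gene.
#'   \item `mirnas.fa`, `mirna_truth.tsv`: three miRNAs — a perfect
#'     complement of a `fla02` window, one mismatch against `mid01`, one
#'     G:U wobble against `sts02` — with their expected scores.
#'   \item `motifs.tsv`, `tf_list.txt`, `pathway_genes.txt`,
#'     `pipeline.yaml`, `truth.json`.
#' }
#'
#' @param dir Output directory (created).
#' @param seed Integer seed; the whole suite is reproducible from it.
#' @param noise_sd Log2-scale expression noise (default 0.4 = 10% of the
#'   profile amplitude).
#' @param promoter_length Promoter window used for motif
#'   planting/scrubbing and recorded in the config (default 1000).
#' @return Invisibly, a list with the `pipeline_config`, the truth list
#'   and all file paths.
#' @export
simulate_study <- function(dir, seed = 1L, noise_sd = 0.4,
                           promoter_length = 1000L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sts <- sprintf("sts%02d", 1:9)
  tfs <- c("tf_wrky1", "tf_myb1")
  fla <- c("ggt01", sprintf("fla%02d", 2:10))
  mid <- sprintf("mid%02d", 1:8)
  pathway <- c(sts, fla, mid)

  design <- simulation_design(
    modules = list(
      planted_module(c(sts, tfs, "lnc_sts"), "ripening_up"),
      planted_module(c(fla, "lnc_as"), "early_up"),
      planted_module(mid, "mid_peak")),
    n_background = 20, noise_sd = noise_sd, seed = seed)
  expr <- simulate_expression(design)
  bg <- attr(expr, "modules")$background
  expr_path <- file.path(dir, "expression.tsv")
  write_expression(expr, expr_path)

  gspec <- genome_spec(
    other_genes = list(chrom = "chr01",
                       gene_ids = c(fla[-1], mid, tfs, bg),
                       start = 5000, spacing = 3000, gene_length = 1500))
  planted_motif_genes <- c(sts, bg[1:2])
  gen <- simulate_genome(
    gspec, seed = seed + 10L, dir = dir,
    promoter_motif = list(iupac = "CCWACC",
                          planted_gene_ids = planted_motif_genes,
                          region = promoter_length))

  genes <- gen$features$id[gen$features$kind == "gene"]
  transcripts <- .with_seed(seed + 20L, {
    setNames(vapply(genes, function(g) .random_dna(300), character(1)),
             paste0(genes, ".t1"))
  })
  tx_path <- file.path(dir, "transcripts.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(transcripts),
                              tx_path)
  map <- data.frame(transcript_id = names(transcripts),
                    gene_id = genes, stringsAsFactors = FALSE)
  map_path <- file.path(dir, "transcript_map.tsv")
  write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)

  specs <- list(list(target = "fla02.t1", mm = 0L, wo = 0L),
                list(target = "mid01.t1", mm = 1L, wo = 0L),
                list(target = "sts02.t1", mm = 0L, wo = 1L))
  mirnas <- character(0)
  truth_rows <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    pair <- simulate_mirna_pairs(transcripts[s$target], n_pairs = 1,
                                 mismatches = s$mm, wobbles = s$wo,
                                 seed = seed + 30L + i)
    id <- sprintf("mir_%02d", i)
    mirnas[id] <- as.character(pair$mirnas[[1]])
    row <- pair$truth
    row$mirna_id <- id
    truth_rows[[i]] <- row
  }
  mirna_truth <- do.call(rbind, truth_rows)
  mir_path <- file.path(dir, "mirnas.fa")
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(mirnas), mir_path)
  truth_path <- file.path(dir, "mirna_truth.tsv")
  write.table(mirna_truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  motifs_path <- file.path(dir, "motifs.tsv")
  write_motifs(default_motifs(), motifs_path)
  tf_path <- file.path(dir, "tf_list.txt")
  writeLines(tfs, tf_path)
  pathway_path <- file.path(dir, "pathway_genes.txt")
  writeLines(pathway, pathway_path)

  config <- pipeline_config(
    expression = expr_path, features = gen$gff_path,
    genome = gen$fasta_path, transcripts = tx_path, mirnas = mir_path,
    transcript_map = map_path, motifs = motifs_path, tf_list = tf_path,
    pathway_genes = pathway_path, out_dir = file.path(dir, "out"),
    promoter_length = promoter_length, seed = seed)
  yaml_path <- file.path(dir, "pipeline.yaml")
  yaml::write_yaml(list(
    expression = "expression.tsv", features = "features.gff3",
    genome = "genome.fa", transcripts = "transcripts.fa",
    mirnas = "mirnas.fa", transcript_map = "transcript_map.tsv",
    motifs = "motifs.tsv", tf_list = "tf_list.txt",
    pathway_genes = "pathway_genes.txt", out_dir = "out",
    promoter_length = as.integer(promoter_length),
    seed = as.integer(seed)), yaml_path)

  truth <- list(
    modules = attr(expr, "modules"),
    tandem = list(lncrna = "lnc_sts", genes = sts),
    antisense = list(lncrna = "lnc_as", gene = "ggt01"),
    mirna_truth = mirna_truth,
    planted_motif = "MYB_CCWACC",
    planted_motif_genes = planted_motif_genes,
    tf_list = tfs, pathway = pathway)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = config, truth = truth, yaml = yaml_path,
                 dir = dir, features = gen$features))
}
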