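# phenolnet

Multilayer regulatory network construction for fruit secondary
metabolism, with grape berry phenylpropanoid/flavonoid/stilbene pathways
as the motivating case. The package is aimed at plant systems biologists
who want to move from a single co-expression network to an integrated,
typed regulatory graph — and at method developers who need a fully
synthetic, ground-truthed benchmark for each layer.

## What it computes

Four evidence layers are built and merged into one typed network:

1. **Signed gene co-expression network (GCN).** For genes *i*, *j* with
   abundance profiles across a multi-cultivar developmental series, an
   edge exists iff the Pearson correlation satisfies **|r(i,j)| > 0.8**
   (strict; computed on log2(x+1) abundances by default), keeping sign:
   positive edges mark co-regulation, negative edges the antagonism
   between ripening-specific and early-development genes.
2. **lncRNA–gene co-location.** A candidate pair requires the gene to
   intersect the lncRNA interval extended by a **100 kb** flanking
   window (0-based half-open arithmetic) *and* |r| > 0.8. lncRNAs are
   classified antisense (opposite-strand overlap), intergenic, or
   sense-overlapping.
3. **miRNA targets.** Each miRNA is slid over every transcript window
   and scored with a plant-style cumulative expectation penalty:
   Watson–Crick pair 0, G:U wobble 0.5, mismatch 1, doubled in the core
   region (miRNA positions 2–13); duplexes with expectation ≤ 3 are
   reported, and each (miRNA, gene) edge carries the minimum over the
   gene's transcripts.
4. **Promoter cis-regulatory elements.** Promoters (2 kb upstream by
   default) are scanned on both strands for IUPAC motifs (e.g. the
   R2R3-MYB site `CCWACC`, W = A/T); per-module over-representation is
   tested with the one-sided hypergeometric
   P(X ≥ k | N, K, n) and Benjamini–Hochberg FDR.

The merged graph types its nodes (enzyme gene / TF / lncRNA / miRNA) and
edges (positive/negative co-expression, TF→target co-expression,
miRNA→target, lncRNA co-location), supports pathway-focused subnetwork
extraction with one-hop regulators, reproducible module detection on the
positive-edge backbone, per-type degree centrality, and
Cytoscape-compatible export (GraphML, SIF, TSV).

A synthetic-data module generates every input with planted, recoverable
structure: a 5-cultivar × 4-stage expression design with correlated
modules of both signs, a pseudo-chromosome carrying a 9-paralog tandem
cluster with an adjacent intergenic lncRNA and an antisense lncRNA/gene
pair, promoters with motifs planted at controlled frequencies, and
miRNA/target pairs with controlled mismatch and wobble counts.

## Worked example

```r
library(phenolnet)

study <- simulate_study("study", seed = 42)   # writes all inputs + pipeline.yaml
res   <- run_pipeline(study$config)           # gcn -> colocation -> mirna -> cre -> integrate

res$network
#> multilayer_network: 34 nodes, 251 edges
#>
#> enzyme_gene      lncRNA       miRNA          TF
#>          27           2           3           2
#>
#>  coexpression_neg  coexpression_pos lncrna_colocation      mirna_target
#>                90               110                10                 3
#>   tf_coexpression
#>                38
```

The intergenic lncRNA planted 20 kb upstream of the tandem cluster is
linked to the cluster genes by co-location plus strong co-expression:

```r
head(res$lnc_edges[res$lnc_edges$lncrna_id == "lnc_sts", ], 3)
#>   lncrna_id gene_id distance_bp   relation         r
#> 2   lnc_sts   sts01       19000 intergenic 0.9713987
#> 3   lnc_sts   sts02       26000 intergenic 0.9322169
#> 4   lnc_sts   sts03       33000 intergenic 0.9637207
```

(9 such edges in total — one per cluster gene; `distance_bp` is the gap
between the lncRNA and each successive paralog.) The motif planted in
the cluster promoters is the top-ranked enrichment: module M03 holds the
nine cluster genes plus two TFs (n = 11), nine of which carry the MYB
site (k = 9):

```r
head(res$enrichment[, c("module_id", "motif_name", "k", "n", "p_value", "fdr")], 3)
#>   module_id motif_name k  n      p_value          fdr
#> 1       M03 MYB_CCWACC 9 11 1.341437e-06 2.012156e-05
#> 2       M02 ERF_GCCbox 5  8 4.657207e-02 3.492905e-01
#> 3       M01  WRKY_Wbox 8 10 2.890952e-01 1.000000e+00
```

Degree centrality on the pathway subnetwork flags the hubs; every
tandem-cluster gene carries its lncRNA co-location edge and two TF
edges:

```r
cr <- centrality_report(res$subnetwork)
head(cr[, c("id", "node_type", "tf_coexpression", "lncrna_colocation", "total")], 5)
#>      id   node_type tf_coexpression lncrna_colocation total
#> 1 sts02 enzyme_gene               2                 1    22
#> 2 fla02 enzyme_gene               2                 0    21
#> 3 ggt01 enzyme_gene               2                 1    21
#> 4 sts01 enzyme_gene               2                 1    21
#> 5 sts03 enzyme_gene               2                 1    21
```

Every stage is also callable on its own (`load_expression()`,
`compute_pcc_matrix()`, `build_network()`, `parse_features()`,
`lncrna_edges()`, `predict_targets()`, `scan_motif()`,
`enrich_modules()`, `assemble_network()`, ...); see the methods
vignette (`vignettes/phenolnet-methods.Rmd`) for the model, parameter
rationale and limitations.

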