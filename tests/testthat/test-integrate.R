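# Multilayer assembly, subnetwork extraction, module detection, degree
# centrality and export round-trips.

toy_layers <- function() {
  gcn <- data.frame(
    gene_a = c("A", "A", "B", "T1", "C"),
    gene_b = c("B", "C", "C", "A", "D"),
    r = c(0.9, 0.85, 0.95, 0.88, -0.9),
    sign = c("positive", "positive", "positive", "positive", "negative"))
  lnc <- data.frame(lncrna_id = "L1", gene_id = c("A", "B"),
                    distance_bp = c(1000L, 5000L), relation = "intergenic",
                    r = c(0.91, 0.86))
  mir <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("C", "C"),
                    expectation = c(0.5, 2))
  list(gcn = gcn, lnc = lnc, mir = mir)
}

test_that("assembly conserves edges and re-types TF co-expression", {
  ly <- toy_layers()
  net <- assemble_network(ly$gcn, tf_list = "T1", ly$lnc, ly$mir)
  expect_equal(nrow(net$edges), 5 + 2 + 2)
  expect_equal(sum(net$edges$edge_type == "tf_coexpression"), 1)
  tf_edge <- net$edges[net$edges$edge_type == "tf_coexpression", ]
  # directed regulator -> target even though the pair sorts as (A, T1)
  expect_equal(tf_edge$from, "T1")
  expect_equal(tf_edge$to, "A")
  expect_true(tf_edge$directed)
  expect_equal(sum(net$edges$edge_type == "coexpression_neg"), 1)
  expect_equal(net$nodes$node_type[net$nodes$id == "L1"], "lncRNA")
  expect_equal(net$nodes$node_type[net$nodes$id == "m1"], "miRNA")
  expect_equal(net$nodes$lncrna_relation[net$nodes$id == "L1"],
               "intergenic")
  expect_true(any(grepl("re-typed 1", net$log)))

  # empty layers give a valid empty network
  e0 <- assemble_network(ly$gcn[0, ], character(0))
  expect_s3_class(e0, "multilayer_network")
  expect_equal(nrow(e0$edges), 0)
})

test_that("id collisions across layers are namespaced", {
  gcn <- data.frame(gene_a = "A", gene_b = "B", r = 0.9, sign = "positive")
  lnc <- data.frame(lncrna_id = "A", gene_id = "B", distance_bp = 0L,
                    relation = "antisense", r = 0.85)
  net <- assemble_network(gcn, character(0), lnc)
  expect_true("lncrna:A" %in% net$nodes$id)
  expect_equal(net$nodes$node_type[net$nodes$id == "A"], "enzyme_gene")
  expect_true(any(grepl("prefixed", net$log)))
})

test_that("subnetwork extraction honours include_regulators", {
  ly <- toy_layers()
  net <- assemble_network(ly$gcn, tf_list = "T1", ly$lnc, ly$mir)
  sub <- extract_subnetwork(net, c("A", "B"), include_regulators = TRUE)
  expect_setequal(sub$nodes$id, c("A", "B", "T1", "L1"))
  sub2 <- extract_subnetwork(net, c("A", "B"), include_regulators = FALSE)
  expect_setequal(sub2$nodes$id, c("A", "B"))
  expect_equal(sub2$edges$edge_type, "coexpression_pos")
  expect_warning(extract_subnetwork(net, c("A", "ghost")), "not in the")
})

test_that("modules form on positive edges only, deterministically", {
  # two positive cliques joined only by negative edges -> 2 modules
  pos <- expand.grid(a = c("p1", "p2", "p3"), b = c("p1", "p2", "p3"))
  pos <- pos[as.character(pos$a) < as.character(pos$b), ]
  cliq1 <- data.frame(gene_a = as.character(pos$a),
                      gene_b = as.character(pos$b), r = 0.9,
                      sign = "positive")
  cliq2 <- cliq1
  cliq2$gene_a <- sub("p", "q", cliq2$gene_a)
  cliq2$gene_b <- sub("p", "q", cliq2$gene_b)
  bridge <- data.frame(gene_a = "p1", gene_b = "q1", r = -0.9,
                       sign = "negative")
  net <- assemble_network(rbind(cliq1, cliq2, bridge), character(0))
  part <- detect_modules(net, "components")
  expect_equal(length(unique(part)), 2)
  expect_length(unique(part[c("p1", "p2", "p3")]), 1)
  expect_length(unique(part[c("q1", "q2", "q3")]), 1)

  # single positive clique -> 1 module
  net1 <- assemble_network(cliq1, character(0))
  expect_equal(length(unique(detect_modules(net1, "components"))), 1)

  # greedy modularity agrees on this clean two-clique case
  partg <- detect_modules(net, "greedy")
  expect_equal(length(unique(partg)), 2)

  expect_error(detect_modules(net, "spectral"), "arg")
})

test_that("planted modules are recovered with high adjusted Rand index", {
  aris <- vapply(1:20, function(seed) {
    m <- simulate_expression(default_design(seed = seed))
    truth_list <- attr(m, "modules")
    edges <- build_network(compute_pcc_matrix(m), network_config(0.8))
    net <- assemble_network(edges, character(0))
    part <- detect_modules(net, "components")
    planted <- unlist(truth_list[names(truth_list) != "background"])
    truth_lab <- rep(names(truth_list)[names(truth_list) != "background"],
                     lengths(truth_list[names(truth_list) != "background"]))
    keep <- planted %in% names(part)
    mclust::adjustedRandIndex(truth_lab[keep], part[planted[keep]])
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("degree report counts endpoints per edge type", {
  ly <- toy_layers()
  net <- assemble_network(ly$gcn, tf_list = "T1", ly$lnc, ly$mir)
  # add an isolated node through the TF list
  net2 <- assemble_network(ly$gcn, tf_list = c("T1", "T_alone"),
                           ly$lnc, ly$mir)
  cr <- centrality_report(net2)
  expect_equal(cr$total[cr$id == "T_alone"], 0)
  expect_equal(cr$lncrna_colocation[cr$id == "L1"], 2)
  # handshake: the grand total is twice the edge count
  expect_equal(sum(cr$total), 2 * nrow(net2$edges))
  # sorted by decreasing total, ties lexicographic
  expect_true(all(diff(cr$total) <= 0))
})

test_that("a 9-member tandem cluster gives its lncRNA degree 9", {
  res <- cached_study()$res
  cr <- centrality_report(res$subnetwork)
  expect_equal(cr$lncrna_colocation[cr$id == "lnc_sts"], 9)
  expect_true("lnc_sts" %in% res$subnetwork$nodes$id)
})

test_that("GraphML and TSV exports round-trip nodes, edges, attributes", {
  ly <- toy_layers()
  net <- assemble_network(ly$gcn, tf_list = "T1", ly$lnc, ly$mir,
                          annotations = list(
                            pathway_genes = c("A", "B", "C"),
                            motif_presence = matrix(
                              c(TRUE, FALSE), 2, 1,
                              dimnames = list(c("A", "B"), "MYB"))))
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "net.graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_equal(back$nodes$id, net$nodes$id)
  expect_equal(back$nodes$node_type, net$nodes$node_type)
  expect_equal(back$nodes$in_pathway, net$nodes$in_pathway)
  expect_equal(back$nodes$motif_MYB, net$nodes$motif_MYB)
  expect_equal(back$edges[, c("from", "to", "edge_type", "directed")],
               net$edges[, c("from", "to", "edge_type", "directed")])
  expect_equal(back$edges$weight, net$edges$weight)

  pre <- file.path(dir, "net")
  export_network(net, pre, "tsv")
  back2 <- import_network(pre, "tsv")
  expect_equal(back2$edges[, c("from", "to", "edge_type")],
               net$edges[, c("from", "to", "edge_type")])

  # SIF uses the edge type as interaction token
  sif <- file.path(dir, "net.sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_true("m1\tmirna_target\tC" %in% lines)
  expect_length(lines, nrow(net$edges))

  # empty network exports valid (empty) files
  e0 <- assemble_network(ly$gcn[0, ], character(0))
  export_network(e0, file.path(dir, "empty.sif"), "sif")
  expect_length(readLines(file.path(dir, "empty.sif")), 0)
  expect_error(export_network(net, gml, "gexf"), "arg")
})
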