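# Multilayer network assembly and analysis: typed nodes (enzyme_gene, TF,
# lncRNA, miRNA), typed edges (coexpression_pos/neg, tf_coexpression,
# mirna_target, lncrna_colocation), pathway subnetwork extraction, module
# detection, degree centrality and Cytoscape-compatible export.

EDGE_TYPES <- c("coexpression_pos", "coexpression_neg", "tf_coexpression",
                "mirna_target", "lncrna_colocation")
NODE_TYPES <- c("enzyme_gene", "TF", "lncRNA", "miRNA")

.empty_nodes <- function() {
  data.frame(id = character(0), node_type = character(0),
             in_pathway = logical(0), lncrna_relation = character(0),
             stringsAsFactors = FALSE)
}

.empty_mlnet_edges <- function() {
  data.frame(from = character(0), to = character(0),
             edge_type = character(0), weight = numeric(0),
             directed = logical(0), stringsAsFactors = FALSE)
}

.new_mlnet <- function(nodes, edges, log = character(0)) {
  stopifnot(all(edges$edge_type %in% EDGE_TYPES))
  missing <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing)) {
    .stopf("edge endpoint(s) absent from node table: %s",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges, log = log),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("multilayer_network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$nodes)) print(table(x$nodes$node_type))
  if (nrow(x$edges)) print(table(x$edges$edge_type))
  invisible(x)
}

# canonical order for an undirected pair
.pair_sorted <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(a = a, b = b)
}

#' Assemble the multilayer regulatory network
#'
#' Merges the co-expression layer, the lncRNA co-location layer and the
#' miRNA target layer into one typed graph.  Node types: genes in
#' `tf_list` become `TF`, lncRNA/miRNA endpoints take their layer's type,
#' everything else is `enzyme_gene`.  Gene-gene co-expression edges with
#' exactly one TF endpoint are re-typed `tf_coexpression` and directed
#' TF -> target (the symmetric co-expression view is recoverable from the
#' `directed` flag); TF-TF pairs stay undirected co-expression.  No edge
#' is silently dropped: every re-typing or id-namespace adjustment is
#' appended to the network's `log`.
#'
#' Identifier collisions across layers (one id used by two node types)
#' are resolved by prefixing the colliding lncRNA/miRNA ids with
#' `lncrna:` / `mirna:`.
#'
#' @param gcn_edges Data frame from [build_network()] (gene_a, gene_b, r,
#'   sign).
#' @param tf_list Character vector of TF gene ids (may be empty).
#' @param lnc_edges Data frame from [lncrna_edges()], or `NULL`.
#' @param mir_edges Data frame from [mirna_edges()], or `NULL`.
#' @param annotations Optional list: `motif_presence` (logical
#'   genes-by-motifs matrix; becomes `motif_<name>` node attributes),
#'   `pathway_genes` (character; sets `in_pathway`).
#' @return A `multilayer_network` (list with `nodes`, `edges`, `log`).
#' @export
assemble_network <- function(gcn_edges, tf_list = character(0),
                             lnc_edges = NULL, mir_edges = NULL,
                             annotations = list()) {
  log <- character(0)
  edges <- list()

  if (!is.null(gcn_edges) && nrow(gcn_edges)) {
    p <- .pair_sorted(gcn_edges$gene_a, gcn_edges$gene_b)
    a <- p$a; b <- p$b; r <- gcn_edges$r
    a_tf <- a %in% tf_list
    b_tf <- b %in% tf_list
    one_tf <- xor(a_tf, b_tf)
    from <- ifelse(one_tf & b_tf, b, a)
    to <- ifelse(one_tf & b_tf, a, b)
    type <- ifelse(one_tf, "tf_coexpression",
                   ifelse(r > 0, "coexpression_pos", "coexpression_neg"))
    if (any(one_tf)) {
      log <- c(log, sprintf(
        "re-typed %d co-expression edge(s) with one TF endpoint as tf_coexpression",
        sum(one_tf)))
    }
    edges$gcn <- data.frame(from = from, to = to, edge_type = type,
                            weight = r, directed = one_tf,
                            stringsAsFactors = FALSE)
  }
  lnc_ids <- character(0)
  lnc_relation <- character(0)
  if (!is.null(lnc_edges) && nrow(lnc_edges)) {
    edges$lnc <- data.frame(from = lnc_edges$lncrna_id,
                            to = lnc_edges$gene_id,
                            edge_type = "lncrna_colocation",
                            weight = lnc_edges$r, directed = FALSE,
                            stringsAsFactors = FALSE)
    lnc_ids <- unique(lnc_edges$lncrna_id)
    lnc_relation <- vapply(lnc_ids, function(i) {
      lnc_edges$relation[lnc_edges$lncrna_id == i][1]
    }, character(1))
  }
  mir_ids <- character(0)
  if (!is.null(mir_edges) && nrow(mir_edges)) {
    edges$mir <- data.frame(from = mir_edges$mirna_id,
                            to = mir_edges$gene_id,
                            edge_type = "mirna_target",
                            weight = mir_edges$expectation, directed = TRUE,
                            stringsAsFactors = FALSE)
    mir_ids <- unique(mir_edges$mirna_id)
  }
  edges <- if (length(edges)) {
    do.call(rbind, unname(edges))
  } else {
    .empty_mlnet_edges()
  }

  # ids used on the gene side of any layer (co-expression endpoints,
  # colocation/miRNA targets, the TF list)
  gcn_rows <- edges$edge_type %in% c("coexpression_pos", "coexpression_neg",
                                     "tf_coexpression")
  gene_side <- unique(c(edges$from[gcn_rows], edges$to[gcn_rows],
                        edges$to[!gcn_rows], tf_list))
  # resolve id collisions across layers by namespace prefix
  for (cid in intersect(lnc_ids, gene_side)) {
    new <- paste0("lncrna:", cid)
    sel <- edges$edge_type == "lncrna_colocation" & edges$from == cid
    edges$from[sel] <- new
    lnc_ids[lnc_ids == cid] <- new
    names(lnc_relation)[names(lnc_relation) == cid] <- new
    log <- c(log, sprintf("prefixed colliding id %s as %s", cid, new))
  }
  for (cid in intersect(mir_ids, gene_side)) {
    new <- paste0("mirna:", cid)
    sel <- edges$edge_type == "mirna_target" & edges$from == cid
    edges$from[sel] <- new
    mir_ids[mir_ids == cid] <- new
    log <- c(log, sprintf("prefixed colliding id %s as %s", cid, new))
  }

  all_ids <- unique(c(edges$from, edges$to, tf_list))
  node_type <- rep("enzyme_gene", length(all_ids))
  node_type[all_ids %in% tf_list] <- "TF"
  node_type[all_ids %in% lnc_ids] <- "lncRNA"
  node_type[all_ids %in% mir_ids] <- "miRNA"
  nodes <- data.frame(id = all_ids, node_type = node_type,
                      in_pathway = logical(length(all_ids)),
                      lncrna_relation = character(length(all_ids)),
                      stringsAsFactors = FALSE)
  nodes$lncrna_relation[match(names(lnc_relation), nodes$id)] <-
    unname(lnc_relation)

  if (!is.null(annotations$pathway_genes)) {
    nodes$in_pathway <- nodes$id %in% annotations$pathway_genes
  }
  if (!is.null(annotations$motif_presence)) {
    mp <- annotations$motif_presence
    for (motif in colnames(mp)) {
      col <- paste0("motif_", motif)
      nodes[[col]] <- FALSE
      hit <- nodes$id %in% rownames(mp)[mp[, motif]]
      nodes[[col]][hit] <- TRUE
    }
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(edges$edge_type, edges$from, edges$to), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  .new_mlnet(nodes, edges, log)
}

#' Pathway-focused subnetwork
#'
#' Induces the subgraph on the pathway genes; with
#' `include_regulators = TRUE` (default) every TF, lncRNA and miRNA node
#' with at least one edge to a pathway gene is added, together with those
#' regulator-pathway edges.
#'
#' @param net A `multilayer_network`.
#' @param pathway_genes Character vector of pathway gene ids; ids absent
#'   from the network are warned about.
#' @param include_regulators Logical.
#' @return A `multilayer_network`.
#' @export
extract_subnetwork <- function(net, pathway_genes,
                               include_regulators = TRUE) {
  stopifnot(inherits(net, "multilayer_network"))
  missing <- setdiff(pathway_genes, net$nodes$id)
  if (length(missing)) {
    .warnf("%d pathway gene(s) not in the network (e.g. %s)",
           length(missing), missing[1])
  }
  pg <- intersect(pathway_genes, net$nodes$id)
  e <- net$edges
  within <- e$from %in% pg & e$to %in% pg
  keep_edges <- within
  keep_nodes <- pg
  if (include_regulators) {
    reg_ids <- net$nodes$id[net$nodes$node_type %in%
                              c("TF", "lncRNA", "miRNA")]
    touch <- (e$from %in% reg_ids & e$to %in% pg) |
      (e$to %in% reg_ids & e$from %in% pg)
    keep_edges <- keep_edges | touch
    keep_nodes <- union(pg, intersect(reg_ids,
                                      c(e$from[touch], e$to[touch])))
  }
  nodes <- net$nodes[net$nodes$id %in% keep_nodes, , drop = FALSE]
  edges <- e[keep_edges, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  .new_mlnet(nodes, edges,
             c(net$log, sprintf("subnetwork: %d pathway gene(s), regulators %s",
                                length(pg),
                                if (include_regulators) "included" else "excluded")))
}

#' Convert to an igraph object
#'
#' @param net A `multilayer_network`.
#' @param edge_types Optional subset of edge types to keep.
#' @param directed Build a directed graph (undirected edges are stored
#'   once; default `FALSE` gives the undirected view).
#' @return An [igraph::graph] with all node and edge attributes.
#' @export
as_igraph <- function(net, edge_types = NULL, directed = FALSE) {
  e <- net$edges
  if (!is.null(edge_types)) e <- e[e$edge_type %in% edge_types, , drop = FALSE]
  igraph::graph_from_data_frame(e, directed = directed,
                                vertices = net$nodes)
}

#' Detect modules on the positive co-expression backbone
#'
#' Negative co-expression edges are excluded from module formation (they
#' act as between-module links); positive gene-gene and TF co-expression
#' edges define the backbone.  Methods: `"components"` (connected
#' components of the positive backbone; the default) or `"greedy"`
#' (greedy modularity maximisation on `|weight|`).  Labels are
#' deterministic: modules are numbered by their lexicographically
#' smallest member, every node (including isolated ones) is labelled.
#'
#' @param net A `multilayer_network`.
#' @param method `"components"` or `"greedy"`.
#' @param seed Integer seed (recorded; both methods are deterministic).
#' @return Named character vector node id -> module label, with
#'   attributes `method` and `seed`.
#' @export
detect_modules <- function(net, method = c("components", "greedy"),
                           seed = 1L) {
  method <- match.arg(method)
  pos_types <- c("coexpression_pos", "tf_coexpression")
  e <- net$edges
  keep <- e$edge_type %in% pos_types & e$weight > 0
  sub <- net
  sub$edges <- e[keep, , drop = FALSE]
  g <- as_igraph(sub, directed = FALSE)
  membership <- .with_seed(seed, {
    if (method == "components") {
      igraph::components(g)$membership
    } else {
      gs <- igraph::simplify(
        g, edge.attr.comb = list(weight = function(w) max(abs(w)), "ignore"))
      igraph::E(gs)$weight <- abs(igraph::E(gs)$weight)
      igraph::membership(igraph::cluster_fast_greedy(gs))
    }
  })
  ids <- names(membership)
  # deterministic relabelling by smallest member id
  reps <- tapply(ids, membership, min)
  ord <- order(unname(reps))
  relabel <- setNames(sprintf("M%02d", seq_along(ord)), names(reps)[ord])
  out <- setNames(unname(relabel[as.character(membership)]), ids)
  out <- out[order(names(out))]
  attr(out, "method") <- method
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Per-type and total degree report
#'
#' Degrees count edge endpoints: an undirected edge adds 1 to each
#' endpoint, a directed edge adds 1 to its source (out) and 1 to its
#' target (in), so the grand total is twice the edge count.  High-degree
#' nodes flag hub/"switch" regulator candidates.
#'
#' @param net A `multilayer_network`.
#' @return Data frame: id, node_type, one column per edge type, total;
#'   sorted by decreasing total then id.
#' @export
centrality_report <- function(net) {
  nodes <- net$nodes
  out <- data.frame(id = nodes$id, node_type = nodes$node_type,
                    stringsAsFactors = FALSE)
  for (et in EDGE_TYPES) {
    e <- net$edges[net$edges$edge_type == et, , drop = FALSE]
    cnt <- table(factor(c(e$from, e$to), levels = nodes$id))
    out[[et]] <- as.integer(cnt[nodes$id])
  }
  out$total <- rowSums(out[, EDGE_TYPES, drop = FALSE])
  out <- out[order(-out$total, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export / import a multilayer network
#'
#' Formats: `"graphml"` (single file, round-trips all attributes),
#' `"sif"` (one line per edge, `from <TAB> edge_type <TAB> to`), `"tsv"`
#' (two files, `<path>_nodes.tsv` and `<path>_edges.tsv`).
#'
#' @param net A `multilayer_network`.
#' @param path Output file path (for `"tsv"`, the common prefix).
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(net, directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$edge_type,
                     net$edges$to)
    writeLines(lines, path)
  } else {
    write.table(net$nodes, paste0(path, "_nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(net$edges, paste0(path, "_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    v <- igraph::as_data_frame(g, what = "vertices")
    e <- igraph::as_data_frame(g, what = "edges")
    nodes <- data.frame(id = v$name, v[, setdiff(names(v), c("name", "id")),
                                       drop = FALSE],
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = e$from, to = e$to,
                        e[, setdiff(names(e), c("from", "to")), drop = FALSE],
                        stringsAsFactors = FALSE)
  } else {
    nodes <- read.delim(paste0(path, "_nodes.tsv"),
                        stringsAsFactors = FALSE)
    edges <- read.delim(paste0(path, "_edges.tsv"),
                        stringsAsFactors = FALSE)
  }
  for (col in intersect(c("in_pathway", "directed"), names(nodes))) {
    nodes[[col]] <- as.logical(nodes[[col]])
  }
  for (col in grep("^motif_", names(nodes), value = TRUE)) {
    nodes[[col]] <- as.logical(nodes[[col]])
  }
  if ("directed" %in% names(edges)) {
    edges$directed <- as.logical(edges$directed)
  }
  if ("lncrna_relation" %in% names(nodes)) {
    nodes$lncrna_relation[is.na(nodes$lncrna_relation)] <- ""
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$edge_type, edges$from, edges$to), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  .new_mlnet(nodes, edges)
}
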