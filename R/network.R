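# Regulatory network assembly and serialization.

#' Assemble the regulatory network
#'
#' Builds the typed metabolite / gene / TF / miRNA network from the
#' enrichment results: for each enriched metabolite, edges to its
#' differentially expressed metabolic genes (evidence
#' `"pathway_membership"`, upgraded to `"correlation"` for genes that also
#' passed the correlation filter), miRNA-to-gene edges from the overlay
#' (evidence `"mirna_target"`), and optional TF-to-gene edges from a
#' TF-target table (evidence `"tf_target"`). Genes on the TF list are
#' typed `tf`. Node direction (up/down at T1) comes from the DE sign for
#' genes and miRNAs and from the supplied metabolite directions (e.g.
#' OPLS loading signs).
#'
#' @param enriched [enrich_metabolites()] result (uses the enriched rows
#'   and the stored correlation sets).
#' @param db a [pathway_db()].
#' @param de_genes,de_mirnas [paired_de_test()] results.
#' @param mirna_edges [mirna_overlay()] result.
#' @param tf_list character vector of TF gene ids.
#' @param metabolite_direction optional named vector (`"up"`/`"down"`) per
#'   metabolite.
#' @param tf_targets optional data frame `tf_id`, `gene_id` of TF-target
#'   evidence.
#' @return object of class `regulatory_network`: `nodes` (`id`, `kind`,
#'   `direction`) and `edges` (`source`, `target`, `evidence`).
#' @export
assemble_network <- function(enriched, db, de_genes, de_mirnas,
                             mirna_edges = NULL, tf_list = character(0),
                             metabolite_direction = NULL,
                             tf_targets = NULL) {
  cors <- attr(enriched, "correlations")
  sel <- enriched$metabolite[enriched$enriched]
  sig_genes <- de_genes$feature_id[de_genes$significant]
  edges <- list()
  genes <- character(0)
  for (m in sel) {
    mg <- suppressWarnings(metabolic_genes_for(m, db))
    mg_de <- intersect(mg, sig_genes)
    if (length(mg_de) == 0L) next
    corset <- if (!is.null(cors[[m]])) cors[[m]]$gene else character(0)
    ev <- ifelse(mg_de %in% corset, "correlation", "pathway_membership")
    edges[[length(edges) + 1L]] <-
      data.frame(source = m, target = mg_de, evidence = ev)
    genes <- union(genes, mg_de)
  }
  mirnas <- character(0)
  if (!is.null(mirna_edges) && nrow(mirna_edges)) {
    me <- mirna_edges[mirna_edges$gene %in% genes, , drop = FALSE]
    if (nrow(me)) {
      edges[[length(edges) + 1L]] <-
        data.frame(source = me$mirna, target = me$gene,
                   evidence = "mirna_target")
      mirnas <- unique(me$mirna)
    }
  }
  if (!is.null(tf_targets) && nrow(tf_targets)) {
    tt <- tf_targets[tf_targets$tf_id %in% intersect(tf_list, genes) &
                       tf_targets$gene_id %in% genes, , drop = FALSE]
    if (nrow(tt))
      edges[[length(edges) + 1L]] <-
        data.frame(source = tt$tf_id, target = tt$gene_id,
                   evidence = "tf_target")
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               evidence = character(0))
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  rownames(edges) <- NULL
  ids <- unique(c(intersect(sel, edges$source), genes, mirnas))
  if (length(intersect(intersect(sel, genes), mirnas)))
    stop("id collision across node kinds")
  kind <- ifelse(ids %in% mirnas, "mirna",
                 ifelse(ids %in% genes,
                        ifelse(ids %in% tf_list, "tf", "gene"),
                        "metabolite"))
  dir_of <- function(id, k) {
    if (k %in% c("gene", "tf")) {
      i <- match(id, de_genes$feature_id)
      if (!is.na(i)) return(de_genes$direction[i])
    } else if (k == "mirna") {
      i <- match(id, de_mirnas$feature_id)
      if (!is.na(i)) return(de_mirnas$direction[i])
    } else if (!is.null(metabolite_direction) && id %in% names(metabolite_direction)) {
      return(metabolite_direction[[id]])
    }
    NA_character_
  }
  direction <- mapply(dir_of, ids, kind, USE.NAMES = FALSE)
  direction[direction == "over"] <- "up"
  direction[direction == "under"] <- "down"
  structure(list(nodes = data.frame(id = ids, kind = kind,
                                    direction = direction, row.names = NULL),
                 edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  kt <- table(factor(x$nodes$kind,
                     levels = c("metabolite", "gene", "tf", "mirna")))
  cat("regulatory network:", nrow(x$nodes), "nodes (",
      paste(names(kt), kt, sep = ": ", collapse = ", "), "),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a regulatory network to an igraph object
#' @param net a `regulatory_network`.
#' @return a directed `igraph` graph with `kind`/`direction` vertex and
#'   `evidence` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Export a regulatory network
#'
#' GraphML keeps all node and edge attributes; SIF writes
#' `source<TAB>evidence<TAB>target` lines.
#'
#' @param net a `regulatory_network`.
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @export
write_network <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    writeLines(paste(net$edges$source, net$edges$evidence, net$edges$target,
                     sep = "\t"), path)
  }
  invisible(path)
}

#' Read a GraphML regulatory network
#' @param path GraphML file written by [write_network()].
#' @return a `regulatory_network`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      kind = igraph::V(g)$kind,
                      direction = igraph::V(g)$direction,
                      row.names = NULL)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      evidence = igraph::E(g)$evidence, row.names = NULL)
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}
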