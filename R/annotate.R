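#' Module significance of an annotation term
#'
#' The product of the average module membership (kME to the gene's own
#' module eigengene) over the term's genes that lie inside the module,
#' and one minus the term's enrichment p-value — so terms annotating
#' intramodular hubs with strong enrichment score highest.
#'
#' @param term_genes Character vector of the term's annotated genes.
#' @param p_value Term enrichment p-value in \[0, 1\].
#' @param module_genes Character vector of the module's genes.
#' @param kme_own Named numeric vector of each gene's kME to its own
#'   module eigengene (names are gene ids).
#' @return `mean(kME) * (1 - p)`, or `NA` if no annotated gene is in the
#'   module.
#' @export
module_significance <- function(term_genes, p_value, module_genes, kme_own) {
  stopifnot(p_value >= 0, p_value <= 1)
  inside <- intersect(term_genes, module_genes)
  if (length(inside) == 0) return(NA_real_)
  mean(kme_own[inside], na.rm = TRUE) * (1 - p_value)
}

#' Term significance for a behavioral trait
#'
#' Weights the module significance score by the mean gene significance of
#' the term's in-module genes for a chosen trait (absolute value by
#' default, so strong negative correlates are not penalized).
#'
#' @inheritParams module_significance
#' @param gs_trait Named numeric vector of gene significances for one
#'   trait.
#' @param signed Use the signed mean of GS instead of the mean |GS|?
#' @return `MS * mean(|GS|)` over the annotated in-module genes, or `NA`.
#' @export
term_significance <- function(term_genes, p_value, module_genes, kme_own,
                              gs_trait, signed = FALSE) {
  ms <- module_significance(term_genes, p_value, module_genes, kme_own)
  if (is.na(ms)) return(NA_real_)
  inside <- intersect(term_genes, module_genes)
  g <- gs_trait[inside]
  w <- if (signed) mean(g, na.rm = TRUE) else mean(abs(g), na.rm = TRUE)
  ms * w
}

#' Score all terms against all modules of a network
#'
#' Tabular front end to [module_significance()] and
#' [term_significance()].
#'
#' @param terms Annotation tibble with `term_id`, `p_value`, and a
#'   list-column `genes` (as produced by [simulate_annotations()]).
#' @param network A `coexpression_network` (or its `modules` tibble with
#'   `gene_id`, `module`, `kme`).
#' @param gs Gene-significance tibble from [gene_significance()]; optional.
#' @param trait Trait column of `gs` to weight term significance by.
#' @param signed Passed to [term_significance()].
#' @return Tibble: `term_id`, `module`, `n_genes_in_module`,
#'   `module_significance`, and `term_significance` when `gs` is given.
#' @export
score_terms <- function(terms, network, gs = NULL, trait = NULL, signed = FALSE) {
  mods_tbl <- if (inherits(network, "coexpression_network")) network$modules else network
  kme_own <- stats::setNames(mods_tbl$kme, mods_tbl$gene_id)
  gs_vec <- NULL
  if (!is.null(gs)) {
    stopifnot(!is.null(trait), trait %in% names(gs))
    gs_vec <- stats::setNames(gs[[trait]], gs$gene_id)
  }
  mods <- setdiff(unique(mods_tbl$module), "grey")
  rows <- purrr::map(seq_len(nrow(terms)), function(i) {
    tg <- terms$genes[[i]]
    purrr::map(mods, function(m) {
      mg <- mods_tbl$gene_id[mods_tbl$module == m]
      n_in <- length(intersect(tg, mg))
      if (n_in == 0) return(NULL)
      ms <- module_significance(tg, terms$p_value[i], mg, kme_own)
      out <- tibble::tibble(term_id = terms$term_id[i], module = m,
                            n_genes_in_module = n_in, module_significance = ms)
      if (!is.null(gs_vec)) {
        out$term_significance <- term_significance(tg, terms$p_value[i], mg,
                                                   kme_own, gs_vec, signed)
      }
      out
    }) %>% dplyr::bind_rows()
  })
  dplyr::bind_rows(rows) %>% dplyr::arrange(dplyr::desc(.data$module_significance))
}

#' Scale and rank high-confidence interactions
#'
#' Filters a confidence-scored gene-pair list to high-confidence edges
#' (confidence >= `min_confidence`, default 0.9) and ranks them under one
#' of four scaling metrics:
#' 1. `conf * kIN_i * kIN_j` — emphasizes hub-hub interactions;
#' 2. `conf * dk_i * dk_j` — differential connectivity between
#'    conditions, emphasizing juvenile-specific hubs;
#' 3. `conf * GS_i * GS_j` — behavior-correlated genes regardless of
#'    network position;
#' 4. `conf * (kIN_i GS_i) * (kIN_j GS_j)` — hubs that also track
#'    behavior.
#'
#' @param edges Tibble `gene_i`, `gene_j`, `confidence`.
#' @param stats Tibble keyed by `gene_id` with the columns the metric
#'   needs: `k_in` (metrics 1, 4), `delta_k` (metric 2), `gs`
#'   (metrics 3, 4).
#' @param metric Integer 1-4.
#' @param min_confidence Confidence floor applied before scaling.
#' @return Ranked tibble with a `score` column, sorted by descending
#'   score, ties broken lexicographically by gene pair.
#' @export
scale_interactions <- function(edges, stats, metric = 1, min_confidence = 0.9) {
  stopifnot(metric %in% 1:4)
  kept <- dplyr::filter(edges, .data$confidence >= min_confidence)
  need <- switch(metric, c("k_in"), c("delta_k"), c("gs"), c("k_in", "gs"))
  stopifnot(all(need %in% names(stats)))
  val <- function(col) stats::setNames(stats[[col]], stats$gene_id)
  node_score <- switch(
    metric,
    function(g) val("k_in")[g],
    function(g) val("delta_k")[g],
    function(g) val("gs")[g],
    function(g) val("k_in")[g] * val("gs")[g]
  )
  si <- node_score(kept$gene_i)
  sj <- node_score(kept$gene_j)
  missing <- is.na(si) | is.na(sj)
  if (any(missing)) {
    warning(sum(missing), " edge(s) dropped for missing node statistics")
    kept <- kept[!missing, , drop = FALSE]
    si <- si[!missing]
    sj <- sj[!missing]
  }
  kept$score <- unname(kept$confidence * si * sj)
  dplyr::arrange(kept, dplyr::desc(.data$score),
                 pmin(.data$gene_i, .data$gene_j),
                 pmax(.data$gene_i, .data$gene_j))
}

#' Keep only interactions that bridge two module classes
#'
#' Retains edges with one endpoint in each of two module sets (e.g.
#' learning-related vs song-production modules); edges within either
#' class are dropped.
#'
#' @param edges Tibble `gene_i`, `gene_j`, ....
#' @param labels Tibble (`gene_id`, `module`).
#' @param source_modules,target_modules Character vectors of module
#'   labels defining the two classes.
#' @return The cross-class edge subset.
#' @export
cross_module_filter <- function(edges, labels, source_modules, target_modules) {
  lab <- stats::setNames(labels$module, labels$gene_id)
  mi <- lab[edges$gene_i]
  mj <- lab[edges$gene_j]
  keep <- (mi %in% source_modules & mj %in% target_modules) |
    (mi %in% target_modules & mj %in% source_modules)
  keep[is.na(keep)] <- FALSE
  edges[keep, , drop = FALSE]
}

#' Edge width for network display
#'
#' The interaction confidence scaled by the product of the two endpoints'
#' intramodular connectivities (same functional form as scaling metric 1).
#'
#' @param conf Interaction confidence.
#' @param kin_i,kin_j Intramodular connectivities of the endpoints.
#' @return `conf * kin_i * kin_j`.
#' @export
edge_width <- function(conf, kin_i, kin_j) {
  stopifnot(all(conf >= 0), all(kin_i >= 0), all(kin_j >= 0))
  conf * kin_i * kin_j
}

#' Sparsify a weighted network for visualization
#'
#' The display workflow: retain the top `keep_fraction` of edges by
#' weight (ties at the cutoff all retained), drop nodes left with no
#' edges, then keep only the largest connected component (ties between
#' equal-size components go to the one containing the lexicographically
#' smallest node id).
#'
#' @param edges Tibble `gene_i`, `gene_j`, `weight`.
#' @param keep_fraction Fraction of edges to retain; default 0.02
#'   (i.e. remove <= 98% of edges).
#' @return Object of class `viz_graph`: list with `edges` and `nodes`
#'   tibbles.
#' @export
sparsify_for_viz <- function(edges, keep_fraction = 0.02) {
  stopifnot(all(c("gene_i", "gene_j", "weight") %in% names(edges)))
  n_keep <- max(1L, ceiling(keep_fraction * nrow(edges)))
  cutoff <- sort(edges$weight, decreasing = TRUE)[n_keep]
  kept <- dplyr::filter(edges, .data$weight >= cutoff)
  if (nrow(kept) == 0) {
    stop("no edges retained; increase keep_fraction", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    kept[, c("gene_i", "gene_j")], directed = FALSE)
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    firsts <- vapply(big, function(b) min(names(comp$membership)[comp$membership == b]),
                     character(1))
    big <- big[order(firsts)][1]
  }
  nodes <- sort(names(comp$membership)[comp$membership == big])
  out_edges <- dplyr::filter(kept, .data$gene_i %in% nodes & .data$gene_j %in% nodes)
  structure(list(
    edges = out_edges,
    nodes = tibble::tibble(
      gene_id = nodes,
      degree = as.integer(table(factor(c(out_edges$gene_i, out_edges$gene_j),
                                       levels = nodes)))
    ),
    keep_fraction = keep_fraction
  ), class = "viz_graph")
}

#' @export
print.viz_graph <- function(x, ...) {
  cat(sprintf("Visualization graph: %d nodes, %d edges (top %.1f%% of edges)\n",
              nrow(x$nodes), nrow(x$edges), 100 * x$keep_fraction))
  invisible(x)
}

#' @exportS3Method
autoplot.viz_graph <- function(object, labels = NULL, ...) {
  g <- igraph::graph_from_data_frame(object$edges[, c("gene_i", "gene_j")],
                                     directed = FALSE,
                                     vertices = object$nodes$gene_id)
  xy <- igraph::layout_with_fr(g)
  lay <- tibble::tibble(gene_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  if (!is.null(labels)) {
    lay <- dplyr::left_join(lay, labels, by = "gene_id")
  } else {
    lay$module <- "node"
  }
  seg <- object$edges %>%
    dplyr::left_join(dplyr::rename(lay[, c("gene_id", "x", "y")], xi = "x", yi = "y"),
                     by = c(gene_i = "gene_id")) %>%
    dplyr::left_join(dplyr::rename(lay[, c("gene_id", "x", "y")], xj = "x", yj = "y"),
                     by = c(gene_j = "gene_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xi, y = .data$yi,
                                       xend = .data$xj, yend = .data$yj,
                                       linewidth = .data$weight),
                          color = "grey70", alpha = 0.6) +
    ggplot2::scale_linewidth(range = c(0.1, 1.2), guide = "none") +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y, color = .data$module),
                        size = 2) +
    ggplot2::theme_void()
}

#' Export a visualization graph as GEXF XML
#'
#' Minimal GEXF 1.2 writer for downstream interactive plotting tools;
#' node sizes carry degree and edge weights the supplied weight column.
#'
#' @param graph A `viz_graph` from [sparsify_for_viz()].
#' @param path Output file path.
#' @param labels Optional tibble (`gene_id`, `module`) to color nodes by.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(graph, path, labels = NULL) {
  nodes <- graph$nodes
  mod <- if (!is.null(labels)) {
    stats::setNames(labels$module, labels$gene_id)[nodes$gene_id]
  } else rep("", nrow(nodes))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  node_xml <- sprintf(
    '      <node id="%s" label="%s"><viz:size value="%d"/><attvalues><attvalue for="0" value="%s"/></attvalues></node>',
    esc(nodes$gene_id), esc(nodes$gene_id), nodes$degree, esc(mod))
  edge_xml <- sprintf(
    '      <edge id="%d" source="%s" target="%s" weight="%g"/>',
    seq_len(nrow(graph$edges)) - 1L, esc(graph$edges$gene_i),
    esc(graph$edges$gene_j), graph$edges$weight)
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" xmlns:viz="http://www.gexf.net/1.2draft/viz" version="1.2">',
    '  <graph mode="static" defaultedgetype="undirected">',
    '    <attributes class="node"><attribute id="0" title="module" type="string"/></attributes>',
    '    <nodes>', node_xml, '    </nodes>',
    '    <edges>', edge_xml, '    </edges>',
    '  </graph>', '</gexf>'
  )
  writeLines(xml, path)
  invisible(path)
}
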