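# Hierarchy serialization: polytree documents (DOT + GraphML) with
# SRM heat-mapping, and molecular-viewer residue selections.

#' Polytree document for a cluster hierarchy
#'
#' Builds a graph document with one node per cluster and per participating
#' leaf column, and one edge from each constituent to the cluster its
#' merge created (a polytree: merging consumes its inputs, so no node has
#' two parents). Cluster labels list member attribute ids in parentheses;
#' node fill colours are a monotone heat-map of SRM over a sequential
#' palette; nodes are stratified by cluster order. Output is fully
#' deterministic for identical input.
#'
#' @param h An `srm_hierarchy` (or `srm_scan`).
#' @param palette A sequential palette name accepted by
#'   [grDevices::hcl.colors()].
#' @return An object of class `polytree_document`: list with `nodes`
#'   (data.frame `id`, `label`, `type`, `order`, `srm`, `fill`), `edges`
#'   (data.frame `child`, `parent`) and `dot` (DOT source string).
#' @seealso [write_polytree_dot()], [write_polytree_graphml()]
#' @export
to_polytree <- function(h, palette = "YlOrRd") {
  if (inherits(h, "srm_scan")) h <- h$hierarchy
  if (length(h$clusters) == 0L) stop("empty hierarchy: nothing to export")
  ramp <- grDevices::hcl.colors(101, palette, rev = TRUE)
  cl_ids <- names(h$clusters)[order(vapply(h$clusters, `[[`, 0L, "step"))]
  cl <- h$clusters[cl_ids]
  nodes <- rbind(
    data.frame(
      id = paste0("a", h$leaves),
      label = as.character(h$leaves),
      type = "leaf",
      order = 1L,
      srm = NA_real_,
      fill = "#FFFFFF"
    ),
    data.frame(
      id = cl_ids,
      label = vapply(cl, function(x) {
        paste0("(", paste(x$members, collapse = ", "), ")")
      }, ""),
      type = "cluster",
      order = vapply(cl, `[[`, 0L, "order"),
      srm = vapply(cl, `[[`, 0, "srm"),
      fill = ramp[pmin(100L, pmax(0L, round(
        vapply(cl, `[[`, 0, "srm") * 100))) + 1L]
    )
  )
  edges <- h$edges[order(h$edges$parent, h$edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  dot <- c(
    "digraph srm_hierarchy {",
    "  rankdir=BT;",
    "  node [shape=box, style=filled, fontname=\"Helvetica\"];",
    unlist(lapply(sort(unique(nodes$order)), function(o) {
      ids <- nodes$id[nodes$order == o]
      sprintf("  { rank=same; %s }",
              paste(sprintf("\"%s\";", ids), collapse = " "))
    })),
    sprintf("  \"%s\" [label=\"%s\", fillcolor=\"%s\"%s];",
            nodes$id, nodes$label, nodes$fill,
            ifelse(nodes$type == "leaf", ", shape=plaintext", "")),
    sprintf("  \"%s\" -> \"%s\";", edges$child, edges$parent),
    "}"
  )
  structure(list(nodes = nodes, edges = edges,
                 dot = paste(dot, collapse = "\n")),
            class = "polytree_document")
}

#' @export
print.polytree_document <- function(x, ...) {
  cat(sprintf("polytree document: %d nodes (%d clusters), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "cluster"),
              nrow(x$edges)))
  invisible(x)
}

#' Write a polytree document
#'
#' `write_polytree_dot()` writes Graphviz DOT for quick rendering;
#' `write_polytree_graphml()` writes GraphML with `label`, `srm`, `order`
#' and `fill` node attributes for programmatic round-trips.
#'
#' @param pt A `polytree_document` (or an `srm_hierarchy`/`srm_scan`,
#'   converted on the fly).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polytree_dot <- function(pt, path) {
  if (!inherits(pt, "polytree_document")) pt <- to_polytree(pt)
  writeLines(pt$dot, path)
  invisible(path)
}

#' @rdname write_polytree_dot
#' @export
write_polytree_graphml <- function(pt, path) {
  if (!inherits(pt, "polytree_document")) pt <- to_polytree(pt)
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c(id = "label", attr.name = "label", attr.type = "string"),
    c(id = "srm", attr.name = "srm", attr.type = "double"),
    c(id = "order", attr.name = "order", attr.type = "int"),
    c(id = "fill", attr.name = "fill", attr.type = "string")
  )
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[["id"]], `for` = "node",
                        attr.name = k[["attr.name"]],
                        attr.type = k[["attr.type"]])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "srm_hierarchy",
                           edgedefault = "directed")
  for (i in seq_len(nrow(pt$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = pt$nodes$id[i])
    xml2::xml_add_child(nd, "data", pt$nodes$label[i], key = "label")
    if (!is.na(pt$nodes$srm[i])) {
      xml2::xml_add_child(nd, "data",
                          format(pt$nodes$srm[i], digits = 15),
                          key = "srm")
    }
    xml2::xml_add_child(nd, "data", as.character(pt$nodes$order[i]),
                        key = "order")
    xml2::xml_add_child(nd, "data", pt$nodes$fill[i], key = "fill")
  }
  for (i in seq_len(nrow(pt$edges))) {
    xml2::xml_add_child(g, "edge",
                        source = pt$edges$child[i],
                        target = pt$edges$parent[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Molecular-viewer selection string for a cluster
#'
#' Translates a cluster's member columns into a PyMOL-style residue
#' selection on a chain, using the alignment's reference renumbering
#' (see [build_reference_map()]). Members falling in reference-gap
#' columns cannot be mapped and are omitted with a warning; residue
#' numbers appear exactly once, in ascending order.
#'
#' @param cluster An `srm_cluster`, or an integer vector of attribute ids.
#' @param aln An `msa` with a `reference_map`.
#' @param chain Chain identifier (e.g. `"A"`).
#' @param name Selection name used in the emitted command.
#' @return The selection string, e.g.
#'   `"select subdomain, chain A and resi 91+92+99"`.
#' @export
to_viewer_selection <- function(cluster, aln, chain, name = "subdomain") {
  members <- if (inherits(cluster, "srm_cluster")) cluster$members else
    as.integer(cluster)
  if (length(members) == 0L) stop("empty cluster")
  if (is.null(aln$reference_map)) {
    stop("alignment has no reference map; run build_reference_map() first")
  }
  if (!is.character(chain) || length(chain) != 1L || !nzchar(chain)) {
    stop("chain must be a nonempty string")
  }
  res <- aln$reference_map[as.character(members)]
  unmapped <- sum(is.na(res))
  if (unmapped == length(members)) {
    stop("no cluster member maps to a reference residue")
  }
  if (unmapped > 0L) {
    warning(unmapped, " member(s) fall in reference-gap columns and were omitted")
  }
  resi <- sort(unique(res[!is.na(res)]))
  sprintf("select %s, chain %s and resi %s", name, chain,
          paste(resi, collapse = "+"))
}
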