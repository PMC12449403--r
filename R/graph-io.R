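# Graph export/import: GraphML (with node `role` and edge `weight`
# attributes) and a plain weighted edge list.  Round-trips are exact;
# isolated nodes survive only in GraphML (the edge list cannot carry
# them, so edge-list import is restricted to graphs without them).

#' Export a provider graph
#'
#' @param graph A [provider_graph()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"` (CSV `source,target,weight`).
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    doc <- xml2::xml_new_root(
      "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
    xml2::xml_add_child(doc, "key", id = "role", `for` = "node",
                        attr.name = "role", attr.type = "string")
    xml2::xml_add_child(doc, "key", id = "weight", `for` = "edge",
                        attr.name = "weight", attr.type = "long")
    g <- xml2::xml_add_child(doc, "graph", id = graph$network_id,
                             edgedefault = "directed")
    for (i in seq_len(nrow(graph$nodes))) {
      nd <- xml2::xml_add_child(g, "node", id = graph$nodes$provider_id[i])
      d <- xml2::xml_add_child(nd, "data", key = "role")
      xml2::xml_set_text(d, graph$nodes$role[i])
    }
    for (i in seq_len(nrow(graph$edges))) {
      ed <- xml2::xml_add_child(g, "edge",
                                source = graph$edges$from[i],
                                target = graph$edges$to[i])
      d <- xml2::xml_add_child(ed, "data", key = "weight")
      xml2::xml_set_text(d, as.character(graph$edges$weight[i]))
    }
    xml2::write_xml(doc, path)
  } else {
    utils::write.csv(
      data.frame(source = graph$edges$from, target = graph$edges$to,
                 weight = graph$edges$weight, stringsAsFactors = FALSE),
      path, row.names = FALSE)
  }
  invisible(path)
}

#' Import a provider graph written by [export_graph()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edgelist"`.
#' @param providers Provider table; required for `"edgelist"` (which does
#'   not carry roles), optional for GraphML.
#' @param network_id Identifier for edge-list import (GraphML carries its
#'   own).
#' @return A [provider_graph()].
#' @export
import_graph <- function(path, format = c("graphml", "edgelist"),
                         providers = NULL, network_id = "imported") {
  format <- match.arg(format)
  if (format == "graphml") {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    gnode <- xml2::xml_find_first(doc, ".//g:graph", ns)
    nid <- xml2::xml_attr(gnode, "id")
    nodes_xml <- xml2::xml_find_all(gnode, ".//g:node", ns)
    nodes <- data.frame(
      provider_id = xml2::xml_attr(nodes_xml, "id"),
      role = xml2::xml_text(
        xml2::xml_find_first(nodes_xml, ".//g:data[@key='role']", ns)),
      stringsAsFactors = FALSE)
    edges_xml <- xml2::xml_find_all(gnode, ".//g:edge", ns)
    edges <- data.frame(
      from = xml2::xml_attr(edges_xml, "source"),
      to = xml2::xml_attr(edges_xml, "target"),
      weight = as.integer(xml2::xml_text(
        xml2::xml_find_first(edges_xml, ".//g:data[@key='weight']", ns))),
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    provider_graph(nid, nodes, edges)
  } else {
    if (is.null(providers))
      stop("edge-list import requires a provider table for roles",
           call. = FALSE)
    df <- utils::read.csv(path, colClasses = c("character", "character",
                                               "integer"),
                          stringsAsFactors = FALSE)
    .check_cols(df, c("source", "target", "weight"), path)
    pairsless <- data.frame(from = df$source, to = df$target,
                            weight = as.integer(df$weight),
                            stringsAsFactors = FALSE)
    ids <- sort(unique(c(pairsless$from, pairsless$to)))
    role <- providers$role[match(ids, providers$provider_id)]
    nodes <- data.frame(provider_id = ids, role = role,
                        stringsAsFactors = FALSE)
    pairsless <- pairsless[order(pairsless$from, pairsless$to), ,
                           drop = FALSE]
    rownames(pairsless) <- NULL
    provider_graph(network_id, nodes, pairsless)
  }
}
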