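#' Serialize a colored de Bruijn graph to a JSON bundle
#'
#' Versioned, inspectable JSON: k, sample order, anchors, node labels with
#' colors, an edge table, and the per-sample paths. `read_cdbg()` restores
#' an identical object.
#'
#' @param graph a `cdbg`.
#' @param path output file.
#' @export
write_cdbg <- function(graph, path) {
  edges <- graph_edge_table(graph)
  obj <- list(
    format = "panbubble-graph", version = 1L,
    k = graph$k, samples = graph$samples, anchors = as.list(graph$anchors),
    nodes = graph$nodes, node_color = graph$node_color,
    edge_from = edges$from, edge_to = edges$to, edge_color = edges$color,
    sample_paths = graph$sample_paths
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cdbg
#' @export
read_cdbg <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "panbubble-graph")) {
    stop("not a panbubble graph bundle")
  }
  nn <- length(obj$nodes)
  lev <- seq_len(nn)
  from <- as.integer(obj$edge_from); to <- as.integer(obj$edge_to)
  ecol <- as.integer(obj$edge_color)
  adj_out <- split(to, factor(from, levels = lev))
  adj_out_color <- split(ecol, factor(from, levels = lev))
  ord <- order(to, seq_along(to))
  adj_in <- split(from[ord], factor(to[ord], levels = lev))
  adj_in_color <- split(ecol[ord], factor(to[ord], levels = lev))
  names(adj_out) <- names(adj_in) <- NULL
  names(adj_out_color) <- names(adj_in_color) <- NULL
  paths <- lapply(obj$sample_paths, as.integer)
  structure(list(
    k = as.integer(obj$k), nodes = obj$nodes,
    node_color = as.integer(obj$node_color),
    adj_out = adj_out, adj_in = adj_in,
    adj_out_color = adj_out_color, adj_in_color = adj_in_color,
    start = which(lengths(adj_in) == 0L), end = which(lengths(adj_out) == 0L),
    anchors = c(head = obj$anchors$head, tail = obj$anchors$tail),
    samples = obj$samples, sample_paths = paths,
    n_samples = length(obj$samples)
  ), class = "cdbg")
}

graph_edge_table <- function(graph) {
  from <- rep(seq_along(graph$adj_out), lengths(graph$adj_out))
  tibble::tibble(from = from,
                 to = unlist(graph$adj_out, use.names = FALSE),
                 color = unlist(graph$adj_out_color, use.names = FALSE))
}

#' Bubble-forest topology (CST) file
#'
#' One row per bubble: order, source/sink k-mers, color string, parent
#' order (NA for roots) and level. Round-trips through `read_cst()`.
#'
#' @param tree a `bubble_tree`.
#' @param path output TSV.
#' @export
write_cst <- function(tree, path) {
  readr::write_tsv(tibble::tibble(
    order = tree$order, source = tree$source_kmer, sink = tree$sink_kmer,
    color = tree$color_str, parent = tree$parent, level = tree$level
  ), path)
  invisible(path)
}

#' @rdname write_cst
#' @export
read_cst <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    order = "i", source = "c", sink = "c", color = "c",
                    parent = "i", level = "i"))
}

#' Bubble detailed-information (CSDI) file
#'
#' Per bubble: node, edge, branch and supernode counts, per-sample spelled
#' segment length, and the branch (out-edge) information of the source.
#'
#' @param tree a `bubble_tree`.
#' @param graph the `cdbg`.
#' @param path output TSV.
#' @export
write_csdi <- function(tree, graph, path) {
  rows <- lapply(seq_len(nrow(tree)), function(i) {
    U <- tree$nodes[[i]]
    cc <- tree$color[i]
    inU <- logical(length(graph$nodes)); inU[U] <- TRUE
    n_edges <- sum(vapply(U, function(v) {
      sum(inU[graph$adj_out[[v]]] &
            bitwAnd(graph$node_color[graph$adj_out[[v]]], cc) != 0L)
    }, numeric(1)))
    deg_in <- vapply(U, function(v) {
      sum(inU[graph$adj_in[[v]]] &
            bitwAnd(graph$node_color[graph$adj_in[[v]]], cc) != 0L)
    }, numeric(1))
    deg_out <- vapply(U, function(v) {
      sum(inU[graph$adj_out[[v]]] &
            bitwAnd(graph$node_color[graph$adj_out[[v]]], cc) != 0L)
    }, numeric(1))
    supern <- sum(deg_in > 1 | deg_out > 1)
    branches <- sum(deg_in <= 1 & deg_out <= 1)
    members <- color_samples(cc, graph$n_samples)
    seg_len <- vapply(members, function(m) {
      p <- graph$sample_paths[[m]]
      nchar(spell_path(graph, p[match(tree$source[i], p):
                                  match(tree$sink[i], p)]))
    }, integer(1))
    tibble::tibble(
      order = tree$order[i], n_nodes = length(U), n_edges = n_edges,
      n_branch_nodes = branches, n_supernodes = supern,
      sample_lengths = paste(graph$samples[members], seg_len, sep = ":",
                             collapse = ","),
      source_branches = paste(graph$nodes[graph$adj_out[[tree$source[i]]]],
                              color_to_string(
                                graph$adj_out_color[[tree$source[i]]],
                                graph$n_samples),
                              sep = ":", collapse = ","))
  })
  readr::write_tsv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Offset value information (OVI) file
#'
#' @param offsets an `offset_map`.
#' @param graph the `cdbg`.
#' @param path output TSV with `node_kmer`, `forward`, `pre`, `final`.
#' @export
write_ovi <- function(offsets, graph, path) {
  readr::write_tsv(tibble::tibble(
    node_kmer = graph$nodes, forward = offsets$forward,
    pre = offsets$pre, final = offsets$final), path)
  invisible(path)
}

#' Node nearby information (NNI) file
#'
#' @param graph the `cdbg`.
#' @param path output TSV with node, in/out neighbour k-mers, color.
#' @export
write_nni <- function(graph, path) {
  readr::write_tsv(tibble::tibble(
    node_kmer = graph$nodes,
    in_neighbors = vapply(graph$adj_in, function(v)
      paste(graph$nodes[v], collapse = ","), character(1)),
    out_neighbors = vapply(graph$adj_out, function(v)
      paste(graph$nodes[v], collapse = ","), character(1)),
    color = color_to_string(graph$node_color, graph$n_samples)), path)
  invisible(path)
}

#' Cycle cut position (CCP) file
#'
#' @param regions ranked `cut_regions` (per cycle, bind rows with a
#'   `cycle` column if several).
#' @param path output TSV.
#' @export
write_ccp <- function(regions, path) {
  readr::write_tsv(regions, path)
  invisible(path)
}
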