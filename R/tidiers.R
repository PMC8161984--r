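#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a colored de Bruijn graph into its node table
#'
#' @param x a `cdbg`.
#' @param ... unused.
#' @return tibble `node`, `kmer`, `color`, `in_degree`, `out_degree`,
#'   `is_supernode`.
#' @export
tidy.cdbg <- function(x, ...) {
  tibble::tibble(
    node = seq_along(x$nodes), kmer = x$nodes,
    color = color_to_string(x$node_color, x$n_samples),
    in_degree = lengths(x$adj_in), out_degree = lengths(x$adj_out),
    is_supernode = lengths(x$adj_in) > 1L | lengths(x$adj_out) > 1L)
}

#' @rdname tidy.cdbg
#' @export
glance.cdbg <- function(x, ...) {
  tibble::tibble(k = x$k, n_nodes = length(x$nodes), n_edges = n_edges(x),
                 n_samples = x$n_samples,
                 n_supernodes = length(supernodes(x)),
                 acyclic = nrow(detect_cycles(x)) == 0)
}

#' Summarize a bubble forest
#'
#' @param x a `bubble_tree`.
#' @param ... unused.
#' @return one-row tibble: bubble count, root count, max level, simple
#'   bubble count.
#' @export
glance.bubble_tree <- function(x, ...) {
  tibble::tibble(n_bubbles = nrow(x), n_roots = sum(x$is_root),
                 max_level = if (nrow(x)) max(x$level) else 0L,
                 n_simple = sum(x$is_simple))
}

#' @export
tidy.bubble_tree <- function(x, ...) {
  tibble::as_tibble(x[, c("order", "source_kmer", "sink_kmer", "color_str",
                          "n_paths", "is_simple", "parent", "level",
                          "is_root")])
}

#' @export
glance.variant_eval <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.panbubble_run <- function(x, ...) tibble::as_tibble(x$calls)

#' @export
glance.panbubble_run <- function(x, ...) {
  dplyr::bind_cols(glance(x$graph), glance(x$tree),
                   tibble::tibble(n_calls = nrow(x$calls)))
}
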