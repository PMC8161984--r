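#' Postorder-like traversal with longest-path offsets
#'
#' Visits nodes from the start node (or, in reverse mode, from the end
#' node against edge direction), visiting a node only once all its parents
#' in the traversal direction are fully visited (ties broken FIFO on
#' discovery, so the visit order is reproducible). Each visited node gets
#' an offset value `pos(v) = max(pos(parents)) + 1`, the longest-path
#' distance from the traversal source — with `pos(source) = 1`.
#'
#' Four visit states are tracked: unvisited, to-be-visited (some but not
#' all parents done, or queued), fully visited. If the graph has a directed
#' cycle the traversal finishes in advance: `early_finish` is TRUE and the
#' nodes caught with some-but-not-all parents done are reported as
#' half-visited (their partial offsets are in `pos`).
#'
#' @param graph a `cdbg`.
#' @param direction `"forward"` (from start, along edges) or `"reverse"`
#'   (from end, against edges).
#' @return list with `order` (visit order, node indices), `pos` (integer
#'   offsets, NA-free only for visited nodes), `state` (factor-like integer:
#'   0 unvisited, 1 to-be-visited, 2 fully visited), `early_finish`,
#'   `half_visited` (node indices).
#' @export
traverse_graph <- function(graph, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  fwd <- direction == "forward"
  adj <- if (fwd) graph$adj_out else graph$adj_in
  parents_n <- if (fwd) lengths(graph$adj_in) else lengths(graph$adj_out)
  source <- if (fwd) graph$start else graph$end

  nn <- length(graph$nodes)
  rem <- parents_n            # parents not yet fully visited
  maxp <- integer(nn)         # max parent offset seen so far
  state <- integer(nn)        # 0 unvisited, 1 to-be-visited, 2 fully
  pos <- rep(NA_integer_, nn)
  queue <- integer(nn); qh <- 1L; qt <- 0L
  push <- function(v) { qt <<- qt + 1L; queue[qt] <<- v; state[v] <<- 1L }
  roots <- which(parents_n == 0L)
  if (!source %in% roots) stop("traversal source has incoming edges")
  for (v in roots) push(v)

  order <- integer(nn); no <- 0L
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    pos[v] <- maxp[v] + 1L
    state[v] <- 2L
    no <- no + 1L; order[no] <- v
    for (w in adj[[v]]) {
      if (pos[v] > maxp[w]) maxp[w] <- pos[v]
      rem[w] <- rem[w] - 1L
      if (rem[w] == 0L) push(w) else if (state[w] == 0L) state[w] <- 1L
    }
  }
  early <- no < nn
  half <- if (early) which(state == 1L & rem > 0L) else integer(0)
  # expose partial offsets of half-visited nodes (one past their best parent)
  pos[half] <- maxp[half] + 1L
  list(order = order[seq_len(no)], pos = pos, state = state,
       early_finish = early, half_visited = half)
}

#' Forward, pre- and final offset values
#'
#' Forward offsets are longest-path distances from the start node. Pre-
#' offsets come from the reverse traversal (from the end node, against the
#' edges); the final offset is obtained by subtraction,
#' `final(v) = pre(start) + 1 - pre(v)`, so that `final(start) = 1`. Final
#' offsets are monotone along every path and place the offset jump of an
#' unequal-branch bubble adjacent to the (forward) source node — where the
#' variant sits — rather than at the sink.
#'
#' @param graph an acyclic `cdbg`.
#' @return object of class `offset_map`: list with integer vectors
#'   `forward`, `pre`, `final` (one entry per node), plus the reverse visit
#'   order in `reverse_order`.
#' @export
node_offsets <- function(graph) {
  fw <- traverse_graph(graph, "forward")
  if (fw$early_finish) {
    stop("graph has cycles; resolve them first (see detect_cycles(), ",
         "resolve_cycles())", call. = FALSE)
  }
  rv <- traverse_graph(graph, "reverse")
  final <- rv$pos[graph$start] + 1L - rv$pos
  structure(list(forward = fw$pos, pre = rv$pos, final = final,
                 reverse_order = rv$order),
            class = "offset_map")
}

#' @export
print.offset_map <- function(x, ...) {
  cat("offset map over", length(x$final), "nodes; final range [",
      min(x$final), ",", max(x$final), "]\n")
  invisible(x)
}

#' Offsets as a tibble
#'
#' @param x an `offset_map`.
#' @param graph the `cdbg` it was computed from (for node labels).
#' @return tibble with `node`, `kmer`, `forward`, `pre`, `final`.
#' @export
offset_table <- function(x, graph) {
  tibble::tibble(node = seq_along(x$final), kmer = graph$nodes,
                 forward = x$forward, pre = x$pre, final = x$final)
}
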