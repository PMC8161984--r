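#' Verify a colored superbubble candidate
#'
#' Checks the four superbubble criteria — reachability, matching,
#' acyclicity, minimality — for the pair `(s, t)` in the subgraph induced
#' by the nodes whose color intersects `color`. A colored superbubble is a
#' superbubble of that induced subgraph; endpoints must both be supernodes
#' (the minimality scan therefore only considers inner sinks with induced
#' indegree above one). This is a pure predicate and doubles as the
#' brute-force ground truth for `find_bubbles()`.
#'
#' @param graph a `cdbg`.
#' @param s,t distinct node indices (source, sink).
#' @param color non-empty color mask (or '0'/'1' string).
#' @return TRUE/FALSE.
#' @export
verify_bubble <- function(graph, s, t, color) {
  if (is.character(color)) color <- color_from_string(color)
  if (color == 0L) stop("color must be non-empty")
  if (s == t) return(FALSE)
  core <- bubble_core(graph, s, t, color)
  if (is.null(core)) return(FALSE)
  verify_minimal(graph, s, t, color, core$U)
}

# reachability + matching + acyclicity; returns list(U = node set) or NULL.
# With `pre` (reverse-traversal offsets) supplied, exploration fails fast
# the moment it leaves the candidate's offset window: final offsets are
# monotone along paths, so a node past the sink's offset (or before the
# source's) can never satisfy the matching criterion.
bubble_core <- function(graph, s, t, color, pre = NULL,
                        check_acyclic = TRUE) {
  nc <- graph$node_color
  if (bitwAnd(nc[s], color) == 0L || bitwAnd(nc[t], color) == 0L) {
    return(NULL)
  }
  # both endpoints must be supernodes of the color-induced subgraph
  if (sum(bitwAnd(nc[graph$adj_out[[s]]], color) != 0L) < 2L ||
      sum(bitwAnd(nc[graph$adj_in[[t]]], color) != 0L) < 2L) {
    return(NULL)
  }
  mark <- logical(length(graph$nodes))
  bfs <- function(from, stop_at, adj, forward) {
    seen <- integer(64); ns <- 0L
    stack <- integer(64); sp <- 1L; stack[1] <- from
    mark[from] <- TRUE
    ok <- TRUE
    while (sp > 0L) {
      v <- stack[sp]; sp <- sp - 1L
      ns <- ns + 1L
      if (ns > length(seen)) seen <- c(seen, integer(length(seen)))
      seen[ns] <- v
      if (v == stop_at) next
      for (w in adj[[v]]) {
        if (bitwAnd(nc[w], color) == 0L) next
        if (!mark[w]) {
          if (!is.null(pre) && w != stop_at) {
            pw <- pre[w]
            if (is.na(pw) ||
                (if (forward) pw <= pre[stop_at] else pw >= pre[stop_at])) {
              ok <- FALSE
              break
            }
          }
          mark[w] <- TRUE
          sp <- sp + 1L
          if (sp > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[sp] <- w
        }
      }
      if (!ok) break
    }
    res <- seen[seq_len(ns)]
    mark[res] <- FALSE
    mark[stack[seq_len(max(sp, 0L))]] <- FALSE
    if (!ok) NULL else res
  }
  r_s <- bfs(s, t, graph$adj_out, forward = TRUE)
  if (is.null(r_s) || !t %in% r_s) return(NULL)   # reachability / window
  r_t <- bfs(t, s, graph$adj_in, forward = FALSE)
  if (is.null(r_t) || !setequal(r_s, r_t)) return(NULL)  # matching
  U <- sort(r_s)
  # acyclicity of the subgraph induced by U (any induced subgraph of an
  # ambient DAG is acyclic, so callers that already know the graph is a
  # DAG skip this)
  if (!check_acyclic) return(list(U = U))
  ao <- graph$adj_out
  deg <- integer(length(U))
  for (v in U) {
    ws <- ao[[v]]
    ws <- ws[bitwAnd(nc[ws], color) != 0L]
    hit <- match(ws, U, nomatch = 0L)
    hit <- hit[hit > 0L]
    deg[hit] <- deg[hit] + 1L
  }
  queue <- which(deg == 0L); done <- 0L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]; done <- done + 1L
    ws <- ao[[U[i]]]
    ws <- ws[bitwAnd(nc[ws], color) != 0L]
    hit <- match(ws, U, nomatch = 0L)
    for (j in hit[hit > 0L]) {
      deg[j] <- deg[j] - 1L
      if (deg[j] == 0L) queue <- c(queue, j)
    }
  }
  if (done < length(U)) return(NULL)         # cycle inside
  list(U = U)
}

#' Find all colored superbubbles in discovery order
#'
#' Performs the single postorder-like pass from the end node against the
#' edges (the orientation that also yields the pre-offsets), maintaining a
#' queue of pending sink supernodes. When the pass reaches a node with
#' forward outdegree above one it scans the queue newest-first; a pending
#' sink `t` matches source `s` when at least two outgoing edge colors of
#' `s` intersect `color(t)` and at least two incoming edge colors of `t`
#' intersect `color(s)`; a match is emitted as `<s, t, color(s) & color(t)>`
#' and verified before being recorded. After a match, if `color(t)` is a
#' subset of `color(s)` the sink is removed and the scan continues,
#' otherwise the scan stops; non-matching entries are passed over.
#'
#' @param graph an acyclic `cdbg`.
#' @return a tibble of class `bubble_set`, one row per bubble in discovery
#'   order: `order`, `source`, `sink`, `source_kmer`, `sink_kmer`, `color`
#'   (mask), `color_str`, `n_paths`, `is_simple`, and a `nodes` list-column
#'   (the matching node set, endpoints included).
#' @export
find_bubbles <- function(graph) {
  rv <- traverse_graph(graph, "reverse")
  if (rv$early_finish) stop("graph has cycles; resolve them first")
  pre <- rv$pos
  outdeg <- lengths(graph$adj_out)
  indeg <- lengths(graph$adj_in)
  ncol_ <- graph$node_color
  # node -> position on each sample's path (0 when absent): a bubble
  # <s, t, C> requires every sample of C to traverse s before t
  pathpos <- lapply(graph$sample_paths, function(p) {
    x <- integer(length(graph$nodes))
    x[p] <- seq_along(p)
    x
  })
  sample_bits <- bitwShiftL(1L, seq_len(graph$n_samples) - 1L)
  endpoints_ok <- function(s, t, cc) {
    for (m in which(bitwAnd(cc, sample_bits) != 0L)) {
      is <- pathpos[[m]][s]; it <- pathpos[[m]][t]
      if (is == 0L || it == 0L || is >= it) return(FALSE)
    }
    TRUE
  }

  q_nodes <- integer(0)              # pending sinks, oldest first
  res <- list()
  for (x in rv$order) {
    if (outdeg[x] > 1L) {
      # x acts as a (forward) source: scan pending sinks newest-first
      i <- length(q_nodes)
      got_cols <- integer(0)  # colors already emitted from this source
      while (i >= 1L) {
        t <- q_nodes[i]
        emitted <- FALSE
        if (bubble_match(graph, x, t)) {
          cc <- bitwAnd(ncol_[x], ncol_[t])
          # a candidate whose color sits inside one already-emitted bubble
          # of this source must reconverge at that bubble's sink first, so
          # it cannot be minimal: skip without exploring
          covered <- any(bitwAnd(cc, got_cols) == cc)
          core <- if (!covered && endpoints_ok(x, t, cc)) {
            bubble_core(graph, x, t, cc, pre, check_acyclic = FALSE)
          } else NULL
          if (!is.null(core) &&
              verify_minimal(graph, x, t, cc, core$U, pre,
                             endpoint_ok = endpoints_ok,
                             check_acyclic = FALSE)) {
            res[[length(res) + 1L]] <- list(source = x, sink = t,
                                            color = cc, nodes = core$U)
            emitted <- TRUE
            got_cols <- c(got_cols, cc)
          }
        }
        if (emitted && color_subset(ncol_[t], ncol_[x])) {
          q_nodes <- q_nodes[-i]      # sink fully explained: drop, go on
          i <- i - 1L
        } else if (emitted) {
          break                       # sink has colors beyond this source
        } else {
          i <- i - 1L                 # pass over without removing
        }
      }
    }
    if (indeg[x] > 1L) q_nodes <- c(q_nodes, x)
  }

  n <- length(res)
  out <- tibble::tibble(
    order = seq_len(n),
    source = vapply(res, `[[`, integer(1), "source"),
    sink = vapply(res, `[[`, integer(1), "sink"),
    color = vapply(res, `[[`, integer(1), "color"),
    nodes = lapply(res, `[[`, "nodes")
  )
  out$source_kmer <- graph$nodes[out$source]
  out$sink_kmer <- graph$nodes[out$sink]
  out$color_str <- color_to_string(out$color, graph$n_samples)
  out$n_paths <- purrr::pmap_dbl(out[c("source", "sink", "color", "nodes")],
                                 function(source, sink, color, nodes) {
                                   count_paths(graph, source, sink, color, nodes)
                                 })
  out$is_simple <- out$n_paths == 2
  out <- out[, c("order", "source", "sink", "source_kmer", "sink_kmer",
                 "color", "color_str", "n_paths", "is_simple", "nodes")]
  class(out) <- c("bubble_set", class(out))
  out
}

# matching principle, forward orientation
bubble_match <- function(graph, s, t) {
  ct <- graph$node_color[t]; cs <- graph$node_color[s]
  sum(bitwAnd(graph$adj_out_color[[s]], ct) != 0L) >= 2L &&
    sum(bitwAnd(graph$adj_in_color[[t]], cs) != 0L) >= 2L
}

verify_minimal <- function(graph, s, t, color, U, pre = NULL,
                           endpoint_ok = NULL, check_acyclic = TRUE) {
  inner <- setdiff(U, c(s, t))
  # try candidates nearest the source first: a non-minimal pair usually
  # fails at its first inner sink
  if (!is.null(pre)) inner <- inner[order(-pre[inner])]
  for (u in inner) {
    indeg_u <- sum(bitwAnd(graph$node_color[graph$adj_in[[u]]], color) != 0L)
    if (indeg_u <= 1L) next
    if (!is.null(endpoint_ok) && !endpoint_ok(s, u, color)) next
    if (!is.null(bubble_core(graph, s, u, color, pre, check_acyclic))) {
      return(FALSE)
    }
  }
  TRUE
}

# number of distinct source->sink paths inside the induced bubble subgraph
count_paths <- function(graph, source, sink, color, nodes) {
  inU <- logical(length(graph$nodes)); inU[nodes] <- TRUE
  ways <- numeric(length(graph$nodes)); ways[source] <- 1
  # topological order within U (acyclic by construction)
  ord <- topo_within(graph, nodes, color)
  for (v in ord) {
    if (ways[v] == 0 || v == sink) next
    for (w in graph$adj_out[[v]]) {
      if (inU[w] && bitwAnd(graph$node_color[w], color) != 0L) {
        ways[w] <- ways[w] + ways[v]
      }
    }
  }
  ways[sink]
}

topo_within <- function(graph, nodes, color) {
  inU <- logical(length(graph$nodes)); inU[nodes] <- TRUE
  ok <- function(v) inU[v] && bitwAnd(graph$node_color[v], color) != 0L
  deg <- integer(length(graph$nodes))
  for (v in nodes) for (w in graph$adj_out[[v]]) if (ok(w)) deg[w] <- deg[w] + 1L
  queue <- nodes[vapply(nodes, function(v) deg[v] == 0L, logical(1))]
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (w in graph$adj_out[[v]]) {
      if (ok(w)) { deg[w] <- deg[w] - 1L; if (deg[w] == 0L) queue <- c(queue, w) }
    }
  }
  ord
}

#' @export
print.bubble_set <- function(x, ...) {
  cat("colored superbubbles:", nrow(x), "found\n")
  NextMethod()
}
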