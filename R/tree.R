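#' Organize colored superbubbles into a forest
#'
#' A bubble's parent is the nearest later-discovered bubble that contains
#' it: the smallest order `j > i` whose color is a (non-strict) superset of
#' bubble `i`'s color, whose color is required only when bubble `i`'s
#' color is not the full sample set, and whose node set contains bubble
#' `i`'s node set (the inclusion relation). Bubbles with the full color
#' set, and bubbles with no containing bubble, are roots. Levels run from
#' 1 at the roots downward (child level = parent level + 1); every
#' parent/child pair satisfies order(child) < order(parent).
#'
#' @param bubbles a `bubble_set` from [find_bubbles()] (discovery order).
#' @param graph the `cdbg` the bubbles came from.
#' @return a tibble of class `bubble_tree`: the bubble table plus `parent`
#'   (order of parent, NA for roots), `level`, `is_root`. The full color
#'   mask is kept in `attr(, "full_color")`.
#' @export
bubble_tree <- function(bubbles, graph) {
  n <- nrow(bubbles)
  fullc <- full_color(graph$n_samples)
  parent <- rep(NA_integer_, n)
  if (n > 1) {
    for (i in seq_len(n)) {
      ci <- bubbles$color[i]
      if (ci == fullc) next                    # full-color bubbles are roots
      ni <- bubbles$nodes[[i]]
      for (j in seq(i + 1L, length.out = n - i)) {
        if (color_subset(ci, bubbles$color[j]) &&
            all(ni %in% bubbles$nodes[[j]])) {
          parent[i] <- j
          break
        }
      }
    }
  }
  level <- rep(NA_integer_, n)
  assign_level <- function(i) {
    if (!is.na(level[i])) return(level[i])
    level[i] <<- if (is.na(parent[i])) 1L else assign_level(parent[i]) + 1L
    level[i]
  }
  for (i in seq_len(n)) assign_level(i)
  out <- bubbles
  out$parent <- parent
  out$level <- level
  out$is_root <- is.na(parent)
  attr(out, "full_color") <- fullc
  class(out) <- c("bubble_tree", class(bubbles))
  out
}

#' @export
print.bubble_tree <- function(x, ...) {
  cat("colored superbubble forest:", nrow(x), "bubbles,",
      sum(x$is_root), "roots, max level",
      if (nrow(x)) max(x$level) else 0, "\n")
  NextMethod()
}

#' Relation between two colored superbubbles
#'
#' With `V0` the intersection of the two node sets and `C0` the color
#' intersection: separation when `V0` is empty, or non-empty with empty
#' `C0`; inclusion when one bubble's nodes and color are both contained in
#' the other's; intersection otherwise.
#'
#' @param bubbles a `bubble_set` or `bubble_tree`.
#' @param i,j bubble orders.
#' @return one of "separation", "intersection", "inclusion".
#' @export
relate_bubbles <- function(bubbles, i, j) {
  b1 <- bubbles[bubbles$order == i, ]; b2 <- bubbles[bubbles$order == j, ]
  stopifnot(nrow(b1) == 1, nrow(b2) == 1)
  V1 <- b1$nodes[[1]]; V2 <- b2$nodes[[1]]
  V0 <- intersect(V1, V2)
  C0 <- bitwAnd(b1$color, b2$color)
  if (length(V0) == 0) return("separation")
  if (C0 == 0L) return("separation")
  if (setequal(V0, V1) && C0 == b1$color) return("inclusion")
  if (setequal(V0, V2) && C0 == b2$color) return("inclusion")
  "intersection"
}

#' Decompose a bubble into its simple (two-path) bubbles
#'
#' A simple colored superbubble has exactly two source-to-sink paths; it is
#' the minimal unit for comparing two samples. For every pair of samples in
#' the bubble's color, the two sample paths are walked between the bubble's
#' endpoints; each divergence/reconvergence gives a two-path bubble.
#' Structurally identical bubbles found from several pairs are reported
#' once.
#'
#' @param graph the `cdbg`.
#' @param bubbles a `bubble_set`/`bubble_tree`.
#' @param i bubble order to decompose (omit for all bubbles).
#' @return tibble with `source`, `sink`, `source_kmer`, `sink_kmer`,
#'   `color` (union of the two branch path colors), `color_str`,
#'   `branch1`, `branch2` (list-columns of interior node indices).
#' @export
decompose_simple <- function(graph, bubbles, i = NULL) {
  rows <- if (is.null(i)) seq_len(nrow(bubbles)) else which(bubbles$order %in% i)
  seen <- character(0)
  acc <- list()
  for (r in rows) {
    b <- bubbles[r, ]
    members <- color_samples(b$color, graph$n_samples)
    if (length(members) < 2) next
    segs <- lapply(members, function(m) {
      p <- graph$sample_paths[[m]]
      si <- match(b$source, p); ti <- match(b$sink, p)
      p[si:ti]
    })
    names(segs) <- members
    for (a in seq_along(members)) {
      for (bb in seq_along(members)) {
        if (bb <= a) next
        pa <- segs[[a]]; pb <- segs[[bb]]
        common <- intersect(pa, pb)
        ca <- pa[pa %in% common]  # common nodes in path order (DAG: consistent)
        for (ci in seq_len(length(ca) - 1)) {
          u <- ca[ci]; v <- ca[ci + 1]
          ia <- match(u, pa); ja <- match(v, pa)
          ib <- match(u, pb); jb <- match(v, pb)
          int_a <- if (ja > ia + 1) pa[(ia + 1):(ja - 1)] else integer(0)
          int_b <- if (jb > ib + 1) pb[(ib + 1):(jb - 1)] else integer(0)
          if (length(int_a) == 0 && length(int_b) == 0) next  # shared edge
          brs <- sort(c(paste(int_a, collapse = ","),
                        paste(int_b, collapse = ",")))
          key <- paste(u, v, brs[1], brs[2], sep = "|")
          if (key %in% seen) next
          seen <- c(seen, key)
          cc <- bitwOr(path_color(graph, c(u, int_a, v)),
                       path_color(graph, c(u, int_b, v)))
          acc[[length(acc) + 1L]] <- tibble::tibble(
            source = u, sink = v,
            source_kmer = graph$nodes[u], sink_kmer = graph$nodes[v],
            color = cc, color_str = color_to_string(cc, graph$n_samples),
            branch1 = list(int_a), branch2 = list(int_b))
        }
      }
    }
  }
  if (length(acc) == 0) {
    return(tibble::tibble(source = integer(), sink = integer(),
                          source_kmer = character(), sink_kmer = character(),
                          color = integer(), color_str = character(),
                          branch1 = list(), branch2 = list()))
  }
  dplyr::bind_rows(acc)
}

# intersection of node colors along a walk
path_color <- function(graph, path) {
  Reduce(bitwAnd, graph$node_color[path])
}
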