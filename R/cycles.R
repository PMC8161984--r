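#' Detect cycles from an early-finished traversal
#'
#' Runs the forward postorder-like traversal; if it finishes in advance
#' (unvisited nodes remain) the graph has at least one directed cycle, and
#' the half-visited nodes are reported, classified as lying on a cycle or
#' not (at least one always does when the finish is early).
#'
#' @param graph a `cdbg`.
#' @return tibble with `node`, `kmer`, `pos` (partial offset at the halt),
#'   `on_cycle`; zero rows when the graph is acyclic.
#' @export
detect_cycles <- function(graph) {
  tr <- traverse_graph(graph, "forward")
  if (!tr$early_finish) {
    return(tibble::tibble(node = integer(), kmer = character(),
                          pos = integer(), on_cycle = logical()))
  }
  hv <- tr$half_visited
  tibble::tibble(
    node = hv, kmer = graph$nodes[hv], pos = tr$pos[hv],
    on_cycle = vapply(hv, function(v) node_on_cycle(graph, v), logical(1))
  )
}

# can v reach itself? (simple forward BFS)
node_on_cycle <- function(graph, v) {
  seen <- logical(length(graph$nodes))
  stack <- graph$adj_out[[v]]
  while (length(stack)) {
    w <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (w == v) return(TRUE)
    if (!seen[w]) {
      seen[w] <- TRUE
      stack <- c(stack, graph$adj_out[[w]])
    }
  }
  FALSE
}

#' Locate cycle intervals from half-visited nodes
#'
#' Implements the restart procedure: among the half-visited nodes pick the
#' one with the minimal (partial) offset as the cycle start node, mark it
#' fully visited, and resume the traversal. When the resumed traversal
#' visits an adjacent parent `v` of the chosen node `u`, the cycle interval
#' is `[pos(u), pos(v)]`. If the traversal finishes in advance again a new
#' cycle has been met and the procedure recurses on the new half-visited
#' set; if the chosen node was off-cycle the next candidate is taken.
#'
#' @param graph a cyclic `cdbg`.
#' @return tibble of class `cycle_set`, one row per located cycle:
#'   `cycle`, `start_node`, `end_node`, `start_kmer`, `end_kmer`,
#'   `start_pos`, `end_pos`, `half_visited` (list of node vectors). The
#'   offsets of the locating traversal are kept in `attr(, "pos")`.
#' @export
locate_cycle_intervals <- function(graph) {
  adj <- graph$adj_out
  parents <- graph$adj_in
  nn <- length(graph$nodes)
  rem <- lengths(parents)
  maxp <- integer(nn); state <- integer(nn); pos <- rep(NA_integer_, nn)
  queue <- integer(0)
  forced <- integer(0)          # nodes force-marked as cycle starts
  records <- list()
  pending <- list()             # cycle starts awaiting their closing parent

  visit_all <- function() {
    while (length(queue)) {
      v <- queue[1]; queue <<- queue[-1]
      pos[v] <<- maxp[v] + 1L; state[v] <<- 2L
      if (length(pending)) {
        closed <- vapply(pending, function(p) v %in% parents[[p$u]],
                         logical(1))
        for (p in pending[closed]) {
          records[[length(records) + 1L]] <<- list(
            u = p$u, v = v, start_pos = pos[p$u], end_pos = pos[v],
            half = p$half)
        }
        pending[closed] <<- NULL
      }
      for (w in adj[[v]]) {
        if (state[w] == 2L) next
        if (pos[v] > maxp[w]) maxp[w] <<- max(maxp[w], pos[v])
        rem[w] <<- rem[w] - 1L
        if (rem[w] <= 0L) { queue <<- c(queue, w); state[w] <<- 1L }
        else if (state[w] == 0L) state[w] <<- 1L
      }
    }
  }

  queue <- which(lengths(parents) == 0L)
  visit_all()
  guard <- 0L
  while (sum(state == 2L) < nn && guard < nn) {
    guard <- guard + 1L
    half <- which(state == 1L & rem > 0L)
    if (length(half) == 0) break              # unreachable remainder
    hpos <- maxp[half] + 1L
    cand <- half[order(hpos, half)]
    u <- cand[1]
    pos[u] <- maxp[u] + 1L
    # a closing parent that is u itself (self-loop) or an already-forced
    # node will never be re-visited: record such cycles immediately
    closed_now <- intersect(parents[[u]], c(u, forced))
    if (length(closed_now)) {
      v <- closed_now[which.max(pos[closed_now])]
      records[[length(records) + 1L]] <- list(
        u = u, v = v, start_pos = pos[u], end_pos = max(pos[u], pos[v]),
        half = half)
    } else {
      pending[[length(pending) + 1L]] <- list(u = u, half = half)
    }
    state[u] <- 2L
    forced <- c(forced, u)
    # release u's children as if fully visited
    for (w in adj[[u]]) {
      if (state[w] == 2L) next
      if (pos[u] > maxp[w]) maxp[w] <- max(maxp[w], pos[u])
      rem[w] <- rem[w] - 1L
      if (rem[w] <= 0L) { queue <- c(queue, w); state[w] <- 1L }
      else if (state[w] == 0L) state[w] <- 1L
    }
    visit_all()
  }
  # pendings never closed were off-cycle picks; they are simply dropped

  n <- length(records)
  out <- tibble::tibble(
    cycle = seq_len(n),
    start_node = vapply(records, `[[`, integer(1), "u"),
    end_node = vapply(records, `[[`, integer(1), "v"),
    start_pos = vapply(records, `[[`, integer(1), "start_pos"),
    end_pos = vapply(records, `[[`, integer(1), "end_pos"),
    half_visited = lapply(records, function(r) r$half %||% integer(0))
  )
  out$start_kmer <- graph$nodes[out$start_node]
  out$end_kmer <- graph$nodes[out$end_node]
  out <- out[, c("cycle", "start_node", "end_node", "start_kmer", "end_kmer",
                 "start_pos", "end_pos", "half_visited")]
  attr(out, "pos") <- pos
  class(out) <- c("cycle_set", class(out))
  out
}

#' Score candidate cutting regions inside a cycle interval
#'
#' Each offset in the interval is keyed to the last base of the k-mers
#' holding that offset; the hash bucket per offset records the distinct
#' (base, color) states, whose count is the thickness `t`. Candidate
#' cutting points are typed: I — a bridge (a single all-sample node of
#' degree 1/1, the ideal cut); II — not a bridge but involving all
#' samples; III — involving only part of the samples. Adjacent offsets
#' with the same type and thickness merge into regions scored by
#' `R = L / t` (`L` the run length); bridges win ties, and if no run has
#' uniform information the smallest-thickness position is used.
#'
#' @param graph the cyclic `cdbg`.
#' @param record one row of [locate_cycle_intervals()] output (the
#'   attribute `pos` of that object must be passed via `pos`).
#' @param pos integer offset vector from the locating traversal.
#' @return tibble of class `cut_regions`, ranked: `region`, `start_pos`,
#'   `end_pos`, `type` (I/II/III), `L`, `t`, `R`, `bases`,
#'   `reference_cut_pos`, `color` (union mask).
#' @export
score_cut_regions <- function(graph, record, pos) {
  sp <- record$start_pos; ep <- record$end_pos
  if (is.na(sp) || is.na(ep) || ep < sp) stop("empty cycle interval")
  fullc <- full_color(graph$n_samples)
  offs <- sp:ep
  info <- lapply(offs, function(p) {
    vs <- which(!is.na(pos) & pos == p)
    if (length(vs) == 0) return(NULL)
    base <- substring(graph$nodes[vs], graph$k, graph$k)
    col <- graph$node_color[vs]
    st <- unique(paste(base, col))
    list(nodes = vs, t = length(st),
         color = Reduce(bitwOr, col),
         base = names(sort(table(base), decreasing = TRUE))[1],
         bridge = length(vs) == 1L && col[1] == fullc &&
           lengths(graph$adj_in)[vs] == 1L && lengths(graph$adj_out)[vs] == 1L)
  })
  keep <- !vapply(info, is.null, logical(1))
  offs <- offs[keep]; info <- info[keep]
  if (length(offs) == 0) stop("empty cycle interval")
  type <- vapply(info, function(x) {
    if (x$bridge) "I" else if (x$color == fullc) "II" else "III"
  }, character(1))
  tvec <- vapply(info, `[[`, integer(1), "t")
  # maximal runs of consecutive offsets with identical type and thickness
  brk <- c(TRUE, diff(offs) != 1L | type[-1] != type[-length(type)] |
             tvec[-1] != tvec[-length(tvec)])
  run <- cumsum(brk)
  out <- dplyr::tibble(offset = offs, type = type, t = tvec, run = run,
                       base = vapply(info, `[[`, character(1), "base"),
                       color = vapply(info, `[[`, integer(1), "color")) |>
    dplyr::group_by(run) |>
    dplyr::summarise(
      start_pos = min(offset), end_pos = max(offset),
      type = type[1], L = dplyr::n(), t = t[1],
      bases = paste(base, collapse = ""),
      color = Reduce(bitwOr, color), .groups = "drop") |>
    dplyr::mutate(R = L / t,
                  reference_cut_pos = as.integer((start_pos + end_pos) %/% 2)) |>
    dplyr::arrange(dplyr::desc(R), type, dplyr::desc(L), start_pos) |>
    dplyr::mutate(region = dplyr::row_number()) |>
    dplyr::select(region, start_pos, end_pos, type, L, t, R, bases,
                  reference_cut_pos, color)
  class(out) <- c("cut_regions", class(out))
  out
}

#' Cut the sequences at a chosen region and rebuild acyclic graphs
#'
#' The region's base segment is searched in each sample; with a single hit
#' the sequence is split at the hit's middle, with several hits at the one
#' nearest the reference cutting position. Both parts are re-anchored
#' (each rebuilt graph again gets one head and one tail) and two graphs are
#' rebuilt, one per part. Samples that do not contain the segment raise an
#' error when the region claims them (its color), otherwise they stay whole
#' in the first part.
#'
#' @param genomes sanitized genome set used for the cyclic graph.
#' @param region one row of [score_cut_regions()] output.
#' @param k k-mer length for the rebuilt graphs.
#' @param seed anchor seed.
#' @param graph,pos when the cyclic `cdbg` and the locating traversal's
#'   offset vector are supplied, the search key for each sample is the
#'   k-mer it carries at the reference cutting offset (robust even for
#'   single-base regions); otherwise the region's consensus bases are
#'   searched directly.
#' @return list with `parts` (tibble `sample_id`, `part1`, `part2`,
#'   `cut_pos`) and `graphs` (list of rebuilt `cdbg`s, empty parts
#'   dropped).
#' @export
cut_and_rebuild <- function(genomes, region, k, seed = 1L, graph = NULL,
                            pos = NULL) {
  n_samples <- nrow(genomes)
  claimed <- color_samples(region$color, n_samples)
  nodes_at <- if (!is.null(graph) && !is.null(pos)) {
    which(!is.na(pos) & pos == region$reference_cut_pos)
  } else integer(0)
  cut_pos <- integer(n_samples)
  head_len <- if (!is.null(graph)) graph$k else 0L
  for (i in seq_len(n_samples)) {
    s <- genomes$sequence[i]
    # search the anchored sequence: the key k-mer may touch an anchor
    anch <- if (!is.null(graph)) {
      paste0(graph$anchors[["head"]], s, graph$anchors[["tail"]])
    } else s
    bit <- bitwShiftL(1L, i - 1L)
    v <- if (length(nodes_at)) {
      nodes_at[bitwAnd(graph$node_color[nodes_at], bit) != 0L][1]
    } else NA_integer_
    if (!is.na(v)) {
      key <- graph$nodes[v]
      offset_in_key <- nchar(key)      # cut after the offset-defining base
    } else {
      key <- region$bases
      offset_in_key <- max(1L, nchar(key) %/% 2L)  # middle of the region
    }
    hits <- gregexpr(key, anch, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      if (i %in% claimed) {
        stop("cut segment not found in sample ", genomes$sample_id[i])
      }
      cut_pos[i] <- nchar(s)         # stays whole in part 1
      next
    }
    cuts <- as.integer(hits) + offset_in_key - 1L - head_len
    # nearest hit to the reference cutting position (offset ~ sequence coord)
    pick <- if (length(cuts) == 1L) 1L else {
      which.min(abs(cuts - (region$reference_cut_pos - 1L)))
    }
    cut_pos[i] <- min(max(cuts[pick], 1L), nchar(s) - 1L)
  }
  parts <- tibble::tibble(
    sample_id = genomes$sample_id,
    part1 = substring(genomes$sequence, 1L, cut_pos),
    part2 = substring(genomes$sequence, cut_pos + 1L, nchar(genomes$sequence)),
    cut_pos = cut_pos
  )
  graphs <- list()
  for (col in c("part1", "part2")) {
    g <- tibble::tibble(sample_id = genomes$sample_id, sequence = parts[[col]])
    g <- g[nzchar(g$sequence), ]
    if (nrow(g) == 0) next
    graphs[[length(graphs) + 1L]] <- build_cdbg(g, k = k, seed = seed)
  }
  list(parts = parts, graphs = graphs)
}

#' Iteratively cut sequences until every graph is acyclic
#'
#' Convenience wrapper: builds the graph at the requested `k`; while a
#' graph has cycles it locates the intervals, scores cutting regions
#' (preferring, when several cycles overlap, regions inside their
#' intersection), cuts, and recurses on the parts.
#'
#' @param genomes sanitized genome set.
#' @param k k-mer length.
#' @param seed anchor seed.
#' @param max_rounds recursion guard.
#' @return list of acyclic `cdbg`s, in sequence order.
#' @export
resolve_cycles <- function(genomes, k, seed = 1L, max_rounds = 10L) {
  g <- suppressWarnings(build_cdbg(genomes, k = k, seed = seed))
  if (nrow(detect_cycles(g)) == 0) return(list(g))
  if (max_rounds <= 0) stop("cycle resolution did not converge")
  cyc <- locate_cycle_intervals(g)
  pos <- attr(cyc, "pos")
  if (nrow(cyc) == 0) stop("cycles detected but no interval could be located")
  regions <- dplyr::bind_rows(lapply(seq_len(nrow(cyc)), function(i) {
    score_cut_regions(g, cyc[i, ], pos)
  }))
  if (nrow(cyc) > 1) {
    # prefer regions inside the intersection of all cycle intervals
    lo <- max(cyc$start_pos); hi <- min(cyc$end_pos)
    inside <- regions$start_pos >= lo & regions$end_pos <= hi
    if (any(inside)) regions <- regions[inside, ]
  }
  regions <- dplyr::arrange(regions, dplyr::desc(R), type)
  cut <- cut_and_rebuild(genomes, regions[1, ], k = k, seed = seed,
                         graph = g, pos = pos)
  out <- list()
  for (col in c("part1", "part2")) {
    gg <- tibble::tibble(sample_id = genomes$sample_id,
                         sequence = cut$parts[[col]])
    gg <- gg[nzchar(gg$sequence), ]
    if (nrow(gg) == 0) next
    out <- c(out, resolve_cycles(gg, k = k, seed = seed,
                                 max_rounds = max_rounds - 1L))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
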