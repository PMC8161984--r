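# Independent oracles (igraph-based) and fixture generators used across the
# suite. Everything here is deliberately written against igraph primitives,
# not the package's own traversal/bubble code.

igraph_of <- function(g) {
  el <- cbind(rep(seq_along(g$adj_out), lengths(g$adj_out)),
              unlist(g$adj_out, use.names = FALSE))
  igraph::graph_from_edgelist(el, directed = TRUE) |>
    igraph::set_vertex_attr("name", value = as.character(seq_along(g$nodes)))
}

# longest-path distances from `from` over an acyclic graph, by DP along a
# topological order
oracle_longest_path <- function(g, from = g$start, reverse = FALSE) {
  ig <- igraph_of(g)
  if (reverse) ig <- igraph::reverse_edges(ig)
  ord <- as.integer(igraph::topo_sort(ig, mode = "out"))
  adj <- if (reverse) g$adj_in else g$adj_out
  d <- rep(NA_integer_, length(g$nodes))
  d[from] <- 1L
  for (v in ord) {
    if (is.na(d[v])) next
    for (w in adj[[v]]) {
      if (is.na(d[w]) || d[w] < d[v] + 1L) d[w] <- d[v] + 1L
    }
  }
  d
}

oracle_has_cycle <- function(g) !igraph::is_dag(igraph_of(g))

# full four-criteria colored-superbubble check through igraph primitives
oracle_verify_bubble <- function(g, s, t, color) {
  keep <- which(bitwAnd(g$node_color, color) != 0L)
  if (!(s %in% keep) || !(t %in% keep)) return(FALSE)
  ig <- igraph_of(g)
  ig <- igraph::induced_subgraph(ig, vids = as.character(keep))
  sv <- as.character(s); tv <- as.character(t)
  # endpoints must be supernodes of the color-induced subgraph
  if (igraph::degree(ig, sv, mode = "out") < 2 ||
      igraph::degree(ig, tv, mode = "in") < 2) {
    return(FALSE)
  }
  no_out_t <- igraph::delete_edges(ig, igraph::E(ig)[.from(tv)])
  r_s <- names(igraph::subcomponent(no_out_t, sv, mode = "out"))
  if (!tv %in% r_s) return(FALSE)
  no_in_s <- igraph::delete_edges(ig, igraph::E(ig)[.to(sv)])
  r_t <- names(igraph::subcomponent(no_in_s, tv, mode = "in"))
  if (!setequal(r_s, r_t)) return(FALSE)
  sub <- igraph::induced_subgraph(ig, vids = r_s)
  if (!igraph::is_dag(sub)) return(FALSE)
  inner <- setdiff(r_s, c(sv, tv))
  for (u in inner) {
    if (igraph::degree(ig, u, mode = "in") > 1) {
      no_out_u <- igraph::delete_edges(ig, igraph::E(ig)[.from(u)])
      ru_s <- names(igraph::subcomponent(no_out_u, sv, mode = "out"))
      if (!u %in% ru_s) next
      no_in_s2 <- igraph::delete_edges(ig, igraph::E(ig)[.to(sv)])
      ru_t <- names(igraph::subcomponent(no_in_s2, u, mode = "in"))
      if (setequal(ru_s, ru_t) &&
          igraph::is_dag(igraph::induced_subgraph(ig, vids = ru_s))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# every (source, sink) supernode pair forming a valid bubble at the given
# color (exhaustive enumeration)
oracle_enumerate_bubbles <- function(g, color) {
  srcs <- which(lengths(g$adj_out) > 1L)
  snks <- which(lengths(g$adj_in) > 1L)
  out <- list()
  for (s in srcs) for (t in snks) {
    if (s != t && oracle_verify_bubble(g, s, t, color)) {
      out[[length(out) + 1L]] <- c(s, t)
    }
  }
  out
}

# small random mutated population; returns a sanitized genome tibble
rand_population <- function(n_samples, len, snp = 3L, del = 0L, ins = 0L,
                            seed = 1L) {
  simulate_population(n_samples = n_samples, ref_length = len, snp = snp,
                      del = del, ins = ins, indel_len = c(1L, 8L),
                      seed = seed)$genomes
}

trio_graph <- function() {
  tr <- example_trio()
  build_cdbg(tr$genomes, k = tr$k, anchors = tr$anchors)
}

# two-sample sequences with a planted shared cassette that recurs, so the
# graph at small k is cyclic
cyclic_pair <- function(seed = 1L, k = 5L) {
  withr::with_seed(seed, {
    core <- paste(sample(c("A", "C", "G", "T"), 70, TRUE), collapse = "")
    cassette <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    g1 <- paste0(substr(core, 1, 25), cassette, substr(core, 26, 50),
                 cassette, substr(core, 51, 70))
    g2 <- paste0(substr(core, 1, 25), cassette, substr(core, 51, 70))
    tibble::tibble(sample_id = c("a", "b"), sequence = c(g1, g2))
  })
}
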