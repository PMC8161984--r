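#' Build a colored de Bruijn graph from a genome set
#'
#' Nodes are the k-mers of the anchored sequences (head + sequence + tail),
#' edges join k-mers overlapping by k-1 bases, and each node/edge carries
#' the set of samples (its color) whose path uses it. With anchors applied
#' the graph has exactly one start (indegree 0) and one end (outdegree 0)
#' node, and each sample corresponds to a unique start-to-end path spelling
#' its anchored sequence. When k exceeds the longest repeat length of every
#' sample the graph is acyclic.
#'
#' @param genomes sanitized genome set (tibble `sample_id`, `sequence`).
#' @param k k-mer length; `NULL` picks `choose_k(genomes)`.
#' @param anchors optional `c(head =, tail =)` length-k segments; drawn
#'   with `generate_anchors()` when omitted.
#' @param seed seed for anchor generation.
#' @return an object of class `cdbg`: list with `k`, `nodes` (k-mer
#'   labels), `node_color`, `adj_out`/`adj_in` (adjacency index lists),
#'   `adj_out_color`/`adj_in_color` (matching edge colors), `start`, `end`,
#'   `anchors`, `samples`, `sample_paths` (node index vectors), `n_samples`.
#' @export
build_cdbg <- function(genomes, k = NULL, anchors = NULL, seed = 1L) {
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 1)
  if (anyDuplicated(genomes$sample_id)) stop("duplicate sample ids")
  n_samples <- nrow(genomes)
  if (n_samples > MAX_SAMPLES) {
    stop("at most ", MAX_SAMPLES, " samples are supported")
  }
  if (any(stringr::str_detect(genomes$sequence, "[^ACGT]"))) {
    stop("sequences must be sanitized to {A,C,G,T}; see sanitize_genomes()")
  }
  if (is.null(k)) k <- choose_k(genomes)
  k <- as.integer(k)
  if (is.null(anchors)) {
    # random anchors can, rarely, recreate an interior k-mer across the
    # sequence/anchor junction, breaking start/end uniqueness or creating a
    # spurious cycle where k already exceeds every repeat length: redraw
    K <- max(vapply(genomes$sequence, longest_repeat_length, integer(1),
                    USE.NAMES = FALSE))
    g <- NULL
    for (try in 0:24) {
      anchors <- generate_anchors(k, genomes, seed = seed + 1009L * try)
      cand <- tryCatch(build_cdbg(genomes, k = k, anchors = anchors),
                       error = function(e) e)
      if (inherits(cand, "error")) next
      g <- cand
      junction_cycle <- k > K &&
        any(vapply(g$sample_paths, anyDuplicated, integer(1)) > 0L)
      if (!junction_cycle) return(g)
    }
    if (!is.null(g)) return(g)
    stop("could not find anchors giving unique start/end nodes")
  }
  if (any(nchar(anchors) != k)) stop("anchors must have length k")
  anchored <- paste0(anchors[[1]], genomes$sequence, anchors[[2]])
  if (k > min(nchar(anchored))) {
    stop("k exceeds the shortest anchored sequence")
  }

  kmer_list <- lapply(anchored, seq_kmers, k = k)
  nodes <- unique(unlist(kmer_list, use.names = FALSE))
  nn <- length(nodes)
  paths <- lapply(kmer_list, function(x) match(x, nodes))
  bits <- bitwShiftL(1L, seq_len(n_samples) - 1L)

  node_color <- integer(nn)
  ef <- integer(0); et <- integer(0); eb <- integer(0)
  for (i in seq_len(n_samples)) {
    ids <- paths[[i]]
    u <- unique(ids)
    node_color[u] <- bitwOr(node_color[u], bits[i])
    f <- ids[-length(ids)]; t <- ids[-1]
    key <- (as.numeric(f) - 1) * nn + as.numeric(t)
    keep <- !duplicated(key)
    ef <- c(ef, f[keep]); et <- c(et, t[keep]); eb <- c(eb, rep(bits[i], sum(keep)))
  }
  key <- (as.numeric(ef) - 1) * nn + as.numeric(et)
  uk <- !duplicated(key)
  grp <- match(key, key[uk])
  ecol <- as.integer(rowsum(as.numeric(eb), grp)[, 1])  # bits disjoint per sample
  from <- ef[uk]; to <- et[uk]

  lev <- seq_len(nn)
  adj_out <- split(to, factor(from, levels = lev))
  adj_out_color <- split(ecol, factor(from, levels = lev))
  ord <- order(to, seq_along(to))
  adj_in <- split(from[ord], factor(to[ord], levels = lev))
  adj_in_color <- split(ecol[ord], factor(to[ord], levels = lev))
  names(adj_out) <- names(adj_in) <- NULL
  names(adj_out_color) <- names(adj_in_color) <- NULL

  start <- which(lengths(adj_in) == 0L)
  end <- which(lengths(adj_out) == 0L)
  if (length(start) != 1L || length(end) != 1L) {
    stop("graph does not have unique start/end nodes (",
         length(start), " starts, ", length(end), " ends); check anchors")
  }

  structure(list(
    k = k, nodes = nodes, node_color = node_color,
    adj_out = adj_out, adj_in = adj_in,
    adj_out_color = adj_out_color, adj_in_color = adj_in_color,
    start = start, end = end,
    anchors = c(head = unname(anchors[[1]]), tail = unname(anchors[[2]])),
    samples = genomes$sample_id, sample_paths = paths,
    n_samples = n_samples
  ), class = "cdbg")
}

seq_kmers <- function(x, k) {
  n <- nchar(x)
  substring(x, 1:(n - k + 1), k:n)
}

#' Spell the sequence along a node path
#'
#' Concatenates node labels collapsing the k-1 overlaps. Spelling a
#' sample's full path reproduces its anchored sequence exactly.
#'
#' @param graph a `cdbg`.
#' @param path integer node indices (a walk in the graph).
#' @return a string.
#' @export
spell_path <- function(graph, path) {
  if (length(path) == 0) return("")
  labs <- graph$nodes[path]
  paste0(labs[1], paste(substring(labs[-1], graph$k, graph$k), collapse = ""))
}

#' @export
print.cdbg <- function(x, ...) {
  ne <- sum(lengths(x$adj_out))
  cat("colored de Bruijn graph: k =", x$k, "|", length(x$nodes), "nodes,",
      ne, "edges,", x$n_samples, "samples\n")
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

n_edges <- function(graph) sum(lengths(graph$adj_out))

out_degree <- function(graph) lengths(graph$adj_out)
in_degree <- function(graph) lengths(graph$adj_in)

#' Supernodes of the graph
#'
#' Nodes with indegree or outdegree above 1; the only admissible bubble
#' endpoints.
#'
#' @param graph a `cdbg`.
#' @return integer node indices.
#' @export
supernodes <- function(graph) {
  which(lengths(graph$adj_out) > 1L | lengths(graph$adj_in) > 1L)
}
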