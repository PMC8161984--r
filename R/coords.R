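#' Tri-tuple base locations for every node
#'
#' Each node (equivalently, each base across the population: the last base
#' of the k-mer) gets the triple `(position, bubid, basecolor)`: its final
#' offset, the order of the deepest (smallest) bubble containing it — ties
#' broken toward the smallest order, `-1` for bridge nodes outside every
#' bubble — and its color. The triple is one-to-one with nodes.
#'
#' @param graph an acyclic `cdbg`.
#' @param tree [bubble_tree()] result.
#' @param offsets [node_offsets()] result.
#' @param representative when TRUE, `basecolor` is the first sample id
#'   carrying the node instead of the 0/1 string.
#' @return tibble with `node`, `kmer`, `position`, `bubid`, `basecolor`.
#' @export
base_locations <- function(graph, tree, offsets, representative = FALSE) {
  nn <- length(graph$nodes)
  bubid <- deepest_bubble_of(tree, nn)
  bubid[is.na(bubid)] <- -1L
  basecolor <- if (representative) {
    graph$samples[vapply(graph$node_color,
                         function(cc) color_samples(cc, graph$n_samples)[1],
                         integer(1))]
  } else {
    color_to_string(graph$node_color, graph$n_samples)
  }
  tibble::tibble(node = seq_len(nn), kmer = graph$nodes,
                 position = offsets$final, bubid = bubid,
                 basecolor = basecolor)
}

#' Six-tuple location of a path
#'
#' A path (a connected walk, given as node indices or as its spelled
#' sequence) is located by
#' `(startpos, startbub, endpos, endbub, pathbub, pathcolor)`: the final
#' offsets of its end nodes, the deepest bubbles holding them, the
#' smallest bubble containing the whole path, and the intersection of the
#' node colors along it. Endpoints on bridges inherit the bubble of the
#' nearest in-path node that lies in a bubble; when no single bubble
#' contains the path and it crosses `n` root bubbles, `pathbub` is `-n`.
#' A length-1 path collapses to the node's base triple.
#'
#' @param graph an acyclic `cdbg`.
#' @param tree [bubble_tree()] result.
#' @param offsets [node_offsets()] result.
#' @param path integer node indices, or a single string to be spelled into
#'   k-mers and matched.
#' @return one-row tibble `startpos`, `startbub`, `endpos`, `endbub`,
#'   `pathbub`, `pathcolor`.
#' @export
path_location <- function(graph, tree, offsets, path) {
  if (is.character(path)) {
    stopifnot(length(path) == 1, nchar(path) >= graph$k)
    path <- match(seq_kmers(path, graph$k), graph$nodes)
    if (anyNA(path)) stop("path sequence contains k-mers absent from the graph")
  }
  # connectivity
  if (length(path) > 1) {
    for (i in seq_len(length(path) - 1)) {
      if (!path[i + 1] %in% graph$adj_out[[path[i]]]) {
        stop("node sequence is not a connected walk")
      }
    }
  }
  nn <- length(graph$nodes)
  bubid <- deepest_bubble_of(tree, nn)
  endpoint_bub <- function(idx_seq) {
    for (v in idx_seq) if (!is.na(bubid[v])) return(bubid[v])
    -1L
  }
  startbub <- endpoint_bub(path)
  endbub <- endpoint_bub(rev(path))
  in_bubble <- path[!is.na(bubid[path])]
  pathbub <- if (length(in_bubble) == 0) -1L else {
    # walk up from the deepest bubble of the first in-bubble node
    b <- bubid[in_bubble[1]]
    found <- NA_integer_
    while (!is.na(b)) {
      i <- match(b, tree$order)
      members <- logical(nn); members[tree$nodes[[i]]] <- TRUE
      if (all(members[in_bubble])) { found <- b; break }
      b <- tree$parent[i]
    }
    if (!is.na(found)) found else {
      # spans several root bubbles: count the distinct roots it touches
      roots <- unique(vapply(bubid[in_bubble], function(b) {
        root_of(tree, match(b, tree$order))
      }, integer(1)))
      -length(roots)
    }
  }
  tibble::tibble(
    startpos = offsets$final[path[1]], startbub = startbub,
    endpos = offsets$final[path[length(path)]], endbub = endbub,
    pathbub = pathbub,
    pathcolor = color_to_string(path_color(graph, path), graph$n_samples))
}

root_of <- function(tree, i) {
  while (!tree$is_root[i]) i <- match(tree$parent[i], tree$order)
  tree$order[i]
}

#' Relation between two located paths
#'
#' Classifies from the offset intervals and colors: separated when the
#' intervals do not intersect; inclusion when the intervals and the colors
#' both nest; intersection otherwise. For intersecting intervals with
#' disjoint colors the nearest common parent bubble of the two path
#' bubbles (the context in which the two sequences can be compared) and
#' its color are also returned — the full sample set when the paths span
#' root bubbles.
#'
#' @param p1,p2 one-row tibbles from [path_location()].
#' @param tree [bubble_tree()] result.
#' @param n_samples number of samples (for the fallback context color).
#' @return list with `relation` and, when applicable, `context_bubble`
#'   and `context_color`.
#' @export
relate_paths <- function(p1, p2, tree, n_samples) {
  i1 <- c(p1$startpos, p1$endpos); i2 <- c(p2$startpos, p2$endpos)
  c1 <- color_from_string(p1$pathcolor); c2 <- color_from_string(p2$pathcolor)
  disjoint <- i1[2] < i2[1] || i2[2] < i1[1]
  if (disjoint) return(list(relation = "separation"))
  nest_iv <- (i1[1] <= i2[1] && i2[2] <= i1[2]) ||
    (i2[1] <= i1[1] && i1[2] <= i2[2])
  nest_col <- color_subset(c1, c2) || color_subset(c2, c1)
  if (nest_iv && nest_col) return(list(relation = "inclusion"))
  out <- list(relation = "intersection")
  if (bitwAnd(c1, c2) == 0L) {
    ctx <- common_parent(tree, p1$pathbub, p2$pathbub)
    if (is.na(ctx)) {
      out$context_bubble <- NA_integer_
      out$context_color <- color_to_string(full_color(n_samples), n_samples)
    } else {
      out$context_bubble <- ctx
      out$context_color <- tree$color_str[match(ctx, tree$order)]
    }
  }
  out
}

common_parent <- function(tree, b1, b2) {
  if (is.na(b1) || is.na(b2) || b1 < 0 || b2 < 0) return(NA_integer_)
  chain <- function(b) {
    out <- integer(0)
    while (!is.na(b)) {
      out <- c(out, b)
      b <- tree$parent[match(b, tree$order)]
    }
    out
  }
  a <- chain(b1); b <- chain(b2)
  hit <- a[a %in% b]
  if (length(hit)) hit[1] else NA_integer_
}

#' Map linear VCF records onto graph coordinates
#'
#' Each record's position on the designated reference is looked up on the
#' reference path and reported with its base triple: whether it falls
#' inside a bubble (`bubid > 0`) or on a bridge (`bubid == -1`).
#'
#' @param graph an acyclic `cdbg`.
#' @param tree,offsets decomposition results.
#' @param vcf path to a VCF file, or a data frame with a `POS` column.
#' @param ref_id reference sample id.
#' @return tibble: `POS`, `REF`, `ALT`, `node`, `position`, `bubid`,
#'   `basecolor`, `in_bubble`; positions beyond the reference are flagged
#'   with `NA` node and a warning, not an error.
#' @export
map_vcf <- function(graph, tree, offsets, vcf, ref_id) {
  if (is.character(vcf)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF files requires the vcfR package")
    }
    v <- vcfR::read.vcfR(vcf, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    vcf <- tibble::tibble(POS = as.integer(fix$POS), REF = fix$REF,
                          ALT = fix$ALT)
  }
  stopifnot("POS" %in% names(vcf))
  if (!"REF" %in% names(vcf)) vcf$REF <- NA_character_
  if (!"ALT" %in% names(vcf)) vcf$ALT <- NA_character_
  bl <- base_locations(graph, tree, offsets)
  ref_idx <- match(ref_id, graph$samples)
  rp <- graph$sample_paths[[ref_idx]]
  lookup <- function(p) {
    i <- p + 1L                      # reference coordinate -> path index
    if (i < 1L || i > length(rp)) NA_integer_ else rp[i]
  }
  node <- vapply(as.integer(vcf$POS), lookup, integer(1))
  if (anyNA(node)) {
    warning(sum(is.na(node)), " record(s) beyond the reference length")
  }
  out <- tibble::tibble(POS = as.integer(vcf$POS), REF = vcf$REF,
                        ALT = vcf$ALT, node = node)
  out$position <- ifelse(is.na(node), NA_integer_, bl$position[node])
  out$bubid <- ifelse(is.na(node), NA_integer_, bl$bubid[node])
  out$basecolor <- ifelse(is.na(node), NA_character_, bl$basecolor[node])
  out$in_bubble <- !is.na(out$bubid) & out$bubid > 0L
  out
}

#' Map GTF/GFF intervals onto graph coordinates
#'
#' Each feature interval (1-based, inclusive) is projected onto the
#' reference path; the report lists the base triples of its end points,
#' how many distinct bubbles the interval touches, and whether it lies
#' entirely on bridges.
#'
#' @param graph an acyclic `cdbg`.
#' @param tree,offsets decomposition results.
#' @param gtf path to a GTF/GFF file, or a data frame with `start`, `end`
#'   (and optionally `feature`/`gene`) columns.
#' @param ref_id reference sample id.
#' @return tibble: `feature`, `start`, `end`, `start_bubid`, `end_bubid`,
#'   `n_bubbles` (distinct bubbles touched), `on_bridge_only`.
#' @export
map_gtf <- function(graph, tree, offsets, gtf, ref_id) {
  if (is.character(gtf)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF files requires the rtracklayer package")
    }
    g <- rtracklayer::import(gtf)
    gtf <- tibble::tibble(
      feature = as.character(g$type %||% "feature"),
      start = BiocGenerics::start(g), end = BiocGenerics::end(g))
  }
  stopifnot(all(c("start", "end") %in% names(gtf)))
  if (!"feature" %in% names(gtf)) gtf$feature <- "feature"
  bl <- base_locations(graph, tree, offsets)
  ref_idx <- match(ref_id, graph$samples)
  rp <- graph$sample_paths[[ref_idx]]
  L <- length(rp)
  row_for <- function(start, end) {
    i1 <- max(1L, min(L, start + 1L)); i2 <- max(1L, min(L, end + 1L))
    nodes <- rp[i1:i2]
    bubs <- bl$bubid[nodes]
    touched <- unique(bubs[bubs > 0L])
    tibble::tibble(start_bubid = bl$bubid[rp[i1]], end_bubid = bl$bubid[rp[i2]],
                   n_bubbles = length(touched),
                   on_bridge_only = length(touched) == 0L)
  }
  dplyr::bind_cols(
    gtf[, c("feature", "start", "end")],
    dplyr::bind_rows(purrr::map2(gtf$start, gtf$end, row_for)))
}
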