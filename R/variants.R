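#' Gap information at bubble source nodes
#'
#' Under final offsets every indel shows up as an offset jump on an edge
#' leaving the (forward) source node of a bubble: for each out-edge of each
#' source, `gap = final(child) - final(source) - 1`. Substitution branches
#' have gap 0; a positive gap on a branch means those samples spell fewer
#' bases than the longest branch between the source and sink.
#'
#' @param graph an acyclic `cdbg`.
#' @param offsets [node_offsets()] result.
#' @param bubbles `bubble_set` or `bubble_tree`.
#' @return tibble with one row per (source, out-branch): `source`,
#'   `source_kmer`, `branch` (first node of the branch), `branch_color`,
#'   `branch_color_str`, `gap`; plus per-source `max_gap` and
#'   `max_gap_color` columns.
#' @export
empty_gaps <- function() {
  tibble::tibble(source = integer(), source_kmer = character(),
                 branch = integer(), branch_color = integer(),
                 branch_color_str = character(), gap = integer(),
                 max_gap = integer(), max_gap_color = integer())
}

collect_gaps <- function(graph, offsets, bubbles) {
  if (nrow(bubbles) == 0) return(empty_gaps())
  sources <- sort(unique(bubbles$source))
  rows <- lapply(sources, function(s) {
    ch <- graph$adj_out[[s]]
    tibble::tibble(source = s, branch = ch,
                   branch_color = graph$adj_out_color[[s]],
                   gap = offsets$final[ch] - offsets$final[s] - 1L)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, source) |>
    dplyr::mutate(max_gap = max(gap),
                  max_gap_color = branch_color[which.max(gap)]) |>
    dplyr::ungroup()
  out$source_kmer <- graph$nodes[out$source]
  out$branch_color_str <- color_to_string(out$branch_color, graph$n_samples)
  out[, c("source", "source_kmer", "branch", "branch_color",
          "branch_color_str", "gap", "max_gap", "max_gap_color")]
}

# variant type codes: 1 substitution, 2 deletion, 3 insertion, 4 unsure
type_from_gaps <- function(g_base, g_alt) {
  if (g_base == 0L && g_alt == 0L) 1L
  else if (g_alt > 0L && g_base == 0L) 2L
  else if (g_base > 0L && g_alt == 0L) 3L
  else 4L
}

#' Type source nodes in bubbles containing the reference
#'
#' First detection pass: bubbles are taken in ascending discovery order and
#' only those whose color includes the reference are processed. At each
#' source the branch carrying the reference is the baseline; every other
#' out-branch is typed from the pair of gaps: both zero — substitution (1);
#' positive gap on the alt branch — deletion (2); positive gap on the
#' reference branch — insertion (3); both positive — unsure indel (4).
#'
#' @param graph the `cdbg`.
#' @param tree [bubble_tree()] result.
#' @param gaps [collect_gaps()] result.
#' @param ref_id reference sample id.
#' @return tibble `node_variants` rows: `source`, `branch`, `branch_color`,
#'   `vartype`, `affected_color`, `has_ref`, `bubble` (order used).
#' @export
nvd_reference_pass <- function(graph, tree, gaps, ref_id) {
  ref_bit <- ref_mask(graph, ref_id)
  gx <- split(seq_len(nrow(gaps)), gaps$source)
  done <- integer(0)
  out <- new_nv_acc()
  for (r in which(bitwAnd(tree$color, ref_bit) != 0L)) {  # ascending order
    s <- tree$source[r]
    if (s %in% done) next
    done <- c(done, s)
    ix <- gx[[as.character(s)]]
    base <- ix[bitwAnd(gaps$branch_color[ix], ref_bit) != 0L]
    if (length(base) != 1L) next   # defensive; reference path is unique
    for (i in setdiff(ix, base)) {
      out <- nv_add(out, s, gaps$branch[i], gaps$branch_color[i],
                    type_from_gaps(gaps$gap[base], gaps$gap[i]),
                    TRUE, tree$order[r])
    }
  }
  nv_collect(out)
}

new_nv_acc <- function() {
  list(source = integer(0), branch = integer(0), branch_color = integer(0),
       vartype = integer(0), has_ref = logical(0), bubble = integer(0))
}

nv_add <- function(acc, s, branch, bcol, vt, has_ref, bubble) {
  acc$source <- c(acc$source, s)
  acc$branch <- c(acc$branch, branch)
  acc$branch_color <- c(acc$branch_color, bcol)
  acc$vartype <- c(acc$vartype, vt)
  acc$has_ref <- c(acc$has_ref, has_ref)
  acc$bubble <- c(acc$bubble, bubble)
  acc
}

nv_collect <- function(acc) {
  tibble::tibble(source = acc$source, branch = acc$branch,
                 branch_color = acc$branch_color, vartype = acc$vartype,
                 affected_color = acc$branch_color, has_ref = acc$has_ref,
                 bubble = acc$bubble)
}

#' Type the remaining source nodes (bubbles without the reference)
#'
#' Second pass, again in ascending bubble order: sources seen only in
#' bubbles lacking the reference are typed relative to the bubble's
#' largest-membership branch (the stand-in baseline), walking the bubble
#' forest to the nearest reference-containing ancestor for context. A
#' source with no reference-bearing ancestor is typed 4 with a warning.
#' Calls from this pass carry `has_ref = FALSE` (their reference positions
#' are approximate).
#'
#' @inheritParams nvd_reference_pass
#' @param ref_pass output of [nvd_reference_pass()].
#' @return the complete node-variant tibble (both passes).
#' @export
nvd_nonreference_pass <- function(graph, tree, gaps, ref_pass, ref_id) {
  ref_bit <- ref_mask(graph, ref_id)
  if (nrow(tree) == 0) return(ref_pass)
  gx <- split(seq_len(nrow(gaps)), gaps$source)
  done <- unique(ref_pass$source)
  out <- new_nv_acc()
  for (r in which(bitwAnd(tree$color, ref_bit) == 0L)) {
    s <- tree$source[r]
    if (s %in% done) next
    done <- c(done, s)
    anc <- ref_ancestor(tree, r, ref_bit)
    ix <- gx[[as.character(s)]]
    pc <- color_popcount(gaps$branch_color[ix], graph$n_samples)
    base <- ix[pc == max(pc)]
    ambiguous <- length(base) > 1L
    base <- base[1]
    if (is.na(anc)) {
      warning("source node ", graph$nodes[s],
              " has no reference-containing ancestor bubble; typed as 4")
    }
    for (i in setdiff(ix, base)) {
      vt <- if (is.na(anc)) 4L else type_from_gaps(gaps$gap[base],
                                                   gaps$gap[i])
      if (ambiguous && vt != 1L) vt <- 4L
      out <- nv_add(out, s, gaps$branch[i], gaps$branch_color[i], vt,
                    FALSE, tree$order[r])
    }
  }
  dplyr::bind_rows(ref_pass, nv_collect(out))
}

ref_mask <- function(graph, ref_id) {
  idx <- match(ref_id, graph$samples)
  if (is.na(idx)) stop("reference sample '", ref_id, "' not in graph")
  bitwShiftL(1L, idx - 1L)
}

# nearest ancestor bubble (inclusive) whose color contains the reference
ref_ancestor <- function(tree, row, ref_bit) {
  b <- tree$order[row]
  while (!is.na(b)) {
    i <- match(b, tree$order)
    if (bitwAnd(tree$color[i], ref_bit) != 0L) return(b)
    b <- tree$parent[i]
  }
  NA_integer_
}

# node -> order of deepest bubble containing it (ties: smallest order); NA
# for bridge nodes outside every bubble
deepest_bubble_of <- function(tree, n_nodes) {
  bubid <- rep(NA_integer_, n_nodes)
  if (nrow(tree) == 0) return(bubid)
  ord <- order(tree$level, -tree$order)   # later assignments win
  for (i in ord) bubid[tree$nodes[[i]]] <- tree$order[i]
  bubid
}

#' Reference position determination
#'
#' Nodes on the reference path get the exact reference coordinate of their
#' k-mer's last base (head-anchor nodes get non-positive values, tail nodes
#' values past the reference end). Source nodes off the reference inherit
#' an approximate position from the nearest reference-containing ancestor
#' bubble: that bubble's source plus the final-offset difference.
#'
#' @param graph the `cdbg`.
#' @param tree [bubble_tree()] result.
#' @param offsets [node_offsets()] result.
#' @param ref_id reference sample id.
#' @return tibble `node`, `refpos`, `exact`.
#' @export
reference_positions <- function(graph, tree, offsets, ref_id) {
  ref_idx <- match(ref_id, graph$samples)
  if (is.na(ref_idx)) stop("reference sample '", ref_id, "' not in graph")
  nn <- length(graph$nodes)
  refpos <- rep(NA_integer_, nn)
  exact <- rep(FALSE, nn)
  rp <- graph$sample_paths[[ref_idx]]
  refpos[rp] <- seq_along(rp) - 1L      # last base, reference coordinates
  exact[rp] <- TRUE
  ref_bit <- bitwShiftL(1L, ref_idx - 1L)
  bubid <- deepest_bubble_of(tree, nn)
  for (s in unique(tree$source)) {
    if (!is.na(refpos[s])) next
    b <- bubid[s]
    anc <- if (is.na(b)) NA_integer_ else {
      ref_ancestor(tree, match(b, tree$order), ref_bit)
    }
    if (is.na(anc)) next
    src <- tree$source[match(anc, tree$order)]
    refpos[s] <- refpos[src] + (offsets$final[s] - offsets$final[src])
  }
  tibble::tibble(node = seq_len(nn), refpos = refpos, exact = exact)
}

#' Transform node variants to locus variants
#'
#' For every typed out-branch the reference (or baseline) and an affected
#' sample are walked between the source and the sink of the deepest bubble
#' joining them; the two spelled segments are trimmed (common suffix, then
#' common prefix keeping a left anchor) into VCF-style `REF`/`ALT` alleles
#' with a 1-based position. Alleles of 50 bp or more are outside the
#' small-indel scope and are skipped with a warning.
#'
#' @param graph the `cdbg`.
#' @param tree [bubble_tree()] result.
#' @param offsets [node_offsets()] result.
#' @param node_variants output of the two detection passes.
#' @param refmap [reference_positions()] result.
#' @param ref_id reference sample id.
#' @param max_allele maximum allele length (exclusive bound 50).
#' @return tibble of class `variant_calls`, sorted by `refpos`: `refpos`,
#'   `ref`, `alt`, `vartype`, `affected_color`, `affected_color_str`,
#'   `samples`, `source_kmer`, `exact`.
#' @export
node_to_locus <- function(graph, tree, offsets, node_variants, refmap,
                          ref_id, max_allele = 50L) {
  if (nrow(node_variants) == 0) {
    return(empty_calls())
  }
  ref_bit <- ref_mask(graph, ref_id)
  ref_idx <- match(ref_id, graph$samples)
  k <- graph$k
  acc <- list()
  skipped <- 0L
  refpos_of <- refmap$refpos[order(refmap$node)]
  rows_by_source <- split(seq_len(nrow(tree)), tree$source)
  pathpos <- lapply(graph$sample_paths, function(p) {
    x <- integer(length(graph$nodes))
    x[p] <- seq_along(p)
    x
  })
  nv_source <- node_variants$source
  nv_bcol <- node_variants$branch_color
  nv_has_ref <- node_variants$has_ref
  nv_type <- node_variants$vartype
  for (i in seq_len(nrow(node_variants))) {
    s <- nv_source[i]
    alt_sample <- color_samples(nv_bcol[i], graph$n_samples)[1]
    base_sample <- if (nv_has_ref[i]) ref_idx else {
      g <- graph$adj_out_color[[s]]
      cand <- g[bitwAnd(g, nv_bcol[i]) == 0L]
      if (length(cand) == 0) next
      pc <- color_popcount(cand, graph$n_samples)
      color_samples(cand[which.max(pc)], graph$n_samples)[1]
    }
    need <- bitwOr(bitwShiftL(1L, alt_sample - 1L),
                   bitwShiftL(1L, base_sample - 1L))
    cand <- rows_by_source[[as.character(s)]]
    cand <- cand[bitwAnd(need, tree$color[cand]) == need]
    if (length(cand) == 0) next
    cand <- cand[which.min(lengths(tree$nodes[cand]))]
    t <- tree$sink[cand]
    spell <- function(m) {
      p <- graph$sample_paths[[m]]
      spell_path(graph, p[pathpos[[m]][s]:pathpos[[m]][t]])
    }
    a <- spell(base_sample)    # baseline (reference when available)
    b <- spell(alt_sample)
    al <- trim_alleles(a, b)
    if (is.null(al)) next      # identical spellings
    p0 <- refpos_of[s]
    if (is.na(p0)) next                # no reference projection at all
    pos <- p0 - k + 1L + al$lead
    # a length-L indel spells an (L+1)-character anchored allele; only
    # events of 50 bp or more are out of scope
    if (max(nchar(al$ref), nchar(al$alt)) > max_allele) {
      skipped <- skipped + 1L
      next
    }
    acc[[length(acc) + 1L]] <- list(
      refpos = pos, ref = al$ref, alt = al$alt, vartype = nv_type[i],
      affected_color = nv_bcol[i],
      source_kmer = graph$nodes[s], exact = nv_has_ref[i])
  }
  if (skipped > 0) {
    warning(skipped, " variant(s) with alleles of 50 bp or more skipped")
  }
  if (length(acc) == 0) return(empty_calls())
  out <- dplyr::bind_rows(acc)
  out$affected_color_str <- color_to_string(out$affected_color,
                                            graph$n_samples)
  out$samples <- vapply(out$affected_color, function(cc) {
    paste(graph$samples[color_samples(cc, graph$n_samples)], collapse = ",")
  }, character(1))
  out <- dplyr::arrange(out, refpos, ref, alt)
  out <- out[, c("refpos", "ref", "alt", "vartype", "affected_color",
                 "affected_color_str", "samples", "source_kmer", "exact")]
  class(out) <- c("variant_calls", class(out))
  out
}

empty_calls <- function() {
  out <- tibble::tibble(refpos = integer(), ref = character(),
                        alt = character(), vartype = integer(),
                        affected_color = integer(),
                        affected_color_str = character(),
                        samples = character(), source_kmer = character(),
                        exact = logical())
  class(out) <- c("variant_calls", class(out))
  out
}

# trim to minimal left-anchored alleles; lead = retained prefix length
trim_alleles <- function(a, b) {
  if (a == b) return(NULL)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  while (length(av) > 1 && length(bv) > 1 &&
         av[length(av)] == bv[length(bv)]) {
    av <- av[-length(av)]; bv <- bv[-length(bv)]
  }
  lead <- 0L
  while (length(av) > 1 && length(bv) > 1 && av[1] == bv[1]) {
    av <- av[-1]; bv <- bv[-1]; lead <- lead + 1L
  }
  if (length(av) == length(bv) && length(av) >= 1 && av[1] == bv[1] &&
      length(av) > 1) {
    # same length, anchored: drop the shared anchor too (pure MNP/SNP)
    av <- av[-1]; bv <- bv[-1]; lead <- lead + 1L
  }
  list(ref = paste(av, collapse = ""), alt = paste(bv, collapse = ""),
       lead = lead)
}

#' Call substitutions and small indels from the graph
#'
#' Runs the node-based detection end to end: gap collection at bubble
#' sources, the reference pass, the non-reference pass, reference position
#' determination, and node-to-locus transformation.
#'
#' @param graph an acyclic `cdbg`.
#' @param ref_id reference sample id (must be one of the graph's samples).
#' @param tree,offsets optional precomputed [bubble_tree()] and
#'   [node_offsets()] results.
#' @return a `variant_calls` tibble (see [node_to_locus()]); the node-level
#'   variants and the reference position map are attached as attributes
#'   `node_variants` and `refmap`.
#' @export
call_variants <- function(graph, ref_id, tree = NULL, offsets = NULL) {
  if (is.null(offsets)) offsets <- node_offsets(graph)
  if (is.null(tree)) tree <- bubble_tree(find_bubbles(graph), graph)
  gaps <- collect_gaps(graph, offsets, tree)
  nv <- nvd_reference_pass(graph, tree, gaps, ref_id)
  nv <- nvd_nonreference_pass(graph, tree, gaps, nv, ref_id)
  refmap <- reference_positions(graph, tree, offsets, ref_id)
  calls <- node_to_locus(graph, tree, offsets, nv, refmap, ref_id)
  attr(calls, "node_variants") <- nv
  attr(calls, "refmap") <- refmap
  calls
}

#' Write calls as a minimal VCF 4.2
#'
#' One record per call; `INFO` carries `VT` (1 substitution, 2 deletion,
#' 3 insertion, 4 unsure indel), `COLOR` (affected samples as a 0/1
#' string) and `APPROX=1` when the position was inferred through the
#' bubble forest rather than read off the reference path. `GT` is 1 for
#' affected samples, 0 otherwise.
#'
#' @param calls a `variant_calls` tibble.
#' @param path output file.
#' @param graph the `cdbg` (for sample names); or pass `samples`.
#' @param samples character vector of sample names.
#' @param ref_id reference sample id (written in the header).
#' @export
write_vcf <- function(calls, path, graph = NULL, samples = NULL,
                      ref_id = NULL) {
  if (is.null(samples)) samples <- graph$samples
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=panbubble",
    if (!is.null(ref_id)) paste0("##reference=", ref_id),
    '##INFO=<ID=VT,Number=1,Type=Integer,Description="Variant type: 1 substitution, 2 deletion, 3 insertion, 4 unsure indel">',
    '##INFO=<ID=COLOR,Number=1,Type=String,Description="Affected samples as 0/1 string">',
    '##INFO=<ID=APPROX,Number=0,Type=Flag,Description="Position inferred through the bubble forest">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="1 when the sample carries the alternate allele">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- hdr
  if (nrow(calls) > 0) {
    gt <- vapply(seq_len(nrow(calls)), function(i) {
      aff <- color_samples(calls$affected_color[i], length(samples))
      paste(ifelse(seq_along(samples) %in% aff, "1", "0"), collapse = "\t")
    }, character(1))
    info <- paste0("VT=", calls$vartype, ";COLOR=", calls$affected_color_str,
                   ifelse(calls$exact, "", ";APPROX"))
    lines <- c(lines, paste(ref_id %||% "graph", calls$refpos, ".",
                            calls$ref, calls$alt, ".", "PASS", info, "GT",
                            gt, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
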