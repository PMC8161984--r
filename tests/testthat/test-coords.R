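trio_ctx <- function() {
  g <- trio_graph()
  off <- node_offsets(g)
  tree <- bubble_tree(find_bubbles(g), g)
  list(g = g, off = off, tree = tree)
}

test_that("base triples reproduce the worked example", {
  ctx <- trio_ctx()
  bl <- base_locations(ctx$g, ctx$tree, ctx$off)
  row <- function(km) bl[match(km, ctx$g$nodes), ]
  expect_equal(unlist(row("TCA")[, c("position", "bubid")]),
               c(position = 3L, bubid = 4L))
  expect_equal(row("TCA")$basecolor, "111")
  expect_equal(unlist(row("ATG")[, c("position", "bubid")]),
               c(position = 13L, bubid = 1L))
  expect_equal(row("ATG")$basecolor, "100")
  expect_equal(unlist(row("CCC")[, c("position", "bubid")]),
               c(position = 17L, bubid = -1L))
  expect_equal(row("CCC")$basecolor, "111")
  expect_equal(unlist(row("GGG")[, c("position", "bubid")]),
               c(position = 7L, bubid = 2L))
  # representative mode names a carrying sample instead
  blr <- base_locations(ctx$g, ctx$tree, ctx$off, representative = TRUE)
  expect_equal(blr$basecolor[match("ATG", ctx$g$nodes)], "s1")
})

test_that("base triples are one-to-one with nodes and monotone along paths", {
  for (seed in 1:4) {
    gen <- rand_population(n_samples = 3, len = 250, snp = 5, del = 1,
                           seed = 800 + seed)
    g <- build_cdbg(gen, k = 14, seed = seed)
    off <- node_offsets(g)
    tree <- bubble_tree(find_bubbles(g), g)
    bl <- base_locations(g, tree, off)
    key <- paste(bl$position, bl$bubid, bl$basecolor)
    expect_equal(anyDuplicated(key), 0L)          # injective
    rev_lookup <- match(key, key)
    expect_identical(bl$node[rev_lookup], bl$node) # reverse lookup works
    for (p in g$sample_paths) {
      expect_true(all(diff(bl$position[p]) > 0))   # strictly increasing
    }
  }
})

test_that("path six-tuples reproduce the worked example", {
  ctx <- trio_ctx()
  pa <- path_location(ctx$g, ctx$tree, ctx$off, "CAGGGTGTA")
  expect_equal(unlist(pa),
               c(startpos = 5, startbub = 4, endpos = 11, endbub = 2,
                 pathbub = 5, pathcolor = "100"),
               ignore_attr = TRUE)
  expect_equal(pa$pathcolor, "100")
  pb <- path_location(ctx$g, ctx$tree, ctx$off, "GGGAGTA")
  expect_equal(c(pb$startpos, pb$startbub, pb$endpos, pb$endbub, pb$pathbub),
               c(7, 2, 11, 2, 2))
  expect_equal(pb$pathcolor, "010")
  pc <- path_location(ctx$g, ctx$tree, ctx$off, "ATAACCC")
  expect_equal(c(pc$startpos, pc$startbub, pc$endpos, pc$endbub, pc$pathbub),
               c(13, 1, 17, 1, 1))
  expect_equal(pc$pathcolor, "011")
  # a length-1 path collapses to the base triple
  p1 <- path_location(ctx$g, ctx$tree, ctx$off, match("TCA", ctx$g$nodes))
  expect_equal(c(p1$startpos, p1$startbub, p1$endpos, p1$endbub, p1$pathbub),
               c(3, 4, 3, 4, 4))
  expect_equal(p1$pathcolor, "111")
  expect_error(path_location(ctx$g, ctx$tree, ctx$off,
                             match(c("TCA", "GGG"), ctx$g$nodes)),
               "connected")
})

test_that("a path spanning two roots reports pathbub as minus the span", {
  ctx <- trio_ctx()
  # GTA .. TAT crosses from the bub5 complex into bub1
  p <- path_location(ctx$g, ctx$tree, ctx$off, "CAGGGTGTATG")
  expect_equal(p$pathbub, -2L)
})

test_that("path relations follow the interval/color rules", {
  ctx <- trio_ctx()
  pa <- path_location(ctx$g, ctx$tree, ctx$off, "CAGGGTGTA")
  pb <- path_location(ctx$g, ctx$tree, ctx$off, "GGGAGTA")
  pc <- path_location(ctx$g, ctx$tree, ctx$off, "ATAACCC")
  expect_equal(relate_paths(pa, pb, ctx$tree, 3)$relation, "intersection")
  expect_equal(relate_paths(pa, pc, ctx$tree, 3)$relation, "separation")
  expect_equal(relate_paths(pb, pc, ctx$tree, 3)$relation, "separation")
  expect_equal(relate_paths(pa, pa, ctx$tree, 3)$relation, "inclusion")
  # disjoint colors with intersecting intervals: context bubble supplied
  rel <- relate_paths(pa, pb, ctx$tree, 3)
  expect_equal(rel$context_bubble, 5L)   # colors 100 vs 010 are disjoint
  expect_equal(rel$context_color, "111")
})

test_that("relation is a trichotomy and inclusion nests both axes", {
  ctx <- trio_ctx()
  paths <- list("CAGGGTGTA", "GGGAGTA", "ATAACCC", "TCACGGG", "GTATGACC",
                "TATAACC")
  locs <- lapply(paths, function(p)
    path_location(ctx$g, ctx$tree, ctx$off, p))
  for (i in seq_along(locs)) {
    for (j in seq_along(locs)) {
      rel <- relate_paths(locs[[i]], locs[[j]], ctx$tree, 3)
      expect_true(rel$relation %in%
                    c("separation", "intersection", "inclusion"))
      if (rel$relation == "inclusion") {
        i1 <- c(locs[[i]]$startpos, locs[[i]]$endpos)
        i2 <- c(locs[[j]]$startpos, locs[[j]]$endpos)
        expect_true((i1[1] <= i2[1] && i2[2] <= i1[2]) ||
                      (i2[1] <= i1[1] && i1[2] <= i2[2]))
      }
    }
  }
})

test_that("VCF records map to bubbles or bridges on the reference path", {
  ctx <- trio_ctx()
  # reference s2 = CACGGGAGTATAACCC; position 5 sits in a bubble,
  # position 16 on the trailing bridge (the k-mer CCC past the last sink)
  vcf <- tibble::tibble(POS = c(5L, 16L), REF = c("G", "C"),
                        ALT = c("T", "A"))
  out <- map_vcf(ctx$g, ctx$tree, ctx$off, vcf, ref_id = "s2")
  expect_equal(nrow(out), 2L)
  expect_true(out$in_bubble[1])
  expect_false(out$in_bubble[2])
  expect_equal(out$bubid[2], -1L)
  # empty input gives an empty table
  empty <- map_vcf(ctx$g, ctx$tree, ctx$off,
                   tibble::tibble(POS = integer()), ref_id = "s2")
  expect_equal(nrow(empty), 0L)
  # beyond-reference positions are flagged, not fatal
  expect_warning(
    far <- map_vcf(ctx$g, ctx$tree, ctx$off,
                   tibble::tibble(POS = 400L), ref_id = "s2"),
    "beyond")
  expect_true(is.na(far$node[1]))
})

test_that("GTF intervals count the bubbles they touch", {
  ctx <- trio_ctx()
  gtf <- tibble::tibble(feature = c("geneA", "geneB"),
                        start = c(2L, 16L), end = c(9L, 16L))
  out <- map_gtf(ctx$g, ctx$tree, ctx$off, gtf, ref_id = "s2")
  expect_equal(nrow(out), 2L)
  expect_gte(out$n_bubbles[1], 2L)   # spans the nested complex
  expect_true(out$on_bridge_only[2]) # trailing bridge only
})
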