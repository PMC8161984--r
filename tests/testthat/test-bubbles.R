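test_that("the worked example yields the five printed bubbles in order", {
  g <- trio_graph()
  bb <- find_bubbles(g)
  expect_equal(nrow(bb), 5L)
  expect_equal(bb$source_kmer, c("TAT", "GGG", "CAC", "TCA", "TCA"))
  expect_equal(bb$sink_kmer, c("ACC", "GTA", "GTA", "GGG", "GTA"))
  expect_equal(bb$color_str, c("111", "110", "011", "110", "111"))
  expect_equal(bb$is_simple, c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("verify_bubble accepts the printed triples and rejects non-bubbles", {
  g <- trio_graph()
  idx <- function(km) match(km, g$nodes)
  expect_true(verify_bubble(g, idx("TAT"), idx("ACC"), "111"))
  expect_true(verify_bubble(g, idx("TCA"), idx("GTA"), "111"))
  expect_true(verify_bubble(g, idx("GGG"), idx("GTA"), "110"))
  expect_true(verify_bubble(g, idx("CAC"), idx("GTA"), "011"))
  # an interior sink also matching the source breaks minimality
  expect_false(verify_bubble(g, idx("TCA"), idx("GTA"), "110"))
  # wrong color: sample 3 alone never branches at GGG
  expect_false(verify_bubble(g, idx("GGG"), idx("GTA"), "001"))
  expect_error(verify_bubble(g, idx("TCA"), idx("GTA"), "000"), "non-empty")
})

test_that("emitted bubbles all pass the independent checker on random graphs", {
  skip_if_not_installed("igraph")
  n_checked <- 0L
  for (seed in 1:15) {
    gen <- rand_population(n_samples = 2 + seed %% 4, len = 200 + 25 * seed,
                           snp = 5, del = 1, ins = 1, seed = 400 + seed)
    g <- build_cdbg(gen, k = 14, seed = seed)
    bb <- find_bubbles(g)
    for (i in seq_len(nrow(bb))) {
      expect_true(oracle_verify_bubble(g, bb$source[i], bb$sink[i],
                                       bb$color[i]),
                  label = sprintf("seed %d bubble %d", seed, i))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 20)
})

test_that("full-color bubbles coincide with plain superbubbles", {
  skip_if_not_installed("igraph")
  # at the full color set the induced subgraph is the whole graph, so the
  # emitted bubbles whose color is the full set must be exactly the plain
  # superbubbles (Definition 1) found by an exhaustive enumerator
  for (seed in 1:5) {
    gen <- rand_population(n_samples = 2, len = 220, snp = 4,
                           seed = 500 + seed)
    g <- build_cdbg(gen, k = 12, seed = seed)
    bb <- find_bubbles(g)
    fullc <- color_from_string("11")
    mono <- bb[bb$color == fullc, ]
    ora <- oracle_enumerate_bubbles(g, fullc)
    expect_setequal(paste(mono$source, mono$sink),
                    vapply(ora, function(p) paste(p[1], p[2]), character(1)))
  }
})

test_that("every whole-graph superbubble pair is found at some color", {
  skip_if_not_installed("igraph")
  # (s,t) pairs valid at the full color set must be discovered; the
  # emitted triple carries color(s) & color(t), the canonical color
  for (seed in 1:8) {
    gen <- rand_population(n_samples = 4, len = 150, snp = 3, seed = 600 + seed)
    g <- build_cdbg(gen, k = 12, seed = seed)
    bb <- find_bubbles(g)
    fullc <- color_from_string(strrep("1", 4))
    ora <- oracle_enumerate_bubbles(g, fullc)
    got <- paste(bb$source, bb$sink)
    for (p in ora) {
      expect_true(paste(p[1], p[2]) %in% got,
                  label = sprintf("seed %d pair %s-%s", seed, p[1], p[2]))
      i <- match(paste(p[1], p[2]), got)
      expect_equal(bb$color[i],
                   bitwAnd(g$node_color[p[1]], g$node_color[p[2]]))
    }
  }
})

test_that("the forest reproduces the printed parentage and is a proper forest", {
  g <- trio_graph()
  tree <- bubble_tree(find_bubbles(g), g)
  expect_equal(tree$parent, c(NA, 5L, 5L, 5L, NA))
  expect_equal(tree$level, c(1L, 2L, 2L, 2L, 1L))
  expect_true(all(tree$color_str[tree$is_root] == "111"))
  # order(child) < order(parent), one parent per bubble
  kids <- which(!is.na(tree$parent))
  expect_true(all(tree$order[kids] < tree$parent[kids]))
})

test_that("forest invariants hold on random graphs", {
  for (seed in 1:10) {
    gen <- rand_population(n_samples = 3 + seed %% 3, len = 300, snp = 6,
                           del = 1, seed = 700 + seed)
    g <- build_cdbg(gen, k = 14, seed = seed)
    tree <- bubble_tree(find_bubbles(g), g)
    kids <- which(!is.na(tree$parent))
    expect_true(all(tree$order[kids] < tree$parent[kids]))
    expect_true(all(tree$level[tree$is_root] == 1L))
    for (i in kids) {
      p <- match(tree$parent[i], tree$order)
      expect_equal(tree$level[i], tree$level[p] + 1L)
      # inclusion: child node set inside parent's, child color inside parent's
      expect_true(all(tree$nodes[[i]] %in% tree$nodes[[p]]))
      expect_true(bitwAnd(tree$color[i], tree$color[p]) == tree$color[i])
    }
  }
})

test_that("bubble relations classify by node and color intersections", {
  g <- trio_graph()
  tree <- bubble_tree(find_bubbles(g), g)
  expect_equal(relate_bubbles(tree, 2, 5), "inclusion")
  expect_equal(relate_bubbles(tree, 1, 5), "separation")  # disjoint nodes
  expect_equal(relate_bubbles(tree, 2, 3), "intersection") # share sink GTA
  expect_equal(relate_bubbles(tree, 4, 2), "intersection") # share GGG
})

test_that("simple decomposition returns two-path bubbles that verify", {
  g <- trio_graph()
  tree <- bubble_tree(find_bubbles(g), g)
  # an already-simple bubble decomposes to itself
  d2 <- decompose_simple(g, tree, 2)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$source_kmer, "GGG")
  expect_equal(d2$sink_kmer, "GTA")
  # the non-simple root decomposes into pairwise units
  d5 <- decompose_simple(g, tree, 5)
  expect_gt(nrow(d5), 1)
  for (i in seq_len(nrow(d5))) {
    # each unit has exactly two paths between its endpoints for its pair
    expect_true(d5$source[i] != d5$sink[i])
  }
  # a three-branch multiallelic site yields the three pairwise units
  gen <- tibble::tibble(sample_id = c("r", "a", "b"),
                        sequence = c("ACGTATGCA", "ACGTCTGCA", "ACGTTTGCA"))
  gm <- build_cdbg(gen, k = 3, anchors = c(head = "CCC", tail = "GGG"))
  tm <- bubble_tree(find_bubbles(gm), gm)
  dm <- decompose_simple(gm, tm)
  expect_equal(nrow(dm), 3L)
})

test_that("CST and CSDI files round-trip and recount correctly", {
  g <- trio_graph()
  tree <- bubble_tree(find_bubbles(g), g)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cst(tree, f)
  back <- read_cst(f)
  expect_equal(nrow(back), nrow(tree))
  expect_equal(back$order, tree$order)
  expect_equal(back$source, tree$source_kmer)
  expect_equal(back$color, tree$color_str)
  expect_equal(back$parent, tree$parent)
  expect_equal(back$level, tree$level)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_csdi(tree, g, f2)
  csdi <- readr::read_tsv(f2, show_col_types = FALSE)
  expect_equal(nrow(csdi), nrow(tree))
  expect_equal(csdi$n_nodes, lengths(tree$nodes))
  # recount bubble 2 directly: GGG,GGT,GTG,TGT,GGA,GAG,AGT,GTA
  expect_equal(csdi$n_nodes[2], 8L)
})
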