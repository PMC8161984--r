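test_that("gaps are zero in substitution bubbles and positive on short branches", {
  g <- trio_graph()
  off <- node_offsets(g)
  tree <- bubble_tree(find_bubbles(g), g)
  gaps <- collect_gaps(g, off, tree)
  # the all-sample substitution bubble: both branches gap 0
  tat <- gaps[gaps$source_kmer == "TAT", ]
  expect_equal(tat$gap, c(0L, 0L))
  # the 1 bp deletion: gap 1 on the deleted branch (sample 1), attached at
  # the source TCA, not at the sink GGG
  tca <- gaps[gaps$source_kmer == "TCA", ]
  expect_setequal(tca$gap, c(1L, 0L))
  expect_equal(tca$branch_color_str[tca$gap == 1L], "100")
  expect_equal(unique(tca$max_gap), 1L)
  expect_false("GGG" %in% gaps$source_kmer[gaps$gap > 0])
})

test_that("the worked example calls match the manual alignments", {
  g <- trio_graph()
  calls <- call_variants(g, ref_id = "s2")
  # manual truth vs reference s2 = CACGGGAGTATAACCC:
  #   s1 deletes the C at 3 (left-anchored at 2), carries T at 7, G at 12
  #   s3 replaces GGGA (4..7) by AAGC
  expect_equal(nrow(calls), 4L)
  expect_equal(calls$refpos, c(2L, 4L, 7L, 12L))
  expect_equal(calls$ref, c("AC", "GGGA", "A", "A"))
  expect_equal(calls$alt, c("A", "AAGC", "T", "G"))
  expect_equal(calls$vartype, c(2L, 1L, 1L, 1L))
  expect_equal(calls$samples, c("s1", "s3", "s1", "s1"))
  expect_true(all(calls$exact))
})

test_that("a 3 bp deletion is typed 2 with correct left-anchored alleles", {
  ref <- "ATTACGGATCGATTGCCATAGCAT"
  alt <- paste0(substr(ref, 1, 8), substr(ref, 12, 24))  # drop bases 9..11
  gen <- tibble::tibble(sample_id = c("ref", "alt"), sequence = c(ref, alt))
  g <- build_cdbg(gen, k = 5, seed = 3)
  calls <- call_variants(g, ref_id = "ref")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$vartype, 2L)
  expect_equal(calls$refpos, 8L)
  expect_equal(calls$ref, substr(ref, 8, 11))
  expect_equal(calls$alt, substr(ref, 8, 8))
  expect_equal(calls$samples, "alt")
})

test_that("an insertion is typed 3 with the inserted bases in the alt allele", {
  ref <- "ATTACGGATCGATTGCCATAGCAT"
  alt <- paste0(substr(ref, 1, 10), "TTTT", substr(ref, 11, 24))
  gen <- tibble::tibble(sample_id = c("ref", "alt"), sequence = c(ref, alt))
  g <- build_cdbg(gen, k = 5, seed = 3)
  calls <- call_variants(g, ref_id = "ref")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$vartype, 3L)
  expect_equal(calls$refpos, 10L)
  expect_equal(calls$ref, substr(ref, 10, 10))
  expect_equal(calls$alt, paste0(substr(ref, 10, 10), "TTTT"))
})

test_that("a substitution nested inside an insertion resolves via the forest", {
  # three samples: ref; X carries an 8 bp insertion; Y carries the same
  # insertion with one base changed inside it
  ref <- "ATTACGGATCGATTGCCATAGCATGGATC"
  ins1 <- "GTGTCCGA"
  ins2 <- "GTGACCGA"                 # substitution at the 4th inserted base
  x <- paste0(substr(ref, 1, 12), ins1, substr(ref, 13, 29))
  y <- paste0(substr(ref, 1, 12), ins2, substr(ref, 13, 29))
  gen <- tibble::tibble(sample_id = c("ref", "x", "y"),
                        sequence = c(ref, x, y))
  g <- build_cdbg(gen, k = 6, seed = 11)
  calls <- call_variants(g, ref_id = "ref")
  nv <- attr(calls, "node_variants")
  # the outer source is an insertion affecting both alternates; the
  # inserted tail GA matches the reference's CGA so the left-aligned
  # anchor shifts from 12 to 9
  expect_true(any(calls$vartype == 3L & calls$affected_color_str == "011"))
  ins_call <- calls[calls$vartype == 3L, ][1, ]
  expect_equal(ins_call$refpos, 9L)
  # the inner (no-reference) bubble resolves to a substitution between x, y
  expect_true(any(nv$vartype == 1L & !nv$has_ref))
  inner <- calls[!calls$exact, ]
  expect_true(any(inner$vartype == 1L))
})

test_that("non-reference pass falls back to type 4 on ambiguity and warns", {
  g <- trio_graph()
  off <- node_offsets(g)
  tree <- bubble_tree(find_bubbles(g), g)
  gaps <- collect_gaps(g, off, tree)
  # all bubbles contain s2: the non-reference pass is a no-op
  nv1 <- nvd_reference_pass(g, tree, gaps, "s2")
  nv <- nvd_nonreference_pass(g, tree, gaps, nv1, "s2")
  expect_identical(nv, nv1)
})

test_that("reference positions are exact on the reference path", {
  g <- trio_graph()
  off <- node_offsets(g)
  tree <- bubble_tree(find_bubbles(g), g)
  rm_ <- reference_positions(g, tree, off, "s2")
  p <- g$sample_paths[[2]]
  # node i on the reference path ends at reference coordinate i - 1
  expect_equal(rm_$refpos[p], seq_along(p) - 1L)
  expect_true(all(rm_$exact[p]))
  # off-reference source CAC? (CAC is on s2's path); ATG is off-reference
  atg <- match("ATG", g$nodes)
  expect_false(rm_$exact[atg])
})

test_that("VCF output is well-formed and empty calls give a header-only file", {
  g <- trio_graph()
  calls <- call_variants(g, ref_id = "s2")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, f, graph = g, ref_id = "s2")
  lines <- readLines(f)
  expect_equal(sum(!startsWith(lines, "#")), nrow(calls))
  expect_true(any(startsWith(lines, "##fileformat=VCFv4.2")))
  body <- strsplit(lines[!startsWith(lines, "#")], "\t")
  expect_true(all(lengths(body) == 9 + 3))
  # GT columns follow the affected color
  del <- body[[1]]
  expect_equal(del[10:12], c("1", "0", "0"))
  # header-only when there is nothing to report
  f2 <- withr::local_tempfile(fileext = ".vcf")
  gen <- tibble::tibble(sample_id = c("a", "b"),
                        sequence = c("ACGTTGCA", "ACGTTGCA"))
  g2 <- build_cdbg(gen, k = 3, anchors = c(head = "CCC", tail = "GGG"))
  calls2 <- call_variants(g2, ref_id = "a")
  expect_equal(nrow(calls2), 0L)
  write_vcf(calls2, f2, graph = g2, ref_id = "a")
  expect_true(all(startsWith(readLines(f2), "#")))
})

test_that("the small-indel scope boundary falls between 49 and 50 bp", {
  withr::with_seed(31, {
    ref <- paste(sample(c("A", "C", "G", "T"), 700, TRUE), collapse = "")
  })
  # 49 bp deletion: in scope, called with a 50-character anchored allele
  del49 <- paste0(substr(ref, 1, 300), substr(ref, 350, 700))
  g <- build_cdbg(tibble::tibble(sample_id = c("ref", "alt"),
                                 sequence = c(ref, del49)),
                  k = 15, seed = 2)
  calls <- call_variants(g, ref_id = "ref")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$vartype, 2L)
  expect_equal(nchar(calls$ref), 50L)
  # 50 bp deletion: out of scope, skipped with a warning
  del50 <- paste0(substr(ref, 1, 300), substr(ref, 351, 700))
  g2 <- build_cdbg(tibble::tibble(sample_id = c("ref", "alt"),
                                  sequence = c(ref, del50)),
                   k = 15, seed = 2)
  expect_warning(calls2 <- call_variants(g2, ref_id = "ref"), "50 bp")
  expect_equal(nrow(calls2), 0L)
})

test_that("three planted variants on a 1 kb reference are recovered exactly", {
  sim <- simulate_population(n_samples = 3, ref_length = 1000, snp = 1,
                             del = 1, ins = 1, indel_len = c(3L, 6L),
                             seed = 42)
  gen <- sim$genomes
  g <- build_cdbg(gen, k = 15, seed = 42)
  calls <- call_variants(g, ref_id = "ref")
  ev_loc <- evaluate_calls(calls, sim$truth, mode = "location")
  ev_typ <- evaluate_calls(calls, sim$truth, mode = "type")
  expect_equal(ev_loc$precision, 1)
  expect_equal(ev_loc$recall, 1)
  expect_equal(ev_typ$precision, 1)
  expect_equal(ev_typ$recall, 1)
})
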