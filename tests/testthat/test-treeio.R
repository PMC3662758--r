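test_that("parse_newick builds correct trees from minimal cases", {
  tr <- parse_newick("(A:1.0,B:1.0):0.0;")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(tr$Nnode, 1L)
  expect_equal(sort(tr$edge.length), c(1, 1))
  expect_equal(tr$root.edge, 0)

  tr2 <- parse_newick("((A:1,B:1):1,C:2);")
  d <- ape::node.depth.edgelength(tr2)
  expect_equal(d[match("A", tr2$tip.label)], 2)
  expect_equal(d[match("C", tr2$tip.label)], 2)
  # child order preserved as written
  expect_equal(tr2$tip.label, c("A", "B", "C"))
})

test_that("quoted labels and underscores survive writing bit-exactly", {
  s <- "('sp. nov.':1,B_x:2);"
  tr <- parse_newick(s)
  expect_equal(tr$tip.label, c("sp. nov.", "B_x"))
  expect_equal(write_newick(tr), s)
  # '' escapes a quote inside a quoted label
  tr2 <- parse_newick("('it''s':1,B:1);")
  expect_equal(tr2$tip.label[1], "it's")
  expect_equal(parse_newick(write_newick(tr2))$tip.label[1], "it's")
})

test_that("malformed input is rejected with the offending position", {
  expect_error(parse_newick("((A,B),C;"), "position")
  expect_error(parse_newick("(A,B))"), ";")
  expect_error(parse_newick("(A:1,A:2);"), "duplicate tip label 'A'")
  expect_error(parse_newick("(A:-1,B:1);"), "negative branch length")
  expect_error(parse_newick("(A:x,B:1);"), "invalid branch length")
  expect_error(parse_newick("(A,B); junk"), "end in ';'")
  expect_error(parse_newick("(A,B);;"), "trailing")
})

test_that("newick round-trip is isomorphic with equal branch lengths", {
  set.seed(42)
  for (i in 1:100) {
    tr <- simulate_yule(sample(4:30, 1))
    back <- parse_newick(write_newick(tr))
    expect_true(trees_isomorphic(tr, back))
  }
})

test_that("NEXUS translate tables are applied and order preserved", {
  doc <- paste("#NEXUS", "BEGIN TREES;", "TRANSLATE", "1 A,", "2 B;",
               "TREE one = (1:1,2:1);", "END;", sep = "\n")
  s <- parse_nexus_trees(doc)
  expect_equal(length(s), 1L)
  expect_setequal(s$trees[[1]]$tip.label, c("A", "B"))

  doc3 <- paste("#NEXUS", "BEGIN TREES;",
                "TREE STATE_0 = [&R] ((A:1,B:1):1,C:2);",
                "TREE STATE_100 = ((A:1,C:1):1,B:2);",
                "TREE STATE_200 = ((B:1,C:1):1,A:2);", "END;", sep = "\n")
  s3 <- parse_nexus_trees(doc3)
  expect_equal(length(s3), 3L)
  expect_equal(s3$provenance$generation, c(0L, 100L, 200L))
  expect_equal(s3$trees[[2]]$tip.label[1:2], c("A", "C"))

  expect_error(parse_nexus_trees(paste("#NEXUS", "BEGIN TREES;", "TRANSLATE 1 A;",
                                       "TREE t = (1:1,2:1);", "END;", sep = "\n")),
               "no mapping")
})

test_that("NEXUS write-then-read round-trips a simulated 50-tree sample", {
  set.seed(7)
  base <- simulate_yule(12)
  s <- perturb_tree_sample(base, 50, n_nni = 1)
  doc <- write_nexus_trees(s)
  s2 <- parse_nexus_trees(doc)
  expect_equal(length(s2), 50L)
  expect_equal(s2$provenance$generation, s$provenance$generation)
  for (i in c(1, 25, 50)) {
    expect_true(trees_isomorphic(s$trees[[i]], s2$trees[[i]]))
  }
  # independent reader agrees on labels and lengths
  f <- tempfile(fileext = ".trees")
  writeLines(doc, f)
  a <- ape::read.nexus(f)
  expect_equal(length(a), 50L)
  expect_setequal(a[[1]]$tip.label, base$tip.label)
  expect_equal(sort(a[[3]]$edge.length), sort(s$trees[[3]]$edge.length), tolerance = 1e-9)
})

test_that("posterior_sample_count follows the burn-in arithmetic", {
  expect_equal(posterior_sample_count(1, 1000, 100, 0), 10)
  expect_equal(posterior_sample_count(3, 10000, 100, 10000), 0)
  expect_error(posterior_sample_count(1, 1000, 300, 0), "divide")
  expect_error(posterior_sample_count(1, 1000, 100, 2000), "burnin")
  # counts over disjoint generation windows add up to the full count
  set.seed(1)
  for (i in 1:20) {
    interval <- sample(c(10, 50, 100), 1)
    chain <- interval * sample(5:50, 1)
    cut <- interval * sample(0:(chain / interval), 1)
    m <- sample(1:5, 1)
    expect_equal(posterior_sample_count(m, chain, interval, cut) +
                   posterior_sample_count(m, cut, interval, 0),
                 posterior_sample_count(m, chain, interval, 0))
  }
})

test_that("discard_burnin keeps exactly the post-burn-in trees", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  s <- tree_sample(rep(list(tr), 10), run = 1L, generation = seq(100, 1000, 100))
  expect_equal(length(discard_burnin(s, 500)), 5L)
  expect_equal(length(discard_burnin(s, 0)), 10L)
  s_none <- tree_sample(rep(list(tr), 2))
  expect_error(discard_burnin(s_none, 100), "provenance")
  # consistency with the closed-form count, multi-run
  s2 <- tree_sample(rep(list(tr), 20), run = rep(1:2, each = 10),
                    generation = rep(seq(100, 1000, 100), 2),
                    sample_interval = 100)
  expect_equal(length(discard_burnin(s2, 400)),
               posterior_sample_count(2, 1000, 100, 400))
})

test_that("tree_sample enforces shared tip sets and increasing generations", {
  t1 <- parse_newick("((A:1,B:1):1,C:2);")
  t2 <- parse_newick("((A:1,C:1):1,D:2);")
  expect_error(tree_sample(list(t1, t2)), "tip-label set")
  expect_error(tree_sample(rep(list(t1), 3), generation = c(100, 100, 200)),
               "strictly increasing")
})

test_that("prune_to preserves retained tip path lengths and is idempotent", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  p <- prune_to(tr, c("A", "C"))
  expect_setequal(p$tip.label, c("A", "C"))
  d <- ape::node.depth.edgelength(p)
  expect_equal(d[match("A", p$tip.label)], 2)
  expect_equal(d[match("C", p$tip.label)], 2)
  expect_identical(prune_to(tr, c("A", "B", "C")), tr)
  expect_error(prune_to(tr, c("A", "Z")), "unknown tip")
  expect_error(prune_to(tr, character(0)), "empty")

  set.seed(9)
  for (i in 1:50) {
    tr <- simulate_yule(sample(5:25, 1))
    keep <- sample(tr$tip.label, sample(2:4, 1))
    full_d <- ape::node.depth.edgelength(tr)
    p <- prune_to(tr, keep)
    stem <- if (is.null(p$root.edge)) 0 else p$root.edge
    pd <- ape::node.depth.edgelength(p) + stem
    for (tip in keep)
      expect_equal(pd[match(tip, p$tip.label)], full_d[match(tip, tr$tip.label)],
                   tolerance = 1e-9)
    expect_true(trees_isomorphic(p, prune_to(p, keep)))
  }
})
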