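test_that("phylogeny classes follow the topology taxonomy", {
  m <- function(...) {
    v <- c(...)
    matrix(v, ncol = 2, byrow = TRUE,
           dimnames = list(paste0("C", seq_len(length(v) / 2) - 1),
                           c("S1", "S2")))
  }
  expect_equal(make_tree(c(C0 = NA), m(1, 1))$class, "A")
  expect_equal(make_tree(c(C0 = NA, C1 = "C0"), m(1, 1, .6, .6))$class, "B")
  expect_equal(make_tree(c(C0 = NA, C1 = "C0", C2 = "C1"),
                         m(1, 1, .6, .6, .3, .3))$class, "C")
  expect_equal(make_tree(c(C0 = NA, C1 = "C0", C2 = "C1", C3 = "C1"),
                         m(1, 1, .8, .8, .5, .1, .1, .5))$class, "D")
  expect_equal(make_tree(c(C0 = NA, C1 = "C0", C2 = "C0"),
                         m(1, 1, .6, .1, .1, .6))$class, "E")
  expect_equal(make_tree(c(C0 = NA, C1 = "C0", C2 = "C1", C3 = "C1",
                           C4 = "C2", C5 = "C2"),
                         m(1, 1, .9, .9, .6, .2, .15, .6, .3, .05,
                           .2, .1))$class, "F")
})

test_that("reconstruction handles the canonical two- and three-cluster cases", {
  # unique chain
  tr <- reconstruct_tree(rbind(c(1, 1), c(0.5, 0.5)))
  expect_equal(tr$class, "B")
  expect_equal(unname(tr$parent["C1"]), "C0")
  expect_equal(tr$n_branching, 0L)

  # crossing subclones must branch from C0
  tr_e <- reconstruct_tree(rbind(c(1, 1), c(0.6, 0), c(0, 0.7)))
  expect_equal(tr_e$class, "E")
  expect_equal(unname(tr_e$parent[c("C1", "C2")]), c("C0", "C0"))

  # parsimony prefers the linear chain when both are admissible
  tr_c <- reconstruct_tree(rbind(c(1, 1), c(0.5, 0.5), c(0.4, 0.5)),
                           eps = 0.05)
  expect_equal(tr_c$n_branching, 0L)
  expect_equal(tr_c$class, "C")
})

test_that("reconstruction output is admissible with minimal branching", {
  set.seed(59)
  for (i in 1:30) {
    nc <- sample(2:5, 1)
    gt <- sample_clone_tree(nc, 2, seed = NULL, min_sep = 0.08)
    centres <- gt$ccf
    oracle <- brute_force_trees(centres, eps = 0.1)
    tr <- tryCatch(reconstruct_tree(centres, eps = 0.1),
                   clonearch_conflict = function(e) NULL)
    if (is.na(oracle$min_branch)) {
      expect_null(tr)
      next
    }
    expect_false(is.null(tr))
    expect_equal(tr$n_branching, oracle$min_branch)
    # sum rule holds on the returned tree
    for (v in tr$labels) {
      kids <- names(tr$parent)[!is.na(tr$parent) & tr$parent == v]
      if (!length(kids)) next
      expect_true(all(colSums(tr$ccf[kids, , drop = FALSE]) <=
                        tr$ccf[v, ] + 0.1 + 1e-9))
    }
  }
})

test_that("multiple near-clonal clusters merge into C0", {
  tr <- reconstruct_tree(rbind(K1 = c(1.02, 1.02), K2 = c(0.95, 1.2),
                               K3 = c(0.5, 0.5)),
                         n_mutations = c(K1 = 100, K2 = 10, K3 = 50))
  expect_equal(length(tr$labels), 2)
  expect_true("merged_root" %in% tr$flags)
  expect_equal(tr$class, "B")
})

test_that("a missing clonal cluster promotes the top shared cluster", {
  tr <- reconstruct_tree(rbind(c(0.8, 0.7), c(0.3, 0.3)))
  expect_true("promoted_root" %in% tr$flags)
  expect_equal(length(tr$labels), 2)
})

test_that("clone composition subtracts children from terminal fractions", {
  m <- matrix(c(1, 1, 0.6, 0.6), 2, 2, byrow = TRUE,
              dimnames = list(c("C0", "C1"), c("S1", "S2")))
  tr <- make_tree(c(C0 = NA, C1 = "C0"), m)
  comp <- clone_composition(tr, "S1")
  expect_equal(comp$terminal_fraction[comp$clone == "C0"], 0.4)
  expect_equal(comp$terminal_fraction[comp$clone == "C1"], 0.6)
  single <- make_tree(c(C0 = NA), matrix(c(1, 1), 1, 2,
                                         dimnames = list("C0", c("S1", "S2"))))
  expect_equal(clone_composition(single, "S1")$terminal_fraction, 1.0)
})

test_that("the relapse seed is the deepest shared ancestor of the post sample", {
  # post sample S2 is made up of C3 cells (terminal); C3 itself was absent
  # before treatment, so the seed is its parent C1, present pre and post
  m <- matrix(c(1, 1, 0.8, 0.95, 0.6, 0, 0.02, 0.9), 4, 2, byrow = TRUE,
              dimnames = list(c("C0", "C1", "C2", "C3"), c("S1", "S2")))
  tr <- make_tree(c(C0 = NA, C1 = "C0", C2 = "C1", C3 = "C1"), m)
  expect_equal(relapse_seed(tr, "S1", "S2"), "C1")
  # two post lineages branching at C0 share only C0
  m2 <- matrix(c(1, 1, 0.6, 0.45, 0.2, 0.5), 3, 2, byrow = TRUE,
               dimnames = list(c("C0", "C1", "C2"), c("S1", "S2")))
  tr2 <- make_tree(c(C0 = NA, C1 = "C0", C2 = "C0"), m2)
  expect_equal(relapse_seed(tr2, "S1", "S2"), "C0")
})

test_that("pair downscaling maximises subclonal complexity deterministically", {
  ps <- data.frame(sample1 = c("S1", "S1", "S2"),
                   sample2 = c("S2", "S3", "S3"),
                   n_subclones = c(1, 3, 1),
                   n_subclonal_mutations = c(40, 25, 60),
                   stringsAsFactors = FALSE)
  expect_equal(downscale_pairs(ps)$sample2, "S3")
  expect_equal(downscale_pairs(ps)$n_subclones, 3)
  ps$n_subclones <- c(2, 2, 2)
  expect_equal(downscale_pairs(ps)$n_subclonal_mutations, 60)
  expect_error(downscale_pairs(ps[0, ]), "pair")
  one <- ps[1, ]
  expect_equal(downscale_pairs(one)$sample1, "S1")
})

test_that("conflicting clusters rescale by integer multiplicity", {
  cen <- rbind(K1 = c(1, 1), K2 = c(2.02, 1.98))
  fix <- rescale_conflicting_clusters(cen)
  expect_equal(unname(fix$rescaled["K2"]), 2L)
  expect_equal(unname(fix$centres["K2", ]), c(1.01, 0.99))
  expect_length(rescale_conflicting_clusters(rbind(K1 = c(1, 1)))$rescaled, 0)
})

test_that("newick and JSON exports round-trip the topology", {
  skip_if_not_installed("ape")
  m <- matrix(c(1, 1, 0.7, 0.2, 0.1, 0.6), 3, 2, byrow = TRUE,
              dimnames = list(c("C0", "C1", "C2"), c("S1", "S2")))
  tr <- make_tree(c(C0 = NA, C1 = "C0", C2 = "C0"), m)
  nwk <- as_newick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, c("C1", "C2"))
  js <- jsonlite::fromJSON(tree_to_json(tr))
  expect_equal(js$class, "E")
  expect_equal(js$parent$C1, "C0")
})
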