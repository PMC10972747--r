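test_that("target classes round-trip through classification", {
  for (cls in names(N_CLONES_OF)) {
    ns <- if (cls == "F") 3 else 2
    for (sd in 1:8) {
      gt <- sample_clone_tree(N_CLONES_OF[[cls]], ns, target_class = cls,
                              seed = sd * 101 + match(cls, LETTERS))
      expect_identical(gt$class, cls)
    }
  }
  # repeated draws of one class all reclassify identically
  cls <- replicate(100, sample_clone_tree(3, 2, target_class = "E",
                                          seed = NULL)$class)
  expect_true(all(cls == "E"))
})

test_that("infeasible class requests raise explicit errors", {
  expect_error(sample_clone_tree(1, 2, target_class = "F"), "infeasible")
  expect_error(sample_clone_tree(3, 2, target_class = "A"), "infeasible")
  expect_error(sample_clone_tree(5, 2, target_class = "F"), "infeasible")
})

test_that("emitted CCF matrices satisfy the sum rule with C0 at 1", {
  set.seed(5)
  for (i in 1:20) {
    nc <- sample(1:6, 1)
    gt <- sample_clone_tree(nc, sample(1:3, 1), seed = NULL, min_sep = 0.02)
    expect_true(all(gt$ccf["C0", ] == 1))
    for (v in rownames(gt$ccf)) {
      kids <- names(gt$parent)[!is.na(gt$parent) & gt$parent == v]
      if (!length(kids)) next
      kid_sum <- colSums(gt$ccf[kids, , drop = FALSE])
      expect_true(all(kid_sum <= gt$ccf[v, ] + 1e-12))
    }
  }
})

test_that("fixed seed fixes every emitted table", {
  b1 <- simulate_patient(3, 2, target_class = "C", seed = 99)
  b2 <- simulate_patient(3, 2, target_class = "C", seed = 99)
  expect_identical(b1$mutations, b2$mutations)
  expect_identical(b1$segments, b2$segments)
  expect_identical(b1$purity, b2$purity)
  expect_identical(b1$truth$ccf, b2$truth$ccf)
})

test_that("diploid clonal mutations at purity 1 read VAF ~ 0.5", {
  gt <- sample_clone_tree(1, 1, seed = 3)
  gt$n_mutations["C0"] <- 3000L
  b <- emit_reads(gt, mean_depth = 1000, purity = 1, seed = 4)
  seg <- b$segments[b$segments$sample == "S1", ]
  dip <- seg[seg$major_cn == 1 & seg$minor_cn == 1, ]
  on_dip <- vapply(seq_len(nrow(b$mutations)), function(i) {
    any(dip$chrom == b$mutations$chrom[i] &
          dip$start <= b$mutations$pos[i] & dip$end >= b$mutations$pos[i])
  }, logical(1))
  m1 <- b$truth$multiplicity[b$mutations$mutation_id] == 1L
  vaf <- b$mutations$alt_reads[on_dip & m1] / b$mutations$depth[on_dip & m1]
  expect_gt(sum(on_dip & m1), 100)
  expect_lt(abs(mean(vaf) - 0.5), 0.01)
})

test_that("a clone with zero CCF in a sample emits no variant reads there", {
  gt <- structure(list(
    parent = c(C0 = NA_character_, C1 = "C0"),
    ccf = matrix(c(1, 1, 0.6, 0), 2, 2, byrow = TRUE,
                 dimnames = list(c("C0", "C1"), c("S1", "S2"))),
    n_mutations = c(C0 = 50L, C1 = 50L),
    class = "B", samples = c("S1", "S2"), seed = 1
  ), class = "ground_truth")
  b <- emit_reads(gt, mean_depth = 120, seed = 8)
  c1_ids <- names(b$truth$mutation_assignment)[
    b$truth$mutation_assignment == "C1"]
  s2 <- b$mutations[b$mutations$sample == "S2" &
                      b$mutations$mutation_id %in% c1_ids, ]
  expect_true(all(s2$alt_reads == 0))
})

test_that("artifact channels inject noise and indel calls when enabled", {
  gt <- sample_clone_tree(2, 2, target_class = "B", seed = 21)
  b <- emit_reads(gt, seed = 22, noise_rate = 20, indel_rate = 10)
  expect_gt(sum(grepl("^noise_", b$mutations$mutation_id)), 0)
  expect_gt(sum(b$mutations$kind == "deletion"), 0)
  b0 <- emit_reads(gt, seed = 22)
  expect_false(any(grepl("^noise_", b0$mutations$mutation_id)))
})
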