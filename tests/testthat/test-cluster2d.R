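test_that("histogram conserves counts and concentrates point masses", {
  h <- build_histogram(rep(1, 100), rep(1, 100))
  expect_equal(sum(h$counts), 100)
  expect_equal(max(h$counts), 100)  # single non-zero bin
  set.seed(3)
  x <- runif(250, 0, 1.4); y <- runif(250, 0, 1.4)
  expect_equal(sum(build_histogram(x, y)$counts), 250)
  # values beyond the range are clamped, not lost
  expect_equal(sum(build_histogram(c(2.5, 0.2), c(0.1, 0.1))$counts), 2)
  expect_error(build_histogram(numeric(0), numeric(0)), "empty")
})

test_that("a constant histogram yields a flat surface without spurious peaks", {
  h <- build_histogram(runif(400, 0, 1.5), runif(400, 0, 1.5))
  h$counts[] <- 2L
  surf <- fit_surface(h)
  expect_lt(diff(range(surf$z)), 0.2)
  expect_lte(nrow(find_peaks(surf)), 1)  # only the argmax fallback
})

test_that("infinite smoothing flattens the surface to at most one peak", {
  set.seed(9)
  h <- build_histogram(c(rnorm(100, 1, 0.05), rnorm(80, 0.4, 0.05)),
                       c(rnorm(100, 1, 0.05), rnorm(80, 0.4, 0.05)))
  surf <- fit_surface(h, lambda = 1e9)
  expect_lte(nrow(find_peaks(surf)), 1)
})

test_that("well-separated simulated clones give the true number of maxima", {
  set.seed(13)
  hits <- 0
  for (i in 1:10) {
    c1 <- c(rnorm(150, 1, 0.08), rnorm(100, 0.45, 0.06))
    c2 <- c(rnorm(150, 1, 0.08), rnorm(100, 0.45, 0.06))
    surf <- fit_surface(build_histogram(pmax(c1, 0), pmax(c2, 0)))
    if (nrow(find_peaks(surf)) == 2) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("undersized peaks are deleted and members conserved", {
  ccf1 <- c(rep(1, 50), rep(0.5, 3))
  ccf2 <- c(rep(1, 50), rep(0.5, 3))
  names(ccf1) <- names(ccf2) <- sprintf("m%02d", 1:53)
  status <- rep("shared", 53)
  centres <- data.frame(x = c(1, 0.5), y = c(1, 0.5),
                        kind = "shared", stringsAsFactors = FALSE)
  res <- assign_mutations(ccf1, ccf2, status, centres, min_members = 4)
  expect_equal(nrow(res$centres), 1)
  expect_equal(sum(res$centres$n), 53)  # re-assigned, not dropped
  expect_true(all(!is.na(res$assignments$cluster)))
})

test_that("assignment respects kind constraints and the tie rule", {
  # equidistant shared centres: larger summed CCF wins
  ccf1 <- c(m1 = 0.75); ccf2 <- c(m1 = 0.75)
  centres <- data.frame(x = c(1, 0.5), y = c(1, 0.5), kind = "shared",
                        stringsAsFactors = FALSE)
  res <- assign_mutations(ccf1, ccf2, c(m1 = "shared"), centres,
                          min_members = 1)
  won <- res$centres[res$centres$cluster == res$assignments$cluster, ]
  expect_equal(won$x, 1)

  # private mutations never join shared clusters
  ccf1 <- c(m1 = 0.6, m2 = 0.62, m3 = 0.58, m4 = 0.61, m5 = 0.6)
  ccf2 <- rep(0, 5); names(ccf2) <- names(ccf1)
  centres <- data.frame(x = c(1, 0.6), y = c(1, 0),
                        kind = c("shared", "private_s1"),
                        stringsAsFactors = FALSE)
  res <- assign_mutations(ccf1, ccf2, rep("private_s1", 5), centres,
                          min_members = 4)
  got <- res$centres[res$centres$cluster %in% res$assignments$cluster, ]
  expect_true(all(got$kind == "private_s1"))

  # a private side with no centre founds one given enough mutations
  centres_sh <- centres[1, ]
  res2 <- assign_mutations(ccf1, ccf2, rep("private_s1", 5), centres_sh,
                           min_members = 4)
  expect_true(any(res2$centres$kind == "private_s1"))
  expect_true(all(!is.na(res2$assignments$cluster)))
})

test_that("assignment partitions the retained input", {
  set.seed(17)
  b <- simulate_patient(3, 2, target_class = "E", seed = 17,
                        mut_clonal = c(80, 120), mut_subclonal = c(50, 80))
  flt <- apply_filters(b$mutations, b$segments, b$purity, c("S1", "S2"))
  cl <- cluster_pair(flt$ccf, flt$status, c("S1", "S2"))
  assigned <- !is.na(cl$assignments$cluster)
  expect_equal(sum(cl$centres$n), sum(assigned))
  expect_equal(nrow(cl$assignments), nrow(flt$ccf))
})

test_that("clustering is deterministic for fixed input", {
  b <- simulate_patient(2, 2, target_class = "B", seed = 23,
                        mut_clonal = c(60, 90), mut_subclonal = c(40, 60))
  flt <- apply_filters(b$mutations, b$segments, b$purity, c("S1", "S2"))
  cl1 <- cluster_pair(flt$ccf, flt$status, c("S1", "S2"))
  cl2 <- cluster_pair(flt$ccf, flt$status, c("S1", "S2"))
  expect_identical(cl1$assignments, cl2$assignments)
  expect_identical(cl1$centres, cl2$centres)
})
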