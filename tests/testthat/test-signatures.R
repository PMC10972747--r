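test_that("channel set and catalogue construction follow the convention", {
  ch <- sbs_channels()
  expect_length(ch, 96)
  expect_false(any(duplicated(ch)))
  mut <- data.frame(ref = "C", alt = "A", kind = "SNM", context = "ACA",
                    stringsAsFactors = FALSE)
  cat1 <- build_catalogue(mut)
  expect_equal(sum(cat1), 1)
  expect_equal(unname(cat1["A[C>A]A"]), 1L)
  # purine reference is reverse-complemented onto the pyrimidine strand
  mutG <- data.frame(ref = "G", alt = "T", kind = "SNM", context = "TGT",
                     stringsAsFactors = FALSE)
  expect_equal(unname(build_catalogue(mutG)["A[C>A]A"]), 1L)
  # non-SNMs are skipped with a count
  mix <- rbind(mut, data.frame(ref = "CT", alt = "C", kind = "deletion",
                               context = NA, stringsAsFactors = FALSE))
  cat2 <- build_catalogue(mix)
  expect_equal(sum(cat2), 1)
  expect_equal(attr(cat2, "skipped"), 1L)
})

test_that("catalogue totals equal usable input size", {
  set.seed(61)
  sigs <- synthetic_sbs_catalogue()
  cat96 <- simulate_catalogue(sigs[, c("SBS4", "SBS5")], c(0.7, 0.3), 500)
  expect_equal(sum(cat96), 500)
})

test_that("the bundled synthetic catalogue is a valid signature matrix", {
  sigs <- synthetic_sbs_catalogue()
  expect_equal(dim(sigs), c(96L, 15L))
  expect_true(all(sigs >= 0))
  expect_true(all(abs(colSums(sigs) - 1) < 1e-6))
  path <- system.file("extdata", "synthetic_sbs_catalogue.tsv",
                      package = "clonearch")
  expect_true(file.exists(path))
  re <- read_signature_catalog(path)
  expect_equal(re, sigs[, colnames(re)], tolerance = 1e-4)
})

test_that("NNLS exposures recover exact and mixed catalogues", {
  sigs <- synthetic_sbs_catalogue()
  pure <- round(300 * sigs[, "SBS4"])
  fit <- fit_exposures(pure, sigs)
  expect_gt(fit$exposures["SBS4"], 250)
  expect_lt(sum(fit$exposures[setdiff(names(fit$exposures), "SBS4")]), 50)
  expect_true(all(fit$exposures >= 0))
  expect_lte(fit$cost, sqrt(sum(pure^2)))  # no worse than the zero vector

  set.seed(67)
  cat96 <- simulate_catalogue(sigs[, c("SBS1", "SBS13")], c(0.7, 0.3), 2000)
  fit2 <- fit_exposures(cat96, sigs[, c("SBS1", "SBS13")])
  props <- fit2$exposures / sum(fit2$exposures)
  expect_lt(abs(props["SBS1"] - 0.7), 0.05)
  expect_error(fit_exposures(cat96, sigs[, 0]), "empty")
})

test_that("backward selection keeps cost within threshold of the full fit", {
  sigs <- synthetic_sbs_catalogue()
  set.seed(71)
  cat96 <- simulate_catalogue(sigs[, c("SBS2", "SBS4")], c(0.5, 0.5), 1000)
  sel <- backward_select(cat96, sigs, threshold = 0.02)
  expect_lte(sel$fit$cost, sel$full_cost * 1.02 + 1e-6)
  expect_true(all(c("SBS2", "SBS4") %in% sel$selected))

  # threshold 0: only exactly redundant signatures may go
  dup <- cbind(sigs[, c("SBS2", "SBS4")], DUP = sigs[, "SBS2"])
  sel0 <- backward_select(cat96, dup, threshold = 0)
  expect_lte(sel0$fit$cost, sel0$full_cost + 1e-6)
})

test_that("cohort prevalence subset respects threshold and platinum forcing", {
  expo <- matrix(0, 6, 3, dimnames = list(NULL, c("SBS1", "SBS4", "SBS31")))
  expo[1:5, "SBS1"] <- 1   # 5 cases
  expo[1:4, "SBS4"] <- 1   # 4 cases
  expect_equal(cohort_subset(expo), "SBS1")
  expect_setequal(cohort_subset(expo, post_treatment = TRUE),
                  c("SBS1", "SBS31", "SBS35")[c(1, 2)])
  expect_error(cohort_subset(expo[0, , drop = FALSE]), "empty")
  # monotone in min_cases
  for (k in 1:6)
    expect_true(all(cohort_subset(expo, min_cases = k + 1) %in%
                      cohort_subset(expo, min_cases = k)))
})

test_that("eligibility thresholds are strict", {
  expect_false(eligibility(20, "subclonal")$fit)
  expect_true(eligibility(21, "subclonal")$fit)
  expect_false(eligibility(300, "clonal")$fit)
  expect_true(eligibility(1000, "clonal")$fit)
})

test_that("radiation ratios report missing denominators as NA", {
  k <- c(rep("SNM", 100), rep("insertion", 4), rep("deletion", 6))
  r <- radiation_ratios(k)
  expect_equal(r$indel_substitution, 0.1)
  expect_equal(r$deletion_insertion, 1.5)
  r2 <- radiation_ratios(c(rep("SNM", 10), rep("deletion", 6)))
  expect_true(is.na(r2$deletion_insertion))
  expect_equal(radiation_ratios(c("deletion", rep("SNM", 0),
                                  "insertion"))$indel_substitution,
               NA_real_)
})
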