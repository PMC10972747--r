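test_that("forward-reverse score interpolates between its endpoints", {
  expect_equal(forward_reverse_score(5, 5), 1.0)
  expect_equal(forward_reverse_score(10, 0), 0.0)
  expect_equal(forward_reverse_score(8, 2), 0.4)
  expect_true(is.na(forward_reverse_score(0, 0)))
})

test_that("low-AF power gate fails only underpowered low-AF calls", {
  expect_false(low_af_power_gate(0.1, 50, 50))       # 5 < 10
  expect_true(low_af_power_gate(0.1, 200, 200))      # 20 >= 10
  expect_true(low_af_power_gate(0.25, 10, 10))       # gate inactive
  # the minimum of tumour and normal coverage governs
  expect_false(low_af_power_gate(0.1, 500, 50))
})

test_that("SNMs near indels fail with a strict 10 bp window", {
  mut <- rbind(make_mut("s1", "S1", 100, 30, pos = 1005),
               make_mut("s2", "S1", 100, 30, pos = 1010),
               make_mut("i1", "S1", 100, 30, pos = 1000, kind = "deletion"))
  pass <- indel_proximity_filter(mut)
  expect_equal(pass, c(FALSE, TRUE, TRUE))  # indels unaffected
  only_snm <- make_mut(c("a", "b"), "S1", 100, 30, pos = c(500, 900))
  expect_true(all(indel_proximity_filter(only_snm)))
})

test_that("tail, centromere and low-MAPQ regions are flagged", {
  L <- hg19_chrom_lengths()[["chr1"]]
  mut <- make_mut(c("a", "b", "c", "d"), "S1", 100, 30,
                  pos = c(round(0.01 * L), round(0.5 * L),
                          122000000, round(0.5 * L)),
                  fraction_lowmapq = c(0, 0, 0, 0.12))
  fl <- positional_region_filters(mut)
  expect_equal(fl, c("tail", "ok", "centromere", "lowmapq"))
  expect_error(positional_region_filters(make_mut("x", "S1", 10, 5,
                                                  chrom = "chrZZ")),
               "chrZZ")
})

test_that("segmentation unification takes the breakpoint union", {
  seg <- rbind(
    data.frame(sample = "S1", chrom = "chr1", start = 1, end = 100,
               major_cn = 2, minor_cn = 1, stringsAsFactors = FALSE),
    data.frame(sample = "S2", chrom = "chr1", start = c(1, 51),
               end = c(50, 100), major_cn = c(1, 3), minor_cn = c(1, 0),
               stringsAsFactors = FALSE))
  u <- unify_segmentation(seg)
  expect_equal(sort(unique(u$start)), c(1, 51))
  expect_equal(sort(unique(u$end)), c(50, 100))
  expect_equal(u$major_cn[u$sample == "S1"], c(2, 2))
  # idempotence
  expect_equal(unify_segmentation(u)[, names(u)], u, ignore_attr = TRUE)
  # overlap is a validation error
  bad <- data.frame(sample = "S1", chrom = "chr1", start = c(1, 40),
                    end = c(50, 90), major_cn = 1, minor_cn = 1,
                    stringsAsFactors = FALSE)
  expect_error(unify_segmentation(bad), "overlapping")
})

test_that("every base is covered exactly once after unification", {
  set.seed(31)
  for (rep in 1:10) {
    cuts1 <- sort(sample(2:999, 3)); cuts2 <- sort(sample(2:999, 2))
    mk <- function(s, cuts) data.frame(
      sample = s, chrom = "chr1", start = c(1, cuts),
      end = c(cuts - 1, 1000), major_cn = 2, minor_cn = 1,
      stringsAsFactors = FALSE)
    u <- unify_segmentation(rbind(mk("S1", cuts1), mk("S2", cuts2)))
    for (s in c("S1", "S2")) {
      us <- u[u$sample == s, ]
      cov <- integer(1000)
      for (i in seq_len(nrow(us)))
        cov[us$start[i]:us$end[i]] <- cov[us$start[i]:us$end[i]] + 1L
      expect_true(all(cov == 1L))
    }
  }
})

test_that("LOH in some but not all samples excludes ambiguous privates", {
  seg <- rbind(make_segments("S1", major = 2, minor = 1, end = 1000),
               make_segments("S2", major = 2, minor = 0, end = 1000))
  mut <- make_mut("m1", c("S1", "S2"), 100, c(45, 0), pos = 500)
  pur <- make_purity(c("S1", "S2"))
  cc <- compute_ccf(mut, seg, pur)
  v <- loh_conflict_filter(cc, seg, mut[1, ])
  expect_equal(unname(v["m1"]), "excluded_ambiguous")

  # LOH everywhere: retained
  seg_all <- rbind(make_segments("S1", major = 2, minor = 0, end = 1000),
                   make_segments("S2", major = 2, minor = 0, end = 1000))
  cc2 <- compute_ccf(mut, seg_all, pur)
  expect_equal(unname(loh_conflict_filter(cc2, seg_all, mut[1, ])["m1"]),
               "retained")

  # no LOH anywhere, shared: retained
  mut3 <- make_mut("m1", c("S1", "S2"), 100, c(40, 35), pos = 500)
  cc3 <- compute_ccf(mut3, seg, pur)
  seg_none <- rbind(make_segments("S1", end = 1000),
                    make_segments("S2", end = 1000))
  expect_equal(unname(loh_conflict_filter(cc3, seg_none, mut3[1, ])["m1"]),
               "retained")
})

test_that("power trim removes ~5% under its own model and 0% when constant", {
  # degenerate: identical depth and expected VAF -> nothing trimmed
  cc_const <- data.frame(mutation_id = sprintf("m%02d", 1:20), sample = "S1",
                         depth = 100, alt_reads = 40, vaf = 0.4,
                         expected_vaf = 0.5, multiplicity = 1, ccf = 0.8,
                         flag = "ok", stringsAsFactors = FALSE)
  v <- power_trim(cc_const)
  expect_true(all(v == "retained"))

  set.seed(41)
  n <- 10000
  depths <- pmax(round(rlnorm(n, log(120), 0.35)), 5)
  cc <- data.frame(mutation_id = sprintf("m%05d", 1:n), sample = "S1",
                   depth = depths, alt_reads = round(depths * 0.4),
                   vaf = 0.4, expected_vaf = 0.5, multiplicity = 1,
                   ccf = 0.8, flag = "ok", stringsAsFactors = FALSE)
  v <- power_trim(cc)
  frac <- mean(v == "power_trimmed")
  expect_lt(abs(frac - 0.05), 0.01)

  # a gross depth outlier among ordinary depths is trimmed
  set.seed(42)
  cc_out <- cc[1:100, ]
  cc_out$depth <- c(5, round(rnorm(99, 120, 10)))
  v_out <- power_trim(cc_out)
  expect_equal(unname(v_out["m00001"]), "power_trimmed")

  expect_warning(power_trim(cc[1:5, ]), "fewer than")
})

test_that("binomial private test matches its closed form and BH gate", {
  r1 <- private_mutation_test(0.5, 1)
  expect_equal(r1$p, 0.5)
  expect_equal(r1$status, "excluded_ambiguous")
  r2 <- private_mutation_test(0.3, 100)
  expect_equal(r2$p, 0.7^100)
  expect_equal(r2$status, "truly_private")
  r3 <- private_mutation_test(0.4, 0)
  expect_equal(r3$status, "excluded_zero_coverage")
  # configurable detection threshold k: p = P(X < k)
  r4 <- private_mutation_test(0.3, 50, detect_k = 3)
  expect_equal(r4$p, pbinom(2, 50, 0.3))
})

test_that("rescue augments calls monotonically and idempotently", {
  calls <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2,
                  dimnames = list(c("m1", "m2"), c("S1", "S2")))
  alt <- matrix(c(20, 0, 3, 0), 2, 2, dimnames = dimnames(calls))
  r <- rescue_shared_lowaf(calls, alt)
  expect_true(r["m1", "S2"])    # 3 reads at low AF, rescued
  expect_false(any(r["m2", ]))  # failing everywhere stays absent
  expect_true(all(r[calls]))    # never removes a call
  expect_identical(rescue_shared_lowaf(r, alt), r)
})

test_that("the filter battery annotates but never alters read counts", {
  b <- simulate_patient(3, 2, target_class = "E", seed = 77,
                        mut_clonal = c(60, 80), mut_subclonal = c(30, 50))
  flt <- apply_filters(b$mutations, b$segments, b$purity, c("S1", "S2"))
  w <- flt$ccf
  for (s in c("S1", "S2")) {
    orig <- b$mutations[b$mutations$sample == s, ]
    m <- match(w$mutation_id, orig$mutation_id)
    expect_equal(w[[paste0("alt_", s)]], orig$alt_reads[m])
    expect_equal(w[[paste0("depth_", s)]], orig$depth[m])
  }
  # every input mutation has exactly one terminal verdict
  expect_setequal(flt$verdicts$mutation_id, unique(b$mutations$mutation_id))
  expect_false(any(duplicated(flt$verdicts$mutation_id)))
})
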