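# PL-based genotype calling and filtering.

test_that("thinning keeps the greedy 100-bp-spaced subset per chromosome", {
  rec <- make_records("chr1", c(100, 150, 250, 349, 500))
  out <- thin_sites(rec, 100)
  expect_equal(out$sites$pos, c(100, 250, 500))
  # single site kept
  expect_equal(thin_sites(make_records("chr1", 42))$sites$pos, 42)
  # spacing is per chromosome
  rec2 <- make_records(c("chr1", "chr2"), c(100, 150))
  expect_equal(nrow(thin_sites(rec2)$sites), 2)
  # idempotent
  expect_equal(thin_sites(out, 100)$sites, out$sites)
  # unsorted input rejected
  bad <- make_records("chr1", c(500, 100))
  expect_error(thin_sites(bad), "sorted")
})

test_that("biallelic/average-depth filter", {
  rec <- make_records("chr1", c(100, 300, 500),
                      alt = c("C,T", "T", "T"),
                      dp = matrix(c(10, 10, 19, 0, 10, 10), 3, 2,
                                  byrow = TRUE))
  out <- filter_biallelic_depth(rec, 10)
  # multiallelic removed; depth (19,0) averages 9.5 < 10 removed
  expect_equal(out$sites$pos, 500)
  # missing DP counts as zero in the average
  rec2 <- make_records("chr1", 100, dp = matrix(c(19, NA), 1, 2))
  expect_equal(nrow(filter_biallelic_depth(rec2, 10)$sites), 0)
})

test_that("call_genotype applies the probability and coverage rules", {
  expect_equal(call_genotype(c(0, 40, 200), 12), "AA")
  # second-largest probability 10^-1 = 0.1 > 0.05 -> missing
  expect_true(is.na(call_genotype(c(0, 10, 100), 30)))
  # homozygote below 6x coverage -> missing
  expect_true(is.na(call_genotype(c(0, 40, 200), 5)))
  expect_equal(call_genotype(c(60, 0, 60), 8), "AB")
  # BB candidate scored as alt presence by default, droppable by policy
  expect_equal(call_genotype(c(200, 40, 0), 12), "AB")
  expect_true(is.na(call_genotype(c(200, 40, 0), 12,
                                  bb_policy = "missing")))
  # tied minimum PL -> missing (all-zero PL of a depth-0 site included)
  expect_true(is.na(call_genotype(c(0, 0, 0), 0)))
  expect_error(call_genotype(c(0, 40), 10), "PL")
  expect_error(call_genotype(c(0, NA, 40), 10), "PL")
})

test_that("raising the ambiguity threshold never adds missing calls", {
  set.seed(9)
  n_missing <- function(thr) {
    sum(vapply(seq_len(200), function(i) {
      pl <- sort(sample(0:60, 3))
      pl <- pl - min(pl)
      is.na(call_genotype(pl[sample.int(3)], depth = 10,
                          ambiguity = thr))
    }, TRUE))
  }
  set.seed(9); a <- n_missing(0.05)
  set.seed(9); b <- n_missing(0.2)
  set.seed(9); c0 <- n_missing(0.9)
  expect_true(b <= a)
  expect_true(c0 <= b)
})

test_that("matrix building drops monomorphic and high-missing markers", {
  # 4 samples; site 1 all-AA (monomorphic), site 2 informative,
  # site 3 mostly missing
  pl_slab <- function(calls) {
    t(vapply(calls, function(cl) {
      switch(cl, AA = c(0, 60, 120), AB = c(60, 0, 60),
             BB = c(120, 60, 0), MISS = c(0, 3, 60))
    }, numeric(3)))
  }
  pl <- array(0, dim = c(3, 4, 3))
  pl[1, , ] <- pl_slab(c("AA", "AA", "AA", "AA"))
  pl[2, , ] <- pl_slab(c("AA", "AB", "AB", "AA"))
  pl[3, , ] <- pl_slab(c("MISS", "MISS", "MISS", "AB"))
  rec <- make_records("chr1", c(100, 300, 500), dp = matrix(20, 3, 4),
                      pl = pl, samples = paste0("s", 1:4))
  mat <- build_matrix(rec, max_marker_missing = 0.3)
  expect_equal(rownames(mat$calls), "chr1_300")
  expect_equal(unname(mat$calls[1, ]), c("AA", "AB", "AB", "AA"))
})

test_that("noise-free high-depth calls recover simulated truth >= 99%", {
  lay <- regular_layout(n_chrom = 1, n_markers = 30, length_bp = 1e6,
                        length_cm = 100)
  pop <- simulate_bc1_population(lay, 60, "random_chromosome", seed = 21)
  vcf <- tempfile(fileext = ".vcf")
  simulate_gbs_vcf(pop, mean_depth = 30, error_rate = 0, seed = 22,
                   out = vcf)
  rec <- filter_biallelic_depth(thin_sites(read_vcf_records(vcf)), 10)
  mat <- build_matrix(rec)
  truth_pres <- pop$truth[rownames(mat$calls), colnames(mat$calls)] >= 1
  agree <- (mat$calls == "AB") == truth_pres
  expect_gt(mean(agree, na.rm = TRUE), 0.99)
})

test_that("low-coverage individuals are dropped with a log message", {
  calls <- matrix("AB", 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  calls[, 2] <- NA
  calls[1, 2] <- "AA"   # 10% called
  gm <- make_gm(calls)
  expect_message(out <- drop_low_coverage_individuals(gm, 0.2), "b")
  expect_equal(colnames(out$calls), c("a", "c"))
  expect_equal(attr(out, "dropped"), "b")
  # threshold 0 is the identity
  expect_equal(ncol(drop_low_coverage_individuals(gm, 0)$calls), 3)
  all_bad <- make_gm(matrix(NA_character_, 5, 2))
  expect_error(drop_low_coverage_individuals(all_bad, 0.2), "all individuals")
})
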