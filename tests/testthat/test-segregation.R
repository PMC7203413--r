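# Segregation-ratio tests, enrichment classification, distortion detection.

test_that("chi-square ratio test: exact fits and a hand-computed case", {
  r <- chisq_ratio_test(50, 50, expected = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r <- chisq_ratio_test(100, 20, expected = 5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # all-heterozygote extreme: X^2 = 400/100 + 400/20 = 24
  r <- chisq_ratio_test(120, 0, expected = 5)
  expect_equal(r$statistic, 24)
  expect_equal(r$p, stats::pchisq(24, 1, lower.tail = FALSE))
  expect_lt(r$p, 1e-5)
  expect_equal(r$direction, "above")
  expect_error(chisq_ratio_test(0, 0, 5), "observations")
  expect_error(chisq_ratio_test(10, 10, 0), "positive")
})

test_that("the 1:1 test is symmetric in the counts up to direction", {
  a <- chisq_ratio_test(80, 40, expected = 1)
  b <- chisq_ratio_test(40, 80, expected = 1)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p, b$p)
  expect_equal(a$direction, "above")
  expect_equal(b$direction, "below")
})

test_that("group classification uses strict thresholds", {
  expect_equal(classify_group(3.84)$class, "halepense_enriched")
  expect_equal(classify_group(1.0)$class, "balanced")
  expect_equal(classify_group(0.28)$class, "bicolor_enriched")
  # boundary values are balanced (enrichment needs strict inequality)
  expect_equal(classify_group(1.82)$class, "balanced")
  expect_equal(classify_group(0.55)$class, "balanced")
  expect_error(classify_group(-1), "non-negative")
  expect_error(classify_group(1, t_hi = 0.9), "t_hi")
})

test_that("alpha-derived thresholds are reciprocal and match a binomial
          oracle", {
  th <- ratio_threshold_from_alpha(105, 0.001)
  expect_equal(th$t_hi * th$t_lo, 1, tolerance = 1e-12)
  expect_equal(th$t_hi, 1.946, tolerance = 1e-3)
  # alpha -> 1 demands no evidence
  expect_lt(ratio_threshold_from_alpha(100, 0.999)$t_hi, 1.01)
  # oracle: the smallest count k with exact two-sided binomial p < alpha;
  # the chi-square threshold ratio must fall within one count of it
  n <- 105
  k <- which(vapply(53:n, function(k) {
    2 * stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE) < 0.001
  }, TRUE))[1] + 52
  lo_ratio <- (k - 1) / (n - k + 1)
  hi_ratio <- (k + 1) / (n - k - 1)
  expect_gt(th$t_hi, lo_ratio)
  expect_lt(th$t_hi, hi_ratio)
  # classification with derived thresholds agrees with a chi-square test on
  # the group-average counts
  for (ratio in c(0.3, 0.9, 1.5, 2.2)) {
    nAB <- round(n * ratio / (1 + ratio)); nAA <- n - nAB
    cls <- classify_group(nAB / nAA, t_hi = th$t_hi, t_lo = th$t_lo)$class
    sig <- chisq_ratio_test(nAB, nAA, expected = 1)$p < 0.001
    expect_equal(cls != "balanced", sig, info = paste("ratio", ratio))
  }
})

test_that("square-root transform preserves the ratio ranking", {
  set.seed(17)
  gm <- make_gm(matrix(sample(c("AA", "AB"), 20 * 80, TRUE,
                              prob = c(0.3, 0.7)), 20, 80))
  tab <- segregation_table(gm)
  expect_equal(order(tab$ratio), order(tab$sqrt_ratio))
  expect_equal(tab$sqrt_ratio, sqrt(tab$ratio))
})

test_that("distorted-marker detection flags the requested tail", {
  # a marker with every call heterozygous is flagged above 5:1
  calls <- rbind(matrix("AB", 1, 141),
                 matrix(rep(c("AB", "AA"), c(118, 23)), 1, 141))
  gm <- make_gm(calls)
  hit <- detect_distorted_markers(gm, expected = 5, alpha = 0.05,
                                  direction = "above")
  expect_true("m1" %in% hit$id)
  expect_false("m2" %in% hit$id)  # 118:23 is close to 5:1
  # empty matrix -> empty set
  empty <- make_gm(matrix(character(0), 0, 10))
  expect_equal(nrow(detect_distorted_markers(empty)), 0)
  # binomial option agrees with chisq on clear cases
  hitb <- detect_distorted_markers(gm, expected = 5, alpha = 0.05,
                                   direction = "above",
                                   method = "binomial")
  expect_true("m1" %in% hitb$id)
})

test_that("cross-population intersection and count pooling", {
  mk_tab <- function(nAB, nAA) {
    gm <- make_gm(do.call(rbind, lapply(seq_along(nAB), function(i) {
      matrix(rep(c("AB", "AA"), c(nAB[i], nAA[i])), 1)
    })))
    segregation_table(gm)
  }
  # marker m1 distorted in A only; m2 at 5:1 in both; m3 at 11:1 in both
  tabA <- mk_tab(c(141, 118, 130), c(0, 23, 11))
  tabB <- mk_tab(c(88, 88, 97), c(17, 17, 8))
  res <- cross_population_distortion(tabA, tabB, expected = 5,
                                     alpha = 0.05, direction = "above")
  expect_false("m1" %in% res$intersection)
  expect_true("m1" %in% res$pooled)   # strong in A dominates the pooled test
  expect_false("m2" %in% res$pooled)  # exact 5:1 in both
  expect_true("m3" %in% res$pooled)
  # oracle for the pooled 11:1-in-both marker: exact binomial tail
  nAB <- 130 + 97; n <- 141 + 105
  p_exact <- stats::pbinom(nAB - 1, n, 5 / 6, lower.tail = FALSE)
  expect_lt(p_exact, 0.05 / 2)
  fis <- cross_population_distortion(tabA, tabB, expected = 5,
                                     alpha = 0.05, direction = "above",
                                     pooling = "fisher")
  expect_true("m3" %in% fis$pooled)
})

test_that("distortion regions chain flagged markers with a gap rule", {
  flagged <- data.frame(chrom = "chr2", pos = c(1.0e6, 2.5e6, 4.6e6))
  reg <- detect_distortion_regions(flagged, min_markers = 3, max_gap = 5e6)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(1.0e6, 4.6e6))
  # two markers only: below min_markers
  expect_equal(nrow(detect_distortion_regions(flagged[1:2, ])), 0)
  # a large gap splits chains
  far <- data.frame(chrom = "chr2",
                    pos = c(1e6, 2e6, 3e6, 20e6, 21e6, 22e6))
  reg2 <- detect_distortion_regions(far, min_markers = 3, max_gap = 5e6)
  expect_equal(nrow(reg2), 2)
  expect_equal(reg2$start, c(1e6, 20e6))
  # BED export is 0-based half-open
  bed <- tempfile(fileext = ".bed")
  write_regions_bed(reg2, bed)
  lines <- read.delim(bed, header = FALSE)
  expect_equal(lines$V2, c(1e6 - 1, 20e6 - 1))
  expect_equal(lines$V3, c(3e6, 22e6))
})
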