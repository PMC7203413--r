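# Two-point linkage, clustering, binning, ordering, map estimation.

test_that("Kosambi function and inverse", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.2), 25 * log(1.4 / 0.6))
  r <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(kosambi(r)) > 0))
  expect_equal(kosambi_inv(kosambi(r)), r, tolerance = 1e-12)
  # linear limit d ~ 100 r for small r
  expect_equal(kosambi(1e-4) / 1e-4, 100, tolerance = 1e-4)
})

test_that("estimate_rf closed-form cases", {
  a <- rep(c("AA", "AB"), 50)
  pl <- estimate_rf(a, a)
  expect_equal(pl$rf, 0)
  expect_equal(pl$lod, 100 * log10(2), tolerance = 1e-12)
  # exact complement: phase flip recorded, rf 0 after flip
  b <- ifelse(a == "AA", "AB", "AA")
  pl2 <- estimate_rf(a, b)
  expect_true(pl2$phase_flip)
  expect_equal(pl2$rf, 0)
  # independent columns: lod near 0
  set.seed(4)
  x <- sample(c("AA", "AB"), 400, TRUE)
  y <- sample(c("AA", "AB"), 400, TRUE)
  expect_lt(estimate_rf(x, y)$lod, 2)
  # fewer than 2 informative -> undefined sentinel
  u <- estimate_rf(c("AA", NA), c(NA, "AB"))
  expect_false(u$defined)
  expect_equal(u$rf, 0.5)
  expect_equal(u$lod, 0)
})

test_that("rf estimates track the simulated Haldane distance", {
  lay <- genome_layout(
    data.frame(chrom = "chr1", length_bp = 1e6, length_cm = 100),
    data.frame(id = c("a", "b"), chrom = "chr1", pos = c(1, 1e5),
               f1_dosage = c(1, 1)))  # 10 cM apart
  n <- 1e4
  pop <- simulate_bc1_population(lay, n, "random_chromosome", seed = 31)
  mat <- truth_genotype_matrix(pop)
  r_true <- (1 - exp(-2 * 0.10)) / 2  # Haldane, 0.0906
  est <- estimate_rf(mat$calls[1, ], mat$calls[2, ])
  se <- sqrt(r_true * (1 - r_true) / n)
  expect_lt(abs(est$rf - r_true), 3 * se)
})

test_that("clustering separates chromosomes and respects input order", {
  lay <- regular_layout(n_chrom = 2, n_markers = 15, length_cm = 120,
                        dosages = 1)
  pop <- simulate_bc1_population(lay, 141, "random_chromosome", seed = 8)
  mat <- truth_genotype_matrix(pop)
  gr <- cluster_markers(mat, min_lod = 10)
  expect_length(gr, 2)
  chr_of <- function(ids) unique(sub("_m.*", "", ids))
  expect_equal(sort(vapply(gr, chr_of, "")), c("chr1", "chr2"))
  # invariance to marker input order
  shuf <- subset_ids <- sample(rownames(mat$calls))
  mat2 <- tetrabc:::subset_markers(mat, shuf)
  gr2 <- cluster_markers(mat2, min_lod = 10)
  expect_equal(lapply(gr, sort), lapply(gr2, sort))
  # infinite threshold -> all singletons
  gr3 <- cluster_markers(mat, min_lod = Inf)
  expect_true(all(vapply(gr3, length, 0L) == 1L))
  # duplicated marker column joins its twin
  dup <- mat
  dup$calls <- rbind(dup$calls, dup = dup$calls[1, ])
  rownames(dup$calls)[nrow(dup$calls)] <- "dup"
  dup$markers <- rbind(dup$markers,
                       data.frame(id = "dup", chrom = "chr1", pos = 999))
  dup$depth <- rbind(dup$depth, dup$depth[1, ])
  gr4 <- cluster_markers(dup, min_lod = 10)
  grp_of <- function(g, id) which(vapply(g, function(x) id %in% x, TRUE))
  expect_equal(grp_of(gr4, "dup"), grp_of(gr4, rownames(mat$calls)[1]))
})

test_that("bin merging follows the agree/majority/tie rules", {
  expect_equal(tetrabc:::.merge_bin_calls(
    matrix(c("AB", NA, "AB"), 3, 1)), "AB")
  expect_true(is.na(tetrabc:::.merge_bin_calls(
    matrix(c("AB", "AA"), 2, 1))))
  expect_equal(tetrabc:::.merge_bin_calls(
    matrix(c("AB", "AB", "AA"), 3, 1)), "AB")
  expect_true(is.na(tetrabc:::.merge_bin_calls(
    matrix(c(NA, NA), 2, 1))))
})

test_that("binning collapses co-located markers and keeps singleton bins", {
  # markers 1-2 identical columns (0 cM apart), marker 3 far away
  set.seed(12)
  col <- sample(c("AA", "AB"), 200, TRUE)
  far <- ifelse(stats::runif(200) < 0.3, ifelse(col == "AA", "AB", "AA"),
                col)
  calls <- rbind(m1 = col, m2 = col, m3 = far)
  gm <- make_gm(calls, pos = c(1000, 1100, 900000))
  out <- bin_markers(gm, bin_cm = 1)
  expect_equal(nrow(out$matrix$calls), 2)
  expect_equal(out$bin_map$bin[1:2], c("m1", "m1"))
  # singleton bin genotype equals the marker genotype
  expect_equal(unname(out$matrix$calls["m3", ]), unname(far))
  # merged bin equals the shared column
  expect_equal(unname(out$matrix$calls["m1", ]), unname(col))
})

test_that("ordering recovers a simulated gradient and tolerates shuffling", {
  lay <- regular_layout(n_chrom = 1, n_markers = 10, length_cm = 90,
                        dosages = 1)
  pop <- simulate_bc1_population(lay, 200, "random_chromosome", seed = 13)
  mat <- truth_genotype_matrix(pop)
  truth <- rownames(mat$calls)
  ord <- order_markers(mat)
  expect_true(identical(ord, truth) || identical(ord, rev(truth)))
  # shuffled input, same result up to reversal
  mat2 <- tetrabc:::subset_markers(mat, sample(truth))
  ord2 <- order_markers(mat2)
  expect_true(identical(ord2, truth) || identical(ord2, rev(truth)))
  # ordering objective invariant under whole-group reversal
  pw <- tetrabc:::.pairwise_linkage(mat$calls)
  dmat <- kosambi(pmin(pw$rf, 0.4995))
  ix <- match(ord, rownames(mat$calls))
  expect_equal(tetrabc:::.order_length(ix, dmat),
               tetrabc:::.order_length(rev(ix), dmat))
  # two markers: returned in tie-break (physical) order
  two <- tetrabc:::subset_markers(mat, truth[c(2, 1)])
  expect_equal(sort(order_markers(two)), sort(truth[1:2]))
})

test_that("EM map estimation matches two-point rfs when noise-free", {
  lay <- regular_layout(n_chrom = 1, n_markers = 6, length_cm = 100,
                        dosages = 1)
  pop <- simulate_bc1_population(lay, 300, "random_chromosome", seed = 14)
  mat <- truth_genotype_matrix(pop)
  lg0 <- estimate_map(mat, id = "t", error_prob = 0)
  two_point <- vapply(1:5, function(i) {
    estimate_rf(mat$calls[i, ], mat$calls[i + 1, ])$rf
  }, 0)
  expect_equal(lg0$rf, two_point, tolerance = 1e-12)
  # r = 0 interval spans 0 cM
  dup <- mat
  dup$calls[2, ] <- dup$calls[1, ]
  lg1 <- estimate_map(dup, id = "t", error_prob = 0)
  expect_equal(lg1$map$cm[2], 0)
  # with error modelling, rfs stay close to two-point on clean data
  # (the error model absorbs roughly 2*e of apparent recombination)
  lg2 <- estimate_map(mat, id = "t", error_prob = 0.01)
  expect_lt(max(abs(lg2$rf - two_point)), 0.03)
  expect_true(all(diff(lg2$map$cm) >= 0))
  # summary bookkeeping
  s <- lg2$summary
  expect_equal(s$length_cm, max(lg2$map$cm))
  expect_equal(s$avg_spacing, s$length_cm / (s$n_markers - 1))
  n_aa <- rowSums(mat$calls == "AA")
  n_ab <- rowSums(mat$calls == "AB")
  expect_equal(s$ab_aa_ratio, mean(n_ab) / mean(n_aa))
})

test_that("repulsion merge test joins complements, not independent groups", {
  set.seed(15)
  base <- matrix(sample(c("AA", "AB"), 5 * 141, TRUE), 5, 141)
  gA <- make_gm(ifelse(base == "AA", "AB", "AA"))
  rownames(gA$calls) <- gA$markers$id <- paste0("a", 1:5)
  gB <- make_gm(base)
  rownames(gB$calls) <- gB$markers$id <- paste0("b", 1:5)
  rep_res <- merge_repulsion(gA, gB, min_lod = 10)
  expect_true(rep_res$coalesces)
  expect_equal(rep_res$min_rf, 0)
  # independent groups do not coalesce at LOD 10
  lay <- regular_layout(n_chrom = 2, n_markers = 5, dosages = 1)
  pop <- simulate_bc1_population(lay, 141, "random_chromosome", seed = 16)
  mat <- truth_genotype_matrix(pop)
  g1 <- tetrabc:::subset_markers(mat, rownames(mat$calls)[1:5])
  g2 <- tetrabc:::subset_markers(mat, rownames(mat$calls)[6:10])
  expect_false(merge_repulsion(g1, g2, min_lod = 10)$coalesces)
  empty <- make_gm(matrix(character(0), 0, 5))
  expect_error(merge_repulsion(empty, g2), "empty")
})
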