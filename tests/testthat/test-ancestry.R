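# Progenitor-origin classification, tallies, runs, coverage.

test_that("site filter enforces QUAL, depth, and missingness", {
  gt <- matrix("0/0", 3, 4)
  dp <- matrix(12, 3, 4)
  dp[2, 1:2] <- 5                # two of four samples under-covered
  rec <- make_records("chr1", c(100, 200, 300), qual = c(19, 30, 30),
                      dp = dp, gt = gt, samples = paste0("s", 1:4))
  out <- filter_sites(rec, min_qual = 20, min_depth = 10,
                      max_missing = 0.30)
  # QUAL 19 removed; 50% missing removed; clean site retained
  expect_equal(out$sites$pos, 300)
  expect_true(all(out$usable))
})

test_that("classify_site implements the allele-origin decision table", {
  # identical to reference parent
  expect_equal(classify_site("0/0", "1/1", "0/0"), "B")
  # one allele from each progenitor
  expect_equal(classify_site("0/1", "1/1", "0/0"), "H_BP")
  # homozygous for the propinquum allele
  expect_equal(classify_site("1/1", "1/1", "0/0"), "P")
  # alt not seen in propinquum: novel mutation
  expect_equal(classify_site("1/1", "0/0", "0/0"), "N_M")
  expect_equal(classify_site("0/1", "0/0", "0/0"), "N_M")
  # heterozygous propinquum/novel at a multi-allelic site
  expect_equal(classify_site("1/2", "1/1", "0/0"), "H_PM")
  # off-reference control: intra-bicolor polymorphism -> UNKNOWN
  expect_equal(classify_site("0/1", "1/1", "1/1"), "UNKNOWN")
  expect_equal(classify_site("0/0", "1/1", "0/1"), "UNKNOWN")
  # missing data -> UNKNOWN
  expect_equal(classify_site("./.", "1/1", "0/0"), "UNKNOWN")
  expect_equal(classify_site("0/0", NA, "0/0"), "UNKNOWN")
  # two propinquum accessions: disagreement is UNKNOWN under "all",
  # informative under "any"
  expect_equal(classify_site("1/1", c("1/1", "0/0"), "0/0"), "UNKNOWN")
  expect_equal(classify_site("1/1", c("1/1", "0/0"), "0/0",
                             propinquum_consensus = "any"), "P")
  expect_equal(classify_site("1/1", c("1/1", "1/1"), "0/0"), "P")
})

test_that("category tallies exclude UNKNOWN from the denominator", {
  track <- data.frame(category = c("B", "B", "P", "UNKNOWN"))
  tab <- tally_categories(track)
  expect_equal(sum(tab$count), 4)
  expect_equal(tab$proportion[tab$category == "B"], 2 / 3)
  expect_equal(tab$proportion[tab$category == "P"], 1 / 3)
  expect_true(is.na(tab$proportion[tab$category == "UNKNOWN"]))
  expect_equal(sum(tab$proportion, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_error(tally_categories(data.frame(category = rep("UNKNOWN", 3))),
               "non-UNKNOWN")
})

test_that("run detection finds maximal blocks of >= min_run sites", {
  tr <- function(cats) data.frame(chrom = "chr1",
                                  pos = seq_along(cats) * 1000L,
                                  category = cats)
  runs <- detect_runs(tr(c("P", "P", "P", "B")), min_run = 3)
  expect_equal(nrow(runs), 1)
  expect_equal(c(runs$start, runs$end, runs$n_sites), c(1000, 3000, 3))
  expect_equal(nrow(detect_runs(tr(c("P", "P", "B", "P", "P")))), 0)
  expect_equal(nrow(detect_runs(tr(rep(c("P", "B"), 50)))), 0)
  # maximality: blocks are reported whole
  runs2 <- detect_runs(tr(c("B", rep("P", 5), "B", rep("P", 3))))
  expect_equal(runs2$n_sites, c(5, 3))
})

test_that("run coverage merges overlaps and validates bounds", {
  sizes <- data.frame(chrom = c("c1", "c2"), length_bp = c(10e6, 90e6))
  one <- data.frame(chrom = "c1", start = 1, end = 10e6)
  expect_equal(run_coverage(one, sizes), 0.10)
  expect_equal(run_coverage(one[0, ], sizes), 0)
  two <- data.frame(chrom = "c1", start = c(1e6, 3e6), end = c(5e6, 8e6))
  expect_equal(run_coverage(two, sizes), (8e6 - 1e6 + 1) / 100e6)
  beyond <- data.frame(chrom = "c1", start = 5e6, end = 11e6)
  expect_error(run_coverage(beyond, sizes), "beyond")
})

test_that("a spliced mosaic trio is recovered exactly", {
  vcf <- tempfile(fileext = ".vcf")
  res <- write_mosaic_trio_vcf(vcf, seed = 5, n_sites = 120,
                               block_size = 10)
  blocks <- attr(res, "blocks")
  rec <- read_vcf_records(vcf)
  rec <- filter_sites(rec, min_qual = 20, min_depth = 10,
                      max_missing = 0.3)
  track <- classify_sites(rec, roles = list(
    target = "target", control = "control",
    propinquum_1 = "prop1", propinquum_2 = "prop2"))
  # noise-free genotypes: every site classified to its true donor
  truth <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    rep(blocks$origin[i], blocks$end_index[i] - blocks$start_index[i] + 1)
  }))
  expect_gte(mean(track$category == truth), 0.99)
  # run boundaries recovered at marker resolution
  runs <- detect_runs(track, target_category = "P", min_run = 3)
  p_blocks <- blocks[blocks$origin == "P", ]
  expect_equal(nrow(runs), nrow(p_blocks))
  expect_equal(runs$start, p_blocks$start_bp)
  expect_equal(runs$end, p_blocks$end_bp)
})

test_that("run-table bookkeeping counts per-population and shared rows", {
  tab <- data.frame(start_a = c(1, NA, 5), end_a = c(2, NA, 6),
                    start_b = c(1, 3, NA), end_b = c(2, 4, NA))
  s <- summarize_run_table(tab)
  expect_equal(s$n_a, 2)
  expect_equal(s$n_b, 2)
  expect_equal(s$n_shared, 1)
  expect_equal(s$n_distinct, 3)
  bad <- rbind(tab, data.frame(start_a = NA, end_a = NA,
                               start_b = NA, end_b = NA))
  expect_error(summarize_run_table(bad), "neither")
})
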