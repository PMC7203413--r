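# In-code fixtures shared across test files.

# site_records built directly (no VCF round trip): sites data.frame plus
# per-sample DP and PL slabs.
make_records <- function(chrom, pos, alt = NULL, qual = 50,
                         dp = NULL, pl = NULL, gt = NULL,
                         samples = NULL) {
  n <- length(pos)
  if (is.null(alt)) alt <- rep("T", n)
  if (is.null(samples)) {
    samples <- paste0("s", seq_len(if (!is.null(dp)) ncol(dp) else 2))
  }
  ns <- length(samples)
  if (is.null(dp)) dp <- matrix(20, n, ns)
  if (is.null(pl)) {
    pl <- array(rep(c(0, 60, 120), each = n * ns), dim = c(n, ns, 3))
  }
  ids <- paste0(chrom, "_", pos)
  dimnames(dp) <- list(ids, samples)
  dimnames(pl) <- list(ids, samples, c("AA", "AB", "BB"))
  sites <- data.frame(chrom = chrom, pos = pos, id = ids,
                      ref = "A", alt = alt, qual = qual,
                      stringsAsFactors = FALSE)
  if (!is.null(gt)) dimnames(gt) <- list(ids, samples)
  structure(list(sites = sites, samples = samples, dp = dp,
                 ad_ref = NULL, ad_alt = NULL, pl = pl, gt = gt),
            class = "site_records")
}

# genotype_matrix from a plain character matrix of AA/AB/NA
make_gm <- function(calls, chrom = "chr1", pos = NULL) {
  if (nrow(calls) > 0 && is.null(rownames(calls))) {
    rownames(calls) <- paste0("m", seq_len(nrow(calls)))
  }
  if (ncol(calls) > 0 && is.null(colnames(calls))) {
    colnames(calls) <- paste0("i", seq_len(ncol(calls)))
  }
  if (is.null(pos)) pos <- seq_len(nrow(calls)) * 1000L
  ids <- if (nrow(calls) > 0) rownames(calls) else character(0)
  structure(list(
    calls = calls,
    markers = data.frame(id = ids,
                         chrom = rep_len(chrom, nrow(calls)), pos = pos),
    depth = matrix(30, nrow(calls), ncol(calls),
                   dimnames = dimnames(calls))),
    class = "genotype_matrix")
}

named_models <- c("random_chromosome", "random_chromatid", "max_equational")
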