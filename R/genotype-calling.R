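# Genotype calling and filtering: multi-sample VCF -> presence/absence
# (AA/AB) genotype matrix. GBS coverage on tetraploids does not resolve
# heterozygous dosage, so genotypes are coded only as donor allele absent
# (AA, homozygous reference) or present (AB).

#' Thin sites to a minimum spacing
#'
#' Greedy left-to-right scan per chromosome: the first site is kept and each
#' subsequent site is kept only if it lies at least `min_spacing` bp from the
#' previously *retained* site. SNPs within a read length of each other carry
#' little non-redundant information in early generations after a cross.
#'
#' @param records A `site_records` object (see [read_vcf_records()]), sorted
#'   by (chrom, pos).
#' @param min_spacing Minimum bp between retained sites (default 100).
#' @return The thinned `site_records`.
#' @export
thin_sites <- function(records, min_spacing = 100) {
  stopifnot(inherits(records, "site_records"))
  s <- records$sites
  if (nrow(s) == 0L) return(records)
  by_chr <- split(seq_len(nrow(s)), s$chrom)
  for (idx in by_chr) {
    if (is.unsorted(s$pos[idx], strictly = FALSE)) {
      stop("sites must be sorted by position within chromosome")
    }
  }
  keep <- logical(nrow(s))
  for (idx in by_chr) {
    last <- -Inf
    for (i in idx) {
      if (s$pos[i] - last >= min_spacing) {
        keep[i] <- TRUE
        last <- s$pos[i]
      }
    }
  }
  .subset_records(records, which(keep))
}

#' Filter to biallelic sites with sufficient average depth
#'
#' Retains sites with exactly one ALT allele and arithmetic mean per-sample
#' depth at least `min_avg_depth`, counting samples with missing DP as depth
#' 0 (the denominator is all samples).
#'
#' @inheritParams thin_sites
#' @param min_avg_depth Minimum mean depth (default 10).
#' @return Filtered `site_records`.
#' @export
filter_biallelic_depth <- function(records, min_avg_depth = 10) {
  stopifnot(inherits(records, "site_records"))
  s <- records$sites
  if (nrow(s) == 0L) return(records)
  biallelic <- !is.na(s$alt) & s$alt != "." & !grepl(",", s$alt, fixed = TRUE)
  dp <- records$dp
  dp[is.na(dp)] <- 0
  avg <- rowMeans(dp)
  .subset_records(records, which(biallelic & avg >= min_avg_depth))
}

#' Call one genotype from PL and depth
#'
#' The candidate call is the genotype with minimum PL. Each PL is converted
#' to a probability scale, p = 10^(-PL/10); if the second-largest p exceeds
#' `ambiguity` the call is too uncertain and MISSING is returned. Candidate
#' homozygous-reference (AA) calls with depth below `hom_min_depth` are also
#' MISSING, since low coverage cannot exclude an unsampled alternate allele.
#' Homozygous-alternate (BB) candidates map to AB under `bb_policy = "het"`
#' (the default): in a backcross to a reference-homozygous recurrent parent
#' the presence of the alternate allele is the datum, its dosage is not
#' resolved. Ties for the minimum PL return MISSING.
#'
#' @param pl Numeric vector of 3 phred-scaled likelihoods (AA, AB, BB).
#' @param depth Read depth at the site for this sample.
#' @param ambiguity Maximum tolerated second-largest genotype probability
#'   (default 0.05).
#' @param hom_min_depth Minimum depth for a homozygous call (default 6).
#' @param bb_policy `"het"` (BB scored as AB) or `"missing"`.
#' @return `"AA"`, `"AB"`, or `NA_character_` (missing).
#' @examples
#' call_genotype(c(0, 40, 200), 12)  # "AA"
#' call_genotype(c(0, 10, 100), 30)  # missing: second p = 0.1 > 0.05
#' call_genotype(c(0, 40, 200), 5)   # missing: hom below 6x
#' @export
call_genotype <- function(pl, depth, ambiguity = 0.05, hom_min_depth = 6,
                          bb_policy = c("het", "missing")) {
  bb_policy <- match.arg(bb_policy)
  if (length(pl) != 3L || anyNA(pl) || any(!is.finite(pl)) || any(pl < 0)) {
    stop("malformed PL vector: ", paste(pl, collapse = ","))
  }
  if (is.na(depth)) depth <- 0
  p <- 10^(-pl / 10)
  o <- order(p, decreasing = TRUE)
  if (p[o[2]] > ambiguity) return(NA_character_)
  if (p[o[1]] == p[o[2]]) return(NA_character_)
  cand <- o[1]  # 1 = AA, 2 = AB, 3 = BB
  if (cand == 1L) {
    if (depth < hom_min_depth) return(NA_character_)
    return("AA")
  }
  if (cand == 3L && bb_policy == "missing") return(NA_character_)
  "AB"
}

# vectorized caller over a sites x samples slab; same rules as call_genotype
.call_matrix <- function(pl, dp, ambiguity = 0.05, hom_min_depth = 6,
                         bb_policy = "het") {
  n_site <- dim(pl)[1]; n_samp <- dim(pl)[2]
  p1 <- 10^(-pl[, , 1, drop = TRUE] / 10)
  p2 <- 10^(-pl[, , 2, drop = TRUE] / 10)
  p3 <- 10^(-pl[, , 3, drop = TRUE] / 10)
  dim(p1) <- dim(p2) <- dim(p3) <- c(n_site, n_samp)
  top <- pmax(p1, p2, p3)
  bot <- pmin(p1, p2, p3)
  mid <- p1 + p2 + p3 - top - bot
  cand <- ifelse(p1 >= pmax(p2, p3), 1L, ifelse(p2 >= p3, 2L, 3L))
  calls <- matrix(NA_character_, n_site, n_samp,
                  dimnames = dimnames(pl)[1:2])
  dp0 <- dp
  dp0[is.na(dp0)] <- 0
  ok <- !is.na(top) & mid <= ambiguity & top > mid
  calls[ok & cand == 1L & dp0 >= hom_min_depth] <- "AA"
  calls[ok & cand == 2L] <- "AB"
  if (bb_policy == "het") {
    calls[ok & cand == 3L] <- "AB"
  }
  calls
}

#' Build a presence/absence genotype matrix
#'
#' Calls every sample at every (thinned, filtered) site, then drops markers
#' whose missing fraction exceeds `max_marker_missing` and markers that are
#' monomorphic (no AA or no AB observed among non-missing calls).
#'
#' @inheritParams thin_sites
#' @param max_marker_missing Maximum tolerated per-marker missing fraction
#'   (default 0.3).
#' @param ambiguity,hom_min_depth,bb_policy Passed to the caller; see
#'   [call_genotype()].
#' @return An object of class `genotype_matrix`: list with `calls` (markers x
#'   individuals character matrix, values `"AA"`/`"AB"`/`NA`), `markers`
#'   (data.frame id/chrom/pos), `depth` (matching depth matrix).
#' @export
build_matrix <- function(records, max_marker_missing = 0.3,
                         ambiguity = 0.05, hom_min_depth = 6,
                         bb_policy = "het") {
  stopifnot(inherits(records, "site_records"))
  if (length(records$samples) == 0L) stop("no samples in records")
  calls <- .call_matrix(records$pl, records$dp, ambiguity = ambiguity,
                        hom_min_depth = hom_min_depth, bb_policy = bb_policy)
  miss_frac <- rowMeans(is.na(calls))
  n_aa <- rowSums(calls == "AA", na.rm = TRUE)
  n_ab <- rowSums(calls == "AB", na.rm = TRUE)
  keep <- miss_frac <= max_marker_missing & n_aa > 0 & n_ab > 0
  mk <- records$sites[keep, c("id", "chrom", "pos"), drop = FALSE]
  rownames(mk) <- NULL
  structure(list(calls = calls[keep, , drop = FALSE],
                 markers = mk,
                 depth = records$dp[keep, , drop = FALSE]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d markers x %d individuals\n",
              nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

#' Drop individuals with low call rates
#'
#' Individuals whose fraction of non-missing calls falls below
#' `min_called_fraction` (e.g. failed GBS libraries) are removed; their names
#' are attached as attribute `"dropped"` and reported via message.
#'
#' @param matrix A `genotype_matrix`.
#' @param min_called_fraction Minimum fraction of non-missing calls
#'   (default 0.2).
#' @return The reduced `genotype_matrix`.
#' @export
drop_low_coverage_individuals <- function(matrix, min_called_fraction = 0.2) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  called <- colMeans(!is.na(matrix$calls))
  drop <- called < min_called_fraction
  if (all(drop)) stop("all individuals fall below the call-rate threshold")
  if (any(drop)) {
    message("dropping ", sum(drop), " low-coverage individual(s): ",
            paste(colnames(matrix$calls)[drop], collapse = ", "))
  }
  matrix$calls <- matrix$calls[, !drop, drop = FALSE]
  matrix$depth <- matrix$depth[, !drop, drop = FALSE]
  attr(matrix, "dropped") <- names(called)[drop]
  matrix
}

#' Write a genotype matrix and per-marker QC table
#'
#' @param matrix A `genotype_matrix`.
#' @param path CSV path for the calls (rows = markers with chrom,pos,
#'   cells AA/AB/NA).
#' @param qc_path Optional CSV path for per-marker QC (mean depth,
#'   missingness, AA/AB counts).
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(matrix, path, qc_path = NULL) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  df <- cbind(matrix$markers, as.data.frame(matrix$calls))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(qc_path)) {
    dp <- matrix$depth
    dp[is.na(dp)] <- 0
    qc <- cbind(matrix$markers, data.frame(
      mean_depth = rowMeans(dp),
      missing_fraction = rowMeans(is.na(matrix$calls)),
      n_AA = rowSums(matrix$calls == "AA", na.rm = TRUE),
      n_AB = rowSums(matrix$calls == "AB", na.rm = TRUE)))
    utils::write.csv(qc, qc_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Genotype matrix from a truth dosage matrix
#'
#' Presence/absence coding of a simulated truth matrix (dosage >= 1 is AB),
#' optionally perturbed by a symmetric per-call error rate. Used to study
#' downstream stages without the read layer.
#'
#' @param pop A [simulate_bc1_population()] result.
#' @param error_rate Probability of flipping a call (default 0).
#' @param seed Seed used when `error_rate > 0`.
#' @return A `genotype_matrix`.
#' @export
truth_genotype_matrix <- function(pop, error_rate = 0, seed = 1) {
  stopifnot(inherits(pop, "simulated_population"))
  calls <- ifelse(pop$truth >= 1, "AB", "AA")
  if (error_rate > 0) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
    flip <- matrix(stats::runif(length(calls)) < error_rate, nrow(calls))
    calls[flip] <- ifelse(calls[flip] == "AB", "AA", "AB")
  }
  mk <- pop$layout$markers
  structure(list(calls = calls,
                 markers = data.frame(id = mk$id, chrom = mk$chrom,
                                      pos = mk$pos),
                 depth = matrix(NA_real_, nrow(calls), ncol(calls),
                                dimnames = dimnames(calls))),
            class = "genotype_matrix")
}
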