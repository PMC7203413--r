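#' Read a multi-sample VCF into site records
#'
#' Thin wrapper over [vcfR::read.vcfR()] extracting the fields the pipeline
#' needs: site table (chrom, pos, id, ref, alt, qual), per-sample read depth
#' (DP), allelic depths (AD, optional) and the three phred-scaled genotype
#' likelihoods (PL, required for genotype calling).
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @return An object of class `site_records`: list with `sites` (data.frame),
#'   `samples`, `dp` (sites x samples numeric matrix, NA where absent),
#'   `ad_ref`/`ad_alt` (or NULL), and `pl` (sites x samples x 3 array, NA
#'   where absent).
#' @export
read_vcf_records <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = as.character(fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE
  )
  no_id <- is.na(sites$id) | sites$id == "."
  sites$id[no_id] <- paste0(sites$chrom[no_id], "_", sites$pos[no_id])
  samples <- colnames(v@gt)[-1]
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  pl_chr <- suppressWarnings(vcfR::extract.gt(v, element = "PL"))
  pl <- array(NA_real_, dim = c(nrow(sites), length(samples), 3L))
  if (!is.null(pl_chr)) {
    spl <- strsplit(as.vector(pl_chr), ",", fixed = TRUE)
    for (k in 1:3) {
      pl[, , k] <- matrix(suppressWarnings(as.numeric(
        vapply(spl, function(x) if (length(x) >= k) x[k] else NA_character_,
               character(1)))), nrow(sites), length(samples))
    }
  }
  ad_chr <- suppressWarnings(vcfR::extract.gt(v, element = "AD"))
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad_chr) && !all(is.na(ad_chr))) {
    spl <- strsplit(as.vector(ad_chr), ",", fixed = TRUE)
    ad_ref <- matrix(suppressWarnings(as.numeric(vapply(
      spl, function(x) if (length(x) >= 1) x[1] else NA_character_,
      character(1)))), nrow(sites), length(samples))
    ad_alt <- matrix(suppressWarnings(as.numeric(vapply(
      spl, function(x) if (length(x) >= 2) x[2] else NA_character_,
      character(1)))), nrow(sites), length(samples))
    dimnames(ad_ref) <- dimnames(ad_alt) <- list(sites$id, samples)
  }
  dimnames(dp) <- list(sites$id, samples)
  dimnames(pl) <- list(sites$id, samples, c("AA", "AB", "BB"))
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(gt_chr)) dimnames(gt_chr) <- list(sites$id, samples)
  structure(list(sites = sites, samples = samples, dp = dp,
                 ad_ref = ad_ref, ad_alt = ad_alt, pl = pl, gt = gt_chr),
            class = "site_records")
}

#' @export
print.site_records <- function(x, ...) {
  cat(sprintf("<site_records> %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

# subset site_records by site index
.subset_records <- function(records, keep) {
  records$sites <- records$sites[keep, , drop = FALSE]
  rownames(records$sites) <- NULL
  records$dp <- records$dp[keep, , drop = FALSE]
  if (!is.null(records$ad_ref)) {
    records$ad_ref <- records$ad_ref[keep, , drop = FALSE]
    records$ad_alt <- records$ad_alt[keep, , drop = FALSE]
  }
  records$pl <- records$pl[keep, , , drop = FALSE]
  if (!is.null(records$gt)) records$gt <- records$gt[keep, , drop = FALSE]
  records
}
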