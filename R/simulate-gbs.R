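# GBS read-depth simulator over a simulated population, emitting VCF 4.2
# with diploid-style DP/AD/PL FORMAT fields (the caller model applied to
# tetraploid samples in practice: three genotype likelihoods at alt read
# fractions 0, 1/2, 1).

.PL_CAP <- 9999

# Phred-scaled, min-normalized 3-genotype likelihoods for (ref_reads,
# alt_reads) with per-read error rate e. Genotype g in {0,1,2} has alt-read
# probability e, 1/2, 1-e.
.diploid_pl <- function(n_ref, n_alt, error_rate) {
  if (n_ref + n_alt == 0L) return(c(0L, 0L, 0L))
  p_alt <- pmin(pmax(c(error_rate, 0.5, 1 - error_rate), 1e-12), 1 - 1e-12)
  ll <- n_alt * log10(p_alt) + n_ref * log10(1 - p_alt)
  pl <- round(-10 * (ll - max(ll)))
  as.integer(pmin(pl, .PL_CAP))
}

#' Simulate GBS reads over a population and write a VCF
#'
#' For every sample-site pair: read depth ~ Poisson(`mean_depth`); alt reads
#' ~ Binomial(depth, f') with true alt fraction f = dosage/4 (tetraploid
#' progeny carry 0–2 donor alleles among 4 homologs) perturbed by the
#' per-read error rate, f' = f(1-e) + (1-f)e. Per-sample PL holds the three
#' phred-scaled diploid genotype likelihoods (alt fraction 0, 1/2, 1),
#' normalized so the best genotype has PL 0 — mimicking a diploid caller run
#' on tetraploid GBS data, where depth does not resolve heterozygous dosage.
#' GT is emitted as missing (`./.`); DP and AD are always present.
#'
#' @param pop A [simulate_bc1_population()] result.
#' @param mean_depth Mean sequencing depth (> 0).
#' @param error_rate Per-read error rate in \[0, 0.5).
#' @param seed Integer seed for the read layer.
#' @param out Path of the VCF to write (plain text, `.vcf`).
#' @return `out`, invisibly. Side effect: writes a VCF 4.2 file with records
#'   sorted by (chrom, pos), REF = A, ALT = T at every site.
#' @examples
#' lay <- regular_layout(n_chrom = 1, n_markers = 3)
#' pop <- simulate_bc1_population(lay, 4, "random_chromosome", seed = 1)
#' vcf <- tempfile(fileext = ".vcf")
#' simulate_gbs_vcf(pop, mean_depth = 20, error_rate = 0.002, seed = 2,
#'                  out = vcf)
#' @export
simulate_gbs_vcf <- function(pop, mean_depth, error_rate, seed, out) {
  stopifnot(inherits(pop, "simulated_population"))
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    stop("mean_depth must be > 0")
  }
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  mk <- pop$layout$markers
  n_site <- nrow(mk)
  n_samp <- ncol(pop$truth)
  samples <- colnames(pop$truth)

  depth <- matrix(stats::rpois(n_site * n_samp, mean_depth), n_site, n_samp)
  f_true <- pop$truth / 4
  f_eff <- f_true * (1 - error_rate) + (1 - f_true) * error_rate
  alt <- matrix(stats::rbinom(n_site * n_samp, as.vector(depth),
                              as.vector(f_eff)), n_site, n_samp)
  ref <- depth - alt

  con <- tryCatch(file(out, "w"),
                  error = function(e) stop("cannot open VCF for writing: ",
                                           out, " (", conditionMessage(e),
                                           ")"))
  on.exit(close(con), add = TRUE)
  chrom_tab <- pop$layout$chromosomes
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tetrabc_gbs_simulator",
    sprintf("##contig=<ID=%s,length=%d>", chrom_tab$chrom,
            chrom_tab$length_bp),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths (ref,alt)\">"),
    paste0("##FORMAT=<ID=PL,Number=G,Type=Integer,Description=",
           "\"Phred-scaled genotype likelihoods\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(header, con)
  for (i in seq_len(n_site)) {
    cells <- vapply(seq_len(n_samp), function(j) {
      pl <- .diploid_pl(ref[i, j], alt[i, j], error_rate)
      sprintf("./.:%d:%d,%d:%s", depth[i, j], ref[i, j], alt[i, j],
              paste(pl, collapse = ","))
    }, character(1))
    writeLines(paste(c(mk$chrom[i], mk$pos[i], mk$id[i], "A", "T", "50",
                       "PASS", ".", "GT:DP:AD:PL", cells),
                     collapse = "\t"), con)
  }
  invisible(out)
}
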