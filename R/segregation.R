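# Segregation-ratio analysis: per-marker chi-square tests against specified
# het:hom ratios, linkage-group enrichment classification, distortion
# detection within and across populations, and distorted-region calling.

#' Chi-square test of a het:hom segregation ratio
#'
#' Goodness-of-fit of observed heterozygote/homozygote counts to an expected
#' het:hom ratio: `X^2 = sum((O - E)^2 / E)` with `E = n * (eh, 1 - eh)`,
#' `eh = ratio / (1 + ratio)`, compared to chi-square with 1 df. `direction`
#' is the sign of the observed het fraction minus `eh` (`"above"`, `"below"`,
#' `"at"`).
#'
#' @param nAB,nAA Heterozygote and homozygote counts (non-missing calls).
#' @param expected Expected het:hom ratio (e.g. 5 for 5:1, 1 for 1:1).
#' @return List: `statistic`, `p`, `direction`, `ratio` (observed nAB/nAA),
#'   `nAB`, `nAA`.
#' @examples
#' chisq_ratio_test(120, 0, expected = 5)  # X^2 = 24
#' @export
chisq_ratio_test <- function(nAB, nAA, expected = 5) {
  if (!is.numeric(expected) || expected <= 0) {
    stop("expected ratio must be positive")
  }
  n <- nAB + nAA
  if (n < 1) stop("no observations (nAB + nAA == 0)")
  eh <- expected / (1 + expected)
  e <- n * c(eh, 1 - eh)
  o <- c(nAB, nAA)
  stat <- sum((o - e)^2 / e)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  dir <- if (nAB / n > eh) "above" else if (nAB / n < eh) "below" else "at"
  list(statistic = stat, p = p, direction = dir,
       ratio = if (nAA > 0) nAB / nAA else Inf, nAB = nAB, nAA = nAA)
}

#' Per-marker segregation table
#'
#' For every marker of a genotype matrix: AA/AB counts, observed ratio, its
#' square root (the scale used to visualize mixtures of polysomic ratios),
#' and chi-square statistics against 1:1 and 5:1.
#'
#' @param matrix A `genotype_matrix`.
#' @return Data.frame with columns id, chrom, pos, nAA, nAB, ratio,
#'   sqrt_ratio, chisq_1_1, p_1_1, dir_1_1, chisq_5_1, p_5_1, dir_5_1.
#' @export
segregation_table <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (nrow(matrix$calls) == 0L) {
    return(data.frame(id = character(0), chrom = character(0),
                      pos = numeric(0), nAA = integer(0), nAB = integer(0),
                      ratio = numeric(0), sqrt_ratio = numeric(0),
                      chisq_1_1 = numeric(0), p_1_1 = numeric(0),
                      dir_1_1 = character(0), chisq_5_1 = numeric(0),
                      p_5_1 = numeric(0), dir_5_1 = character(0)))
  }
  nAA <- rowSums(matrix$calls == "AA", na.rm = TRUE)
  nAB <- rowSums(matrix$calls == "AB", na.rm = TRUE)
  res <- data.frame(id = rownames(matrix$calls),
                    chrom = matrix$markers$chrom, pos = matrix$markers$pos,
                    nAA = nAA, nAB = nAB,
                    ratio = ifelse(nAA > 0, nAB / nAA, Inf))
  res$sqrt_ratio <- sqrt(res$ratio)
  for (ex in c(1, 5)) {
    tests <- lapply(seq_len(nrow(res)), function(i) {
      chisq_ratio_test(nAB[i], nAA[i], expected = ex)
    })
    res[[sprintf("chisq_%d_1", ex)]] <-
      vapply(tests, `[[`, 0, "statistic")
    res[[sprintf("p_%d_1", ex)]] <- vapply(tests, `[[`, 0, "p")
    res[[sprintf("dir_%d_1", ex)]] <-
      vapply(tests, `[[`, "", "direction")
  }
  rownames(res) <- NULL
  res
}

#' Classify a linkage group by allele enrichment
#'
#' A group whose average AB/AA ratio exceeds `t_hi` is donor
#' (*S. halepense*) enriched — consistent with duplex donor markers; below
#' `t_lo` it is recurrent-parent (*S. bicolor*) enriched; otherwise allele
#' balanced (simplex-like). Boundary values classify as balanced (enrichment
#' requires strict inequality).
#'
#' @param ratio Group-average AB/AA ratio (>= 0).
#' @param t_hi,t_lo Classification thresholds (defaults 1.82 and 0.55).
#' @return List of class `group_class`: `class` (one of
#'   `"halepense_enriched"`, `"balanced"`, `"bicolor_enriched"`), `ratio`,
#'   `t_hi`, `t_lo`.
#' @examples
#' classify_group(3.84)$class  # halepense_enriched
#' classify_group(0.28)$class  # bicolor_enriched
#' @export
classify_group <- function(ratio, t_hi = 1.82, t_lo = 0.55) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio < 0)
    stop("ratio must be a single non-negative number")
  if (!(t_hi > 1 && t_lo < 1 && t_lo > 0)) {
    stop("thresholds must satisfy t_hi > 1 > t_lo > 0")
  }
  cls <- if (ratio > t_hi) "halepense_enriched"
         else if (ratio < t_lo) "bicolor_enriched"
         else "balanced"
  structure(list(class = cls, ratio = ratio, t_hi = t_hi, t_lo = t_lo),
            class = "group_class")
}

#' Enrichment thresholds implied by a chi-square test
#'
#' Solves for the AB/AA ratio at which a chi-square test of n calls against
#' 1:1 becomes significant at level `alpha`: `(nAB - nAA)^2 / n =
#' qchisq(1 - alpha, 1)` under `nAB + nAA = n`, giving
#' `t_hi = (sqrt(n) + sqrt(c)) / (sqrt(n) - sqrt(c))` and the reciprocal
#' `t_lo = 1 / t_hi`. A transparency companion to fixed printed thresholds,
#' useful for sensitivity analysis at other sample sizes or alpha levels.
#'
#' @param n Number of scored individuals (>= 2).
#' @param alpha Significance level in (0, 1).
#' @return List: `t_hi`, `t_lo`.
#' @examples
#' ratio_threshold_from_alpha(105, 0.001)  # t_hi ~ 1.95
#' @export
ratio_threshold_from_alpha <- function(n, alpha) {
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  crit <- stats::qchisq(1 - alpha, df = 1)
  if (crit >= n) stop("no attainable threshold: critical value >= n")
  t_hi <- (sqrt(n) + sqrt(crit)) / (sqrt(n) - sqrt(crit))
  list(t_hi = t_hi, t_lo = 1 / t_hi)
}

#' Markers with distorted segregation
#'
#' Flags markers whose chi-square test against the expected het:hom ratio is
#' significant at `alpha` in the requested direction. With
#' `method = "binomial"` an exact one-sided binomial tail is used instead of
#' the two-sided chi-square + direction filter.
#'
#' @param matrix A `genotype_matrix`.
#' @param expected Expected het:hom ratio (default 5, the duplex random
#'   chromosome expectation).
#' @param alpha Significance level (default 0.05).
#' @param direction `"above"`, `"below"`, or `"any"`.
#' @param method `"chisq"` (default) or `"binomial"`.
#' @return The [segregation_table()] rows of the flagged markers (with a
#'   `p_test` column for the test actually applied).
#' @export
detect_distorted_markers <- function(matrix, expected = 5, alpha = 0.05,
                                     direction = c("above", "below", "any"),
                                     method = c("chisq", "binomial")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  tab <- segregation_table(matrix)
  if (nrow(tab) == 0L) {
    tab$p_test <- numeric(0)
    return(tab)
  }
  eh <- expected / (1 + expected)
  n <- tab$nAA + tab$nAB
  if (method == "chisq") {
    tests <- lapply(seq_len(nrow(tab)), function(i) {
      chisq_ratio_test(tab$nAB[i], tab$nAA[i], expected = expected)
    })
    p <- vapply(tests, `[[`, 0, "p")
    dirs <- vapply(tests, `[[`, "", "direction")
  } else {
    p <- vapply(seq_len(nrow(tab)), function(i) {
      if (tab$nAB[i] / n[i] >= eh) {
        stats::pbinom(tab$nAB[i] - 1, n[i], eh, lower.tail = FALSE)
      } else {
        stats::pbinom(tab$nAB[i], n[i], eh)
      }
    }, 0)
    dirs <- ifelse(tab$nAB / n > eh, "above",
                   ifelse(tab$nAB / n < eh, "below", "at"))
  }
  keep <- p < alpha & (direction == "any" | dirs == direction)
  out <- tab[keep, , drop = FALSE]
  out$p_test <- p[keep]
  rownames(out) <- NULL
  out
}

#' Distortion shared across two populations
#'
#' Given per-marker segregation tables of two populations (from
#' [segregation_table()] over comparable marker ids), reports (1) the
#' markers individually significant in *both* populations, and (2) the
#' markers significant after pooling, i.e. summing AA/AB counts across
#' populations before one chi-square test (`pooling = "counts"`) or
#' combining the two per-population p-values by Fisher's method
#' (`pooling = "fisher"`).
#'
#' @param tabA,tabB [segregation_table()] data.frames.
#' @param expected Expected het:hom ratio (default 5).
#' @param alpha Significance level (default 0.05).
#' @param direction `"above"`, `"below"`, or `"any"`.
#' @param pooling `"counts"` (default) or `"fisher"`.
#' @return List: `intersection` (marker ids), `pooled` (marker ids),
#'   `pooled_table` (per-marker pooled counts and p).
#' @export
cross_population_distortion <- function(tabA, tabB, expected = 5,
                                        alpha = 0.05,
                                        direction = c("above", "below",
                                                      "any"),
                                        pooling = c("counts", "fisher")) {
  direction <- match.arg(direction)
  pooling <- match.arg(pooling)
  shared <- intersect(tabA$id, tabB$id)
  a <- tabA[match(shared, tabA$id), ]
  b <- tabB[match(shared, tabB$id), ]
  eh <- expected / (1 + expected)
  sig_one <- function(tab) {
    tests <- lapply(seq_len(nrow(tab)), function(i) {
      chisq_ratio_test(tab$nAB[i], tab$nAA[i], expected = expected)
    })
    p <- vapply(tests, `[[`, 0, "p")
    dirs <- vapply(tests, `[[`, "", "direction")
    p < alpha & (direction == "any" | dirs == direction)
  }
  inter <- shared[sig_one(a) & sig_one(b)]
  if (pooling == "counts") {
    nAB <- a$nAB + b$nAB
    nAA <- a$nAA + b$nAA
    tests <- lapply(seq_along(shared), function(i) {
      chisq_ratio_test(nAB[i], nAA[i], expected = expected)
    })
    p <- vapply(tests, `[[`, 0, "p")
    dirs <- vapply(tests, `[[`, "", "direction")
    pooled_tab <- data.frame(id = shared, nAB = nAB, nAA = nAA, p = p,
                             direction = dirs)
  } else {
    pa <- vapply(seq_len(nrow(a)), function(i) {
      chisq_ratio_test(a$nAB[i], a$nAA[i], expected)$p
    }, 0)
    pb <- vapply(seq_len(nrow(b)), function(i) {
      chisq_ratio_test(b$nAB[i], b$nAA[i], expected)$p
    }, 0)
    stat <- -2 * (log(pa) + log(pb))
    p <- stats::pchisq(stat, df = 4, lower.tail = FALSE)
    fr <- (a$nAB + b$nAB) / (a$nAB + a$nAA + b$nAB + b$nAA)
    dirs <- ifelse(fr > eh, "above", ifelse(fr < eh, "below", "at"))
    pooled_tab <- data.frame(id = shared, p = p, direction = dirs)
  }
  pooled <- pooled_tab$id[pooled_tab$p < alpha &
                            (direction == "any" |
                               pooled_tab$direction == direction)]
  list(intersection = inter, pooled = pooled, pooled_table = pooled_tab)
}

#' Distorted chromosomal regions
#'
#' Chains flagged markers along each chromosome: maximal runs with
#' inter-marker gaps at most `max_gap` bp and at least `min_markers` members
#' become regions, reported by the bp of their first and last marker.
#'
#' @param flagged Data.frame with columns `chrom`, `pos` (flagged markers;
#'   e.g. output of [detect_distorted_markers()]).
#' @param min_markers Minimum markers per region (default 3).
#' @param max_gap Maximum gap between consecutive flagged markers in bp
#'   (default 5e6).
#' @return Data.frame: chrom, start, end (1-based bp of first/last marker),
#'   n_markers.
#' @export
detect_distortion_regions <- function(flagged, min_markers = 3,
                                      max_gap = 5e6) {
  if (nrow(flagged) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_markers = integer(0)))
  }
  out <- list()
  for (cc in unique(flagged$chrom)) {
    pos <- sort(flagged$pos[flagged$chrom == cc])
    grp <- cumsum(c(1, diff(pos) > max_gap))
    for (g in split(pos, grp)) {
      if (length(g) >= min_markers) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = cc, start = min(g), end = max(g), n_markers = length(g))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_markers = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write distortion regions as BED
#'
#' Converts 1-based inclusive marker spans to 0-based half-open BED.
#'
#' @param regions Output of [detect_distortion_regions()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end,
                    name = paste0("region_", seq_len(nrow(regions))),
                    score = regions$n_markers)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
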