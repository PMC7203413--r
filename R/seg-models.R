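#' Autotetraploid segregation models
#'
#' A segregation model describes how an autotetraploid transmits a locus to
#' its gametes. The three classical named models correspond to fixed values of
#' the double-reduction coefficient alpha — the probability that a gamete
#' receives two sister-derived chromatids of the same parental homolog:
#' random chromosome segregation (no crossover between locus and centromere,
#' alpha = 0), random chromatid segregation (alpha = 1/7), and maximum
#' equational segregation (an obligate locus–centromere crossover,
#' alpha = 1/6). A `custom` model takes any alpha in \[0, 1/6\].
#'
#' @param name One of `"random_chromosome"`, `"random_chromatid"`,
#'   `"max_equational"`, `"custom"`.
#' @param alpha Double-reduction coefficient in \[0, 1/6\]; required (and only
#'   allowed) for `name = "custom"`.
#' @return An object of class `seg_model` with elements `name` and `alpha`.
#' @examples
#' seg_model("random_chromatid")$alpha  # 1/7
#' seg_model("custom", alpha = 0.1)
#' @export
seg_model <- function(name = c("random_chromosome", "random_chromatid",
                               "max_equational", "custom"),
                      alpha = NULL) {
  name <- match.arg(name)
  fixed <- c(random_chromosome = 0, random_chromatid = 1 / 7,
             max_equational = 1 / 6)
  if (name == "custom") {
    if (is.null(alpha)) {
      stop("a 'custom' segregation model requires an explicit alpha")
    }
    if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
        alpha < 0 || alpha > 1 / 6) {
      stop("alpha must be a single number in [0, 1/6], got: ",
           deparse(alpha))
    }
  } else {
    if (!is.null(alpha) && !isTRUE(all.equal(alpha, fixed[[name]]))) {
      stop("model '", name, "' has fixed alpha = ", fixed[[name]],
           "; do not supply a different value")
    }
    alpha <- fixed[[name]]
  }
  structure(list(name = name, alpha = as.numeric(alpha)),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat("<seg_model> ", x$name, " (alpha = ", format(x$alpha), ")\n", sep = "")
  invisible(x)
}

as_seg_model <- function(model) {
  if (inherits(model, "seg_model")) return(model)
  if (is.character(model) && length(model) == 1L) return(seg_model(model))
  stop("'model' must be a seg_model object or a model name")
}

new_dosage_distribution <- function(p0, p1, p2) {
  p <- c(p0 = p0, p1 = p1, p2 = p2)
  if (any(p < -1e-12) || any(p > 1 + 1e-12) || abs(sum(p) - 1) > 1e-12) {
    stop("invalid dosage distribution: ", paste(format(p), collapse = ", "))
  }
  structure(as.list(pmin(pmax(p, 0), 1)), class = "dosage_distribution")
}

#' @export
print.dosage_distribution <- function(x, ...) {
  cat(sprintf("<dosage_distribution> p0 = %s, p1 = %s, p2 = %s\n",
              format(x$p0), format(x$p1), format(x$p2)))
  invisible(x)
}

#' Gamete dosage distribution of a tetraploid parent
#'
#' Closed-form probabilities that a gamete of an autotetraploid carries 0, 1,
#' or 2 copies of the donor allele, given the parent's allele dosage (0–4) and
#' a segregation model. For a simplex parent (dosage 1) the distribution is
#' `(p2, p1, p0) = (a/4, (1-a)/2, 1/2 + a/4)`; for a duplex parent (dosage 2)
#' it is `((1+2a)/6, (4-4a)/6, (1+2a)/6)`, with `a` the double-reduction
#' coefficient. Dosages 3 and 4 follow by allele-swap symmetry (the
#' distribution of the donor dosage of a dosage-d parent is the reverse of
#' that of a dosage-(4-d) parent).
#'
#' @param f1_dosage Integer 0–4: copies of the donor allele among the four
#'   homologs of the parent.
#' @param model A [seg_model()] (or a model name).
#' @return A `dosage_distribution` with elements `p0`, `p1`, `p2` summing
#'   to 1.
#' @examples
#' gamete_dosage_distribution(2, "random_chromosome")  # p0 = 1/6 -> 5:1
#' @seealso [enumerate_chromatid_gametes()] for the brute-force oracle,
#'   [expected_bc1_ratio()] for the implied backcross progeny ratio.
#' @export
gamete_dosage_distribution <- function(f1_dosage, model) {
  model <- as_seg_model(model)
  if (!is.numeric(f1_dosage) || length(f1_dosage) != 1L ||
      is.na(f1_dosage) || f1_dosage != round(f1_dosage) ||
      f1_dosage < 0 || f1_dosage > 4) {
    stop("f1_dosage must be an integer in 0..4, got: ", deparse(f1_dosage))
  }
  a <- model$alpha
  d <- as.integer(f1_dosage)
  p <- switch(as.character(d),
    "0" = c(1, 0, 0),
    "1" = c(1 / 2 + a / 4, (1 - a) / 2, a / 4),
    "2" = c((1 + 2 * a) / 6, (4 - 4 * a) / 6, (1 + 2 * a) / 6),
    "3" = c(a / 4, (1 - a) / 2, 1 / 2 + a / 4),
    "4" = c(0, 0, 1)
  )
  new_dosage_distribution(p[1], p[2], p[3])
}

# Enumerate gamete donor-allele dosages for one fixed bivalent pairing under
# maximum equational segregation. 'homologs' is a 0/1 vector of length 4;
# 'pairing' a list of two index pairs. Each centromere unit ends up carrying
# one chromatid of each homolog of its bivalent; gametes are all pairs of
# chromatids not sharing a centromere unit.
.mes_counts_one_pairing <- function(homologs, pairing) {
  # unit k of bivalent (i,j): chromatid alleles {homologs[i], homologs[j]}
  units <- list()
  for (bv in pairing) {
    units <- c(units, list(homologs[bv]), list(homologs[bv]))
  }
  counts <- c(0L, 0L, 0L)  # dosage 0, 1, 2
  nu <- length(units)
  for (u in seq_len(nu - 1L)) {
    for (v in seq((u + 1L), nu)) {
      for (x in units[[u]]) {
        for (y in units[[v]]) {
          counts[x + y + 1L] <- counts[x + y + 1L] + 1L
        }
      }
    }
  }
  counts
}

#' Exhaustive enumeration of tetraploid gametes
#'
#' Brute-force oracle for [gamete_dosage_distribution()] under the three named
#' segregation models, by direct enumeration of chromatid combinations:
#' \describe{
#'   \item{random chromosome}{all unordered pairs of 2 of the 4 homologs
#'     (each contributing one chromatid): C(4,2) = 6 gametes;}
#'   \item{random chromatid}{all C(8,2) = 28 unordered pairs of the 8
#'     chromatids;}
#'   \item{maximum equational}{one obligate locus–centromere exchange per
#'     bivalent, so each centromere unit carries one chromatid of each
#'     homolog of its bivalent; gametes are the 24 chromatid pairs not
#'     sharing a centromere unit, averaged over the 3 bivalent pairings.}
#' }
#'
#' @inheritParams gamete_dosage_distribution
#' @param model One of the three *named* models; a custom alpha has no
#'   enumeration and is rejected.
#' @return A `dosage_distribution` (exact up to double precision of small
#'   integer ratios).
#' @examples
#' enumerate_chromatid_gametes(1, "max_equational")  # (13, 10, 1)/24
#' @export
enumerate_chromatid_gametes <- function(f1_dosage, model) {
  model <- as_seg_model(model)
  if (model$name == "custom") {
    stop("enumeration is only defined for the three named models")
  }
  if (!is.numeric(f1_dosage) || length(f1_dosage) != 1L ||
      is.na(f1_dosage) || f1_dosage != round(f1_dosage) ||
      f1_dosage < 0 || f1_dosage > 4) {
    stop("f1_dosage must be an integer in 0..4, got: ", deparse(f1_dosage))
  }
  d <- as.integer(f1_dosage)
  homologs <- c(rep(1L, d), rep(0L, 4L - d))
  counts <- c(0L, 0L, 0L)
  if (model$name == "random_chromosome") {
    pairs <- utils::combn(4L, 2L)
    for (k in seq_len(ncol(pairs))) {
      dos <- sum(homologs[pairs[, k]])
      counts[dos + 1L] <- counts[dos + 1L] + 1L
    }
  } else if (model$name == "random_chromatid") {
    chromatids <- rep(homologs, each = 2L)  # two sisters per homolog
    pairs <- utils::combn(8L, 2L)
    for (k in seq_len(ncol(pairs))) {
      dos <- sum(chromatids[pairs[, k]])
      counts[dos + 1L] <- counts[dos + 1L] + 1L
    }
  } else {  # max_equational
    pairings <- list(list(c(1L, 2L), c(3L, 4L)),
                     list(c(1L, 3L), c(2L, 4L)),
                     list(c(1L, 4L), c(2L, 3L)))
    for (pr in pairings) {
      counts <- counts + .mes_counts_one_pairing(homologs, pr)
    }
  }
  tot <- sum(counts)
  new_dosage_distribution(counts[1] / tot, counts[2] / tot, counts[3] / tot)
}

#' Expected heterozygote:homozygote ratio in BC1 progeny
#'
#' In a backcross of the F1 to an inbred recurrent parent contributing a null
#' (donor-allele-free) gamete, a progeny is heterozygous (donor allele
#' present) iff the F1 gamete carried at least one donor allele. The expected
#' het:hom ratio is therefore `(1 - p0) / p0` of the F1 gamete dosage
#' distribution: 1:1 (simplex) and 5:1 (duplex) under random chromosome
#' segregation, 13:15 and 11:3 under random chromatid segregation, 11:13 and
#' 7:2 under maximum equational segregation.
#'
#' @inheritParams gamete_dosage_distribution
#' @return The het:hom ratio as a single number.
#' @examples
#' expected_bc1_ratio(2, "random_chromosome")  # 5
#' expected_bc1_ratio(2, "max_equational")     # 3.5
#' @export
expected_bc1_ratio <- function(f1_dosage, model) {
  dist <- gamete_dosage_distribution(f1_dosage, model)
  if (dist$p0 <= 0) {
    stop("het:hom ratio undefined: every gamete carries the donor allele ",
         "(p0 = 0)")
  }
  (1 - dist$p0) / dist$p0
}
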