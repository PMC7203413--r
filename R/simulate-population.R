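# Meiosis simulator for a tetraploid F1 backcrossed to an inbred tetraploid
# recurrent parent. Linked mode models bivalent pairing with Haldane
# (no-interference) crossovers, which realizes alpha = 0 at every locus;
# alpha > 0 is available only in the single-locus (unlinked) mode.

# One recombinant chromatid from a bivalent of two homolog allele vectors
# (0/1 at each marker cM position in 'cm'). Crossovers: Poisson process of
# rate 1 per 100 cM along the chromosome; chromatid switches homolog at each
# crossover point; start homolog uniform.
.recombinant_chromatid <- function(hA, hB, cm, length_cm) {
  n_xo <- stats::rpois(1L, length_cm / 100)
  cur <- if (stats::runif(1L) < 0.5) 0L else 1L  # 0 = A, 1 = B
  if (n_xo == 0L) {
    return(if (cur == 0L) hA else hB)
  }
  breaks <- sort(stats::runif(n_xo, 0, length_cm))
  # homolog carried at position x: cur flipped once per break below x
  n_below <- findInterval(cm, breaks)
  use_b <- (cur + n_below) %% 2L == 1L
  ifelse(use_b, hB, hA)
}

#' Simulate a BC1F1 population from a tetraploid F1
#'
#' Simulates meioses of an autotetraploid F1 hybrid and backcross progeny
#' obtained by uniting each F1 gamete with a null gamete (no donor alleles)
#' from the inbred recurrent parent. Two modes:
#' \describe{
#'   \item{`linked` (default)}{full multilocus meiosis: per meiosis one of
#'     the 3 bivalent pairings of the 4 homologs is chosen uniformly,
#'     crossovers are laid down per bivalent as a no-interference (Haldane)
#'     Poisson process on the cM scale, and the gamete is one recombinant
#'     chromatid from each bivalent. This realizes a double-reduction
#'     coefficient of 0 at every locus and is only valid for models with
#'     alpha = 0.}
#'   \item{`single_locus`}{each marker is drawn independently from
#'     [gamete_dosage_distribution()]; supports any alpha but carries no
#'     linkage.}
#' }
#'
#' @param layout A [genome_layout()].
#' @param n Number of BC1 individuals (>= 1).
#' @param model A [seg_model()]; alpha > 0 requires `mode = "single_locus"`.
#' @param seed Integer seed; all randomness derives from it.
#' @param mode `"linked"` or `"single_locus"`.
#' @return An object of class `simulated_population`: list with `truth`
#'   (markers x individuals integer matrix of progeny donor dosage 0–2),
#'   `layout`, `model`, `seed`, `mode`.
#' @examples
#' lay <- regular_layout(n_chrom = 1, n_markers = 5)
#' pop <- simulate_bc1_population(lay, 20, seg_model("random_chromosome"),
#'                                seed = 1)
#' dim(pop$truth)
#' @export
simulate_bc1_population <- function(layout, n, model, seed,
                                    mode = c("linked", "single_locus")) {
  stopifnot(inherits(layout, "genome_layout"))
  mode <- match.arg(mode)
  model <- as_seg_model(model)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  if (mode == "linked" && model$alpha > 0) {
    stop("linked multilocus simulation only supports alpha = 0 ",
         "(random chromosome segregation); use mode = 'single_locus' ",
         "for alpha > 0")
  }
  mk <- layout$markers
  truth <- matrix(NA_integer_, nrow(mk), n,
                  dimnames = list(mk$id, sprintf("ind%03d", seq_len(n))))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  if (mode == "single_locus") {
    for (i in seq_len(nrow(mk))) {
      d <- gamete_dosage_distribution(mk$f1_dosage[i], model)
      truth[i, ] <- sample(0:2, n, replace = TRUE,
                           prob = c(d$p0, d$p1, d$p2))
    }
  } else {
    pairings <- list(list(c(1L, 2L), c(3L, 4L)),
                     list(c(1L, 3L), c(2L, 4L)),
                     list(c(1L, 4L), c(2L, 3L)))
    for (cc in seq_len(nrow(layout$chromosomes))) {
      chrom <- layout$chromosomes$chrom[cc]
      len_cm <- layout$chromosomes$length_cm[cc]
      idx <- which(mk$chrom == chrom)
      if (!length(idx)) next
      cm <- mk$cm[idx]
      # donor allele on homologs 1..d at every marker of this chromosome
      hom <- lapply(1:4, function(h) as.integer(mk$f1_dosage[idx] >= h))
      for (j in seq_len(n)) {
        pr <- pairings[[sample.int(3L, 1L)]]
        gam <- 0L
        for (bv in pr) {
          gam <- gam + .recombinant_chromatid(hom[[bv[1]]], hom[[bv[2]]],
                                              cm, len_cm)
        }
        truth[idx, j] <- gam
      }
    }
  }
  structure(list(truth = truth, layout = layout, model = model,
                 seed = as.integer(seed), mode = mode),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  cat(sprintf(
    "<simulated_population> %d markers x %d individuals (%s, %s, seed %d)\n",
    nrow(x$truth), ncol(x$truth), x$model$name, x$mode, x$seed))
  invisible(x)
}

#' Write a simulated truth matrix as CSV
#'
#' Markers x individuals, values 0/1/2 (progeny donor-allele dosage), with
#' `marker`, `chrom`, `pos` leading columns.
#'
#' @param pop A [simulate_bc1_population()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(pop, path) {
  stopifnot(inherits(pop, "simulated_population"))
  mk <- pop$layout$markers
  df <- cbind(data.frame(marker = mk$id, chrom = mk$chrom, pos = mk$pos),
              as.data.frame(pop$truth))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
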