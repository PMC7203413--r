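#' Define a synthetic genome layout
#'
#' A layout lists chromosomes with a physical length (bp), a genetic length
#' (cM), and the markers they carry. Each marker has a 1-based physical
#' position and the donor-allele dosage (0–4) of the F1 hybrid parent at that
#' locus; dosage 1 is a simplex marker, dosage 2 a duplex marker. Genetic
#' positions of markers are obtained by linear interpolation of bp onto the
#' chromosome's cM length.
#'
#' @param chromosomes A data.frame with columns `chrom`, `length_bp`,
#'   `length_cm`.
#' @param markers A data.frame with columns `id`, `chrom`, `pos` (1-based bp)
#'   and `f1_dosage` (integer 0–4). Markers are sorted by (chrom, pos).
#' @return An object of class `genome_layout`.
#' @examples
#' lay <- genome_layout(
#'   data.frame(chrom = "chr1", length_bp = 1e6, length_cm = 100),
#'   data.frame(id = c("m1", "m2"), chrom = "chr1",
#'              pos = c(1e5, 9e5), f1_dosage = c(1, 2)))
#' @export
genome_layout <- function(chromosomes, markers) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(markers))
  need_c <- c("chrom", "length_bp", "length_cm")
  need_m <- c("id", "chrom", "pos", "f1_dosage")
  if (!all(need_c %in% names(chromosomes))) {
    stop("chromosomes needs columns: ", paste(need_c, collapse = ", "))
  }
  if (!all(need_m %in% names(markers))) {
    stop("markers needs columns: ", paste(need_m, collapse = ", "))
  }
  chromosomes$chrom <- as.character(chromosomes$chrom)
  markers$chrom <- as.character(markers$chrom)
  markers$id <- as.character(markers$id)
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome names")
  if (anyDuplicated(markers$id)) stop("duplicated marker ids")
  if (any(chromosomes$length_cm <= 0)) stop("cM length must be > 0")
  if (any(chromosomes$length_bp < 1)) stop("bp length must be >= 1")
  if (!all(markers$chrom %in% chromosomes$chrom)) {
    stop("marker chromosome not in chromosome table")
  }
  if (any(markers$pos < 1)) stop("marker positions are 1-based (>= 1)")
  len <- stats::setNames(chromosomes$length_bp, chromosomes$chrom)
  if (any(markers$pos > len[markers$chrom])) {
    stop("marker position beyond chromosome length")
  }
  if (any(markers$f1_dosage != round(markers$f1_dosage)) ||
      any(markers$f1_dosage < 0) || any(markers$f1_dosage > 4)) {
    stop("f1_dosage must be integers in 0..4")
  }
  ord <- order(match(markers$chrom, chromosomes$chrom), markers$pos)
  markers <- markers[ord, need_m, drop = FALSE]
  rownames(markers) <- NULL
  cm_len <- stats::setNames(chromosomes$length_cm, chromosomes$chrom)
  markers$cm <- markers$pos / len[markers$chrom] * cm_len[markers$chrom]
  structure(list(chromosomes = chromosomes[, need_c], markers = markers),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), %d marker(s)\n",
              nrow(x$chromosomes), nrow(x$markers)))
  invisible(x)
}

#' Regularly spaced marker layout
#'
#' Convenience constructor: `n_markers` evenly spaced markers per chromosome
#' with dosages recycled from `dosages` (default alternating simplex/duplex).
#'
#' @param n_chrom Number of chromosomes.
#' @param length_bp,length_cm Per-chromosome physical and genetic length.
#' @param n_markers Markers per chromosome.
#' @param dosages F1 donor dosages recycled along each chromosome.
#' @return A [genome_layout()].
#' @export
regular_layout <- function(n_chrom = 1, length_bp = 1e7, length_cm = 100,
                           n_markers = 50, dosages = c(1, 2)) {
  chroms <- data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                       length_bp = length_bp, length_cm = length_cm)
  pos <- round(seq(length_bp / (n_markers + 1), length_bp * n_markers /
                     (n_markers + 1), length.out = n_markers))
  mk <- do.call(rbind, lapply(chroms$chrom, function(cc) {
    data.frame(id = sprintf("%s_m%03d", cc, seq_len(n_markers)),
               chrom = cc, pos = pos,
               f1_dosage = rep_len(dosages, n_markers))
  }))
  genome_layout(chroms, mk)
}
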