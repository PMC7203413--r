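# Progenitor-origin classification of hybrid-polyploid alleles: each variant
# site of a target (S. halepense-like) sample is compared against the
# reference (S. bicolor BTx623-like), one or two S. propinquum accessions,
# and a divergent S. bicolor control, then tallied genome-wide and scanned
# for runs of consecutive propinquum-derived alleles.

ANCESTRY_LEVELS <- c("B", "H_BP", "H_PM", "N_M", "P", "UNKNOWN")

#' Filter whole-genome variant sites
#'
#' Site-level filter ahead of ancestry classification: QUAL at least
#' `min_qual`, per-sample calls with depth below `min_depth` treated as
#' missing, and sites whose missing fraction (over all samples) exceeds
#' `max_missing` removed.
#'
#' @param records A `site_records` object (see [read_vcf_records()]).
#' @param min_qual Minimum site QUAL (default 20, i.e. Q20).
#' @param min_depth Minimum per-sample depth for a usable call (default 10).
#' @param max_missing Maximum fraction of missing samples per site
#'   (default 0.30).
#' @return Filtered `site_records`, with an added logical matrix
#'   `usable` (sites x samples: genotype present and depth sufficient).
#' @export
filter_sites <- function(records, min_qual = 20, min_depth = 10,
                         max_missing = 0.30) {
  stopifnot(inherits(records, "site_records"))
  if (is.null(records$gt)) stop("records carry no GT field")
  dp <- records$dp
  dp[is.na(dp)] <- 0
  gt_missing <- is.na(records$gt) |
    records$gt %in% c("./.", ".", ".|.")
  usable <- !gt_missing & dp >= min_depth
  qual_ok <- !is.na(records$sites$qual) & records$sites$qual >= min_qual
  miss_frac <- rowMeans(!usable)
  keep <- which(qual_ok & miss_frac <= max_missing)
  out <- .subset_records(records, keep)
  out$usable <- usable[keep, , drop = FALSE]
  out
}

# parse one VCF GT string into integer allele indices, NA when missing
.gt_alleles <- function(gt) {
  if (is.na(gt) || gt %in% c("./.", ".", ".|.")) return(NULL)
  a <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (anyNA(a)) return(NULL)
  a
}

#' Classify the progenitor origin of one site
#'
#' Allele-level decision for a target (hybrid) genotype against candidate
#' progenitors. Each target allele is labelled *bicolor* (matches the
#' reference allele), *propinquum* (member of the propinquum allele set,
#' i.e. the non-reference alleles carried by the propinquum accession(s)),
#' or *novel* (matches neither). The site category is then:
#' \describe{
#'   \item{B}{both alleles bicolor (identical to the reference parent);}
#'   \item{P}{both alleles propinquum;}
#'   \item{H_BP}{heterozygous bicolor/propinquum;}
#'   \item{H_PM}{heterozygous propinquum/novel;}
#'   \item{N_M}{a novel allele present and no propinquum allele;}
#'   \item{UNKNOWN}{target or a required progenitor genotype missing, or
#'     the bicolor control differs from the reference (intra-bicolor
#'     polymorphism makes the reference allele uninformative of origin).}
#' }
#' With two propinquum accessions, `propinquum_consensus = "all"` (default)
#' demands agreement of their allele sets (disagreement gives UNKNOWN);
#' `"any"` takes the union.
#'
#' @param target_gt Target sample GT string (e.g. `"0/1"`).
#' @param propinquum_gts Character vector of 1–2 propinquum GT strings.
#' @param control_gt Divergent bicolor control GT string.
#' @param propinquum_consensus `"all"` or `"any"`.
#' @return One of `"B"`, `"P"`, `"H_BP"`, `"H_PM"`, `"N_M"`, `"UNKNOWN"`.
#' @examples
#' classify_site("0/0", "1/1", "0/0")  # "B"
#' classify_site("0/1", "1/1", "0/0")  # "H_BP"
#' classify_site("0/1", "1/1", "1/1")  # "UNKNOWN" (control off-reference)
#' @export
classify_site <- function(target_gt, propinquum_gts, control_gt,
                          propinquum_consensus = c("all", "any")) {
  propinquum_consensus <- match.arg(propinquum_consensus)
  tgt <- .gt_alleles(target_gt)
  ctl <- .gt_alleles(control_gt)
  if (is.null(tgt) || is.null(ctl)) return("UNKNOWN")
  if (any(ctl != 0L)) return("UNKNOWN")
  psets <- lapply(propinquum_gts, .gt_alleles)
  if (any(vapply(psets, is.null, TRUE))) return("UNKNOWN")
  psets <- lapply(psets, function(a) sort(unique(a[a != 0L])))
  if (propinquum_consensus == "all" && length(psets) > 1L) {
    if (!all(vapply(psets[-1], identical, TRUE, psets[[1]]))) {
      return("UNKNOWN")
    }
    pset <- psets[[1]]
  } else {
    pset <- sort(unique(unlist(psets)))
  }
  lab <- ifelse(tgt == 0L, "b", ifelse(tgt %in% pset, "p", "n"))
  has_p <- any(lab == "p"); has_b <- any(lab == "b"); has_n <- any(lab == "n")
  if (all(lab == "b")) return("B")
  if (all(lab == "p")) return("P")
  if (has_b && has_p && !has_n) return("H_BP")
  if (has_p && has_n) return("H_PM")
  "N_M"
}

#' Classify every filtered site of a trio-style VCF
#'
#' Applies [classify_site()] along all sites of filtered `site_records`,
#' with sample roles named in `roles`. Samples unusable at a site (per the
#' `usable` matrix from [filter_sites()]) count as missing.
#'
#' @param records Filtered `site_records` (from [filter_sites()]).
#' @param roles Named list/character vector: `target`, `control`, and one or
#'   two of `propinquum_1`, `propinquum_2`, giving sample names.
#' @param propinquum_consensus Passed to [classify_site()].
#' @return An `ancestry_track`: data.frame with chrom, pos, id, category
#'   (ordered by chrom, pos; positions strictly increasing within
#'   chromosome).
#' @export
classify_sites <- function(records, roles,
                           propinquum_consensus = c("all", "any")) {
  propinquum_consensus <- match.arg(propinquum_consensus)
  need <- c("target", "control", "propinquum_1")
  if (!all(need %in% names(roles))) {
    stop("roles must name at least: ", paste(need, collapse = ", "))
  }
  prop_roles <- intersect(c("propinquum_1", "propinquum_2"), names(roles))
  all_samp <- unlist(roles[c("target", "control", prop_roles)])
  if (!all(all_samp %in% records$samples)) {
    stop("role sample(s) not in VCF: ",
         paste(setdiff(all_samp, records$samples), collapse = ", "))
  }
  usable <- records$usable
  if (is.null(usable)) {
    usable <- matrix(TRUE, nrow(records$sites), length(records$samples),
                     dimnames = list(records$sites$id, records$samples))
  }
  gt_of <- function(sample, i) {
    if (!usable[i, sample]) return(NA_character_)
    records$gt[i, sample]
  }
  n <- nrow(records$sites)
  cat_out <- character(n)
  for (i in seq_len(n)) {
    cat_out[i] <- classify_site(
      gt_of(roles[["target"]], i),
      vapply(prop_roles, function(r) gt_of(roles[[r]], i), ""),
      gt_of(roles[["control"]], i),
      propinquum_consensus = propinquum_consensus)
  }
  track <- data.frame(chrom = records$sites$chrom, pos = records$sites$pos,
                      id = records$sites$id, category = cat_out)
  track <- track[order(track$chrom, track$pos), ]
  rownames(track) <- NULL
  class(track) <- c("ancestry_track", "data.frame")
  track
}

#' Tally ancestry categories
#'
#' Counts per category and proportions over the classified (non-UNKNOWN)
#' sites — UNKNOWN sites are excluded from the percentage denominator.
#'
#' @param track An `ancestry_track` (or data.frame with a `category`
#'   column).
#' @return Data.frame: category, count, proportion (NA for UNKNOWN;
#'   non-UNKNOWN proportions sum to 1).
#' @export
tally_categories <- function(track) {
  counts <- table(factor(track$category, levels = ANCESTRY_LEVELS))
  known <- sum(counts[names(counts) != "UNKNOWN"])
  if (known == 0L) stop("no classified (non-UNKNOWN) sites")
  prop <- as.numeric(counts) / known
  prop[names(counts) == "UNKNOWN"] <- NA_real_
  data.frame(category = names(counts), count = as.integer(counts),
             proportion = prop)
}

#' Runs of consecutive same-origin sites
#'
#' Maximal blocks of at least `min_run` consecutive sites (along each
#' chromosome of the ordered track) all assigned to `target_category`,
#' reported as the bp span of the first to last member site.
#'
#' @param track An `ancestry_track`.
#' @param target_category Category forming runs (default `"P"`).
#' @param min_run Minimum sites per run (default 3).
#' @return Data.frame: chrom, start, end (bp of first/last site), n_sites.
#' @export
detect_runs <- function(track, target_category = "P", min_run = 3) {
  out <- list()
  for (cc in unique(track$chrom)) {
    sub <- track[track$chrom == cc, ]
    if (is.unsorted(sub$pos, strictly = TRUE)) {
      stop("track positions must be strictly increasing within chromosome")
    }
    hit <- sub$category == target_category
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start = sub$pos[starts[k]], end = sub$pos[ends[k]],
        n_sites = r$lengths[k])
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome fraction covered by runs
#'
#' Overlapping runs are merged per chromosome, then
#' `sum(end - start + 1) / sum(chromosome lengths)`.
#'
#' @param runs Data.frame from [detect_runs()] (chrom, start, end).
#' @param chrom_sizes Data.frame with columns `chrom`, `length_bp`.
#' @return Single number in \[0, 1\].
#' @export
run_coverage <- function(runs, chrom_sizes) {
  stopifnot(all(c("chrom", "length_bp") %in% names(chrom_sizes)))
  total <- sum(as.numeric(chrom_sizes$length_bp))
  if (nrow(runs) == 0L) return(0)
  if (!all(runs$chrom %in% chrom_sizes$chrom)) {
    stop("run on unknown chromosome")
  }
  len <- stats::setNames(chrom_sizes$length_bp, chrom_sizes$chrom)
  if (any(runs$end > len[runs$chrom])) {
    stop("run extends beyond chromosome end")
  }
  covered <- 0
  for (cc in unique(runs$chrom)) {
    iv <- runs[runs$chrom == cc, c("start", "end")]
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    cur_s <- iv$start[1]; cur_e <- iv$end[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] <= cur_e + 1) {
        cur_e <- max(cur_e, iv$end[i])
      } else {
        covered <- covered + (cur_e - cur_s + 1)
        cur_s <- iv$start[i]; cur_e <- iv$end[i]
      }
    }
    covered <- covered + (cur_e - cur_s + 1)
  }
  covered / total
}

#' Summarize a two-population run table
#'
#' Bookkeeping over a table of progenitor-allele runs observed in two
#' populations (one row per distinct run; per-population start/end columns
#' are NA when the run was not observed in that population): run counts per
#' population, runs shared by both, and distinct runs overall.
#'
#' @param runs Data.frame with columns `start_a`, `end_a`, `start_b`,
#'   `end_b` (bp; NA = absent in that population).
#' @return List: `n_a`, `n_b`, `n_shared`, `n_distinct`.
#' @export
summarize_run_table <- function(runs) {
  in_a <- !is.na(runs$start_a) & !is.na(runs$end_a)
  in_b <- !is.na(runs$start_b) & !is.na(runs$end_b)
  if (any(!in_a & !in_b)) stop("row present in neither population")
  list(n_a = sum(in_a), n_b = sum(in_b), n_shared = sum(in_a & in_b),
       n_distinct = nrow(runs))
}

#' Write ancestry outputs
#'
#' Per-site classification TSV, category summary CSV, and runs as BED
#' (0-based half-open).
#'
#' @param track An `ancestry_track`.
#' @param runs Data.frame from [detect_runs()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ancestry_files <- function(track, runs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(track),
                     file.path(dir, "ancestry_sites.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(tally_categories(track),
                   file.path(dir, "ancestry_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  if (nrow(runs)) {
    bed <- data.frame(chrom = runs$chrom, start = runs$start - 1L,
                      end = runs$end,
                      name = paste0("run_", seq_len(nrow(runs))),
                      score = runs$n_sites)
  } else {
    bed <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0))
  }
  utils::write.table(bed, file.path(dir, "propinquum_runs.bed"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}
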