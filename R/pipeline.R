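# End-to-end orchestration: a validated flat config carrying every threshold
# of the analysis (each defaulting to its published value), stage runners,
# and fixture generation. Stages: simulate -> call -> map -> segregate
# (+ ancestry when sample roles are configured).

.default_config <- function() {
  list(
    # stage toggles
    stages = c("simulate", "call", "map", "segregate"),
    # genotype calling
    min_spacing = 100, min_avg_depth = 10, ambiguity = 0.05,
    hom_min_depth = 6, bb_policy = "het", max_marker_missing = 0.3,
    min_called_fraction = 0.2,
    # map construction
    min_lod = 10, bin_cm = 1, error_prob = 0.01,
    # segregation analysis
    t_hi = 1.82, t_lo = 0.55, alpha_marker = 0.05, alpha_group = 0.001,
    expected_duplex_ratio = 5, min_region_markers = 3, max_region_gap = 5e6,
    # ancestry
    min_qual = 20, anc_min_depth = 10, anc_max_missing = 0.30, min_run = 3,
    roles = NULL, ancestry_vcf = NULL, chrom_sizes = NULL,
    # simulation
    n_individuals = 141, n_chrom = 2, n_markers = 50, length_bp = 1e7,
    length_cm = 120, dosages = c(1, 2), model = "random_chromosome",
    mean_depth = 30, gbs_error_rate = 0.002,
    # io
    vcf = NULL, out_dir = "tetrabc_out", seed = 1
  )
}

#' Build and validate a pipeline configuration
#'
#' Returns the default configuration with the supplied overrides applied.
#' Every numeric threshold defaults to the value used throughout the
#' package's analysis conventions (100-bp thinning, mean depth 10, 0.05
#' ambiguity, 6x homozygote floor, LOD 10, 1-cM bins, 0.01 map error
#' probability, 1.82/0.55 enrichment thresholds, alpha 0.05/0.001, Q20/10x/
#' 30% site filters, 3-site runs). Unknown keys are rejected by name.
#' Configurations round-trip losslessly through YAML via
#' [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param ... Named overrides of default fields.
#' @return A named list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(seed = 7, n_individuals = 50)
#' @export
pipeline_config <- function(...) {
  cfg <- .default_config()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all config overrides must be named")
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages and writes all artifacts under
#' `config$out_dir`:
#' \describe{
#'   \item{simulate}{BC1 population + GBS VCF (`simulated.vcf`,
#'     `truth.csv`) from the configured layout, model and seed;}
#'   \item{call}{thinning, biallelic/depth filtering, PL-based calling,
#'     marker and individual filtering (`genotypes.csv`, `marker_qc.csv`);}
#'   \item{map}{LOD clustering, 1-cM binning, de novo ordering, EM map
#'     estimation (`maps/` with per-group TSVs and `map_summary.csv`);}
#'   \item{segregate}{per-marker segregation tests, per-group enrichment
#'     classes, distorted markers and regions (`segregation.csv`,
#'     `group_classes.csv`, `distorted_markers.csv`,
#'     `distortion_regions.bed`);}
#'   \item{ancestry}{progenitor-origin classification and runs, when
#'     `config$roles` and an ancestry VCF are set (`ancestry/`).}
#' }
#' A `pipeline_log.txt` records marker counts surviving each filter step and
#' every threshold actually used. All outputs are reproducible from
#' (config, seed).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the principal in-memory results
#'   (`matrix`, `groups`, `segregation`, `classes`, `ancestry`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline_log.txt")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat("", file = log_path)  # truncate
  logf("tetrabc pipeline | seed %d", config$seed)
  for (k in c("min_spacing", "min_avg_depth", "ambiguity", "hom_min_depth",
              "max_marker_missing", "min_called_fraction", "min_lod",
              "bin_cm", "error_prob", "t_hi", "t_lo", "alpha_marker",
              "alpha_group", "min_region_markers", "max_region_gap")) {
    logf("config %s = %s", k, format(config[[k]]))
  }
  res <- list()
  vcf_path <- config$vcf

  if ("simulate" %in% config$stages) {
    layout <- regular_layout(n_chrom = config$n_chrom,
                             length_bp = config$length_bp,
                             length_cm = config$length_cm,
                             n_markers = config$n_markers,
                             dosages = config$dosages)
    pop <- simulate_bc1_population(layout, config$n_individuals,
                                   config$model, seed = config$seed)
    vcf_path <- file.path(config$out_dir, "simulated.vcf")
    simulate_gbs_vcf(pop, mean_depth = config$mean_depth,
                     error_rate = config$gbs_error_rate,
                     seed = config$seed + 1L, out = vcf_path)
    write_truth_csv(pop, file.path(config$out_dir, "truth.csv"))
    res$population <- pop
    logf("simulate: %d markers x %d individuals -> %s",
         nrow(pop$truth), ncol(pop$truth), vcf_path)
  }

  if ("call" %in% config$stages) {
    if (is.null(vcf_path)) stop("no VCF: set config$vcf or enable simulate")
    rec <- read_vcf_records(vcf_path)
    logf("call: %d raw sites", nrow(rec$sites))
    rec <- thin_sites(rec, min_spacing = config$min_spacing)
    logf("call: %d sites after %d-bp thinning", nrow(rec$sites),
         config$min_spacing)
    rec <- filter_biallelic_depth(rec, min_avg_depth = config$min_avg_depth)
    logf("call: %d biallelic sites with mean depth >= %s", nrow(rec$sites),
         format(config$min_avg_depth))
    mat <- build_matrix(rec, max_marker_missing = config$max_marker_missing,
                        ambiguity = config$ambiguity,
                        hom_min_depth = config$hom_min_depth,
                        bb_policy = config$bb_policy)
    logf("call: %d polymorphic markers after calling", nrow(mat$calls))
    mat <- drop_low_coverage_individuals(
      mat, min_called_fraction = config$min_called_fraction)
    logf("call: %d individuals retained", ncol(mat$calls))
    write_genotype_csv(mat, file.path(config$out_dir, "genotypes.csv"),
                       qc_path = file.path(config$out_dir, "marker_qc.csv"))
    res$matrix <- mat
  }

  if ("map" %in% config$stages) {
    if (is.null(res$matrix)) stop("map stage requires the call stage")
    groups <- build_linkage_groups(res$matrix, min_lod = config$min_lod,
                                   bin_cm = config$bin_cm,
                                   error_prob = config$error_prob)
    write_map_files(groups, file.path(config$out_dir, "maps"))
    logf("map: %d linkage groups", length(groups))
    res$groups <- groups
  }

  if ("segregate" %in% config$stages) {
    if (is.null(res$matrix)) stop("segregate stage requires the call stage")
    seg <- segregation_table(res$matrix)
    utils::write.csv(seg, file.path(config$out_dir, "segregation.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(res$groups) && length(res$groups)) {
      classes <- do.call(rbind, lapply(res$groups, function(g) {
        cl <- classify_group(g$summary$ab_aa_ratio, t_hi = config$t_hi,
                             t_lo = config$t_lo)
        data.frame(LG = g$id, ratio = round(cl$ratio, 2), class = cl$class)
      }))
      rownames(classes) <- NULL
      utils::write.csv(classes,
                       file.path(config$out_dir, "group_classes.csv"),
                       row.names = FALSE, quote = FALSE)
      res$classes <- classes
      logf("segregate: group classes: %s",
           paste(sprintf("%s=%s", classes$LG, classes$class),
                 collapse = ", "))
    }
    flagged <- detect_distorted_markers(
      res$matrix, expected = config$expected_duplex_ratio,
      alpha = config$alpha_marker, direction = "above")
    utils::write.csv(flagged,
                     file.path(config$out_dir, "distorted_markers.csv"),
                     row.names = FALSE, quote = FALSE)
    regions <- detect_distortion_regions(
      flagged, min_markers = config$min_region_markers,
      max_gap = config$max_region_gap)
    write_regions_bed(regions,
                      file.path(config$out_dir, "distortion_regions.bed"))
    logf("segregate: %d markers distorted above %s:1 at alpha %s; %d regions",
         nrow(flagged), format(config$expected_duplex_ratio),
         format(config$alpha_marker), nrow(regions))
    res$segregation <- seg
    res$distorted <- flagged
    res$regions <- regions
  }

  if ("ancestry" %in% config$stages) {
    if (is.null(config$ancestry_vcf) || is.null(config$roles)) {
      stop("ancestry stage requires config$ancestry_vcf and config$roles")
    }
    rec <- read_vcf_records(config$ancestry_vcf)
    rec <- filter_sites(rec, min_qual = config$min_qual,
                        min_depth = config$anc_min_depth,
                        max_missing = config$anc_max_missing)
    track <- classify_sites(rec, config$roles)
    runs <- detect_runs(track, target_category = "P",
                        min_run = config$min_run)
    write_ancestry_files(track, runs,
                         file.path(config$out_dir, "ancestry"))
    logf("ancestry: %d sites classified, %d propinquum runs",
         nrow(track), nrow(runs))
    if (!is.null(config$chrom_sizes)) {
      cov <- run_coverage(runs, config$chrom_sizes)
      logf("ancestry: runs cover %.2f%% of the genome", 100 * cov)
      attr(runs, "coverage") <- cov
    }
    res$ancestry <- list(track = track, runs = runs)
  }

  invisible(res)
}

#' Cluster, bin, order and map all markers
#'
#' Convenience wrapper chaining [cluster_markers()], [bin_markers()],
#' [order_markers()] and [estimate_map()] over a genotype matrix. Groups are
#' labelled by base chromosome plus a letter (`"chr1A"`, `"chr1B"`, ...)
#' in physical order.
#'
#' @param matrix A `genotype_matrix`.
#' @param min_lod,bin_cm,error_prob See the stage functions.
#' @param min_group_size Groups smaller than this are dropped from mapping
#'   (default 2; singletons carry no interval information).
#' @return List of `linkage_group` objects.
#' @export
build_linkage_groups <- function(matrix, min_lod = 10, bin_cm = 1,
                                 error_prob = 0.01, min_group_size = 2) {
  groups <- cluster_markers(matrix, min_lod = min_lod)
  groups <- groups[vapply(groups, length, 0L) >= min_group_size]
  base_chrom <- vapply(groups, function(ids) {
    mk <- matrix$markers
    chroms <- mk$chrom[match(ids, mk$id)]
    names(sort(table(chroms), decreasing = TRUE))[1]
  }, "")
  out <- list()
  for (cc in unique(base_chrom)) {
    idx <- which(base_chrom == cc)
    for (k in seq_along(idx)) {
      ids <- groups[[idx[k]]]
      gm <- subset_markers(matrix, ids)
      binned <- bin_markers(gm, bin_cm = bin_cm)
      ord <- order_markers(binned$matrix)
      gm_ord <- subset_markers(binned$matrix, ord)
      lg_id <- paste0(cc, LETTERS[k])
      out[[lg_id]] <- estimate_map(gm_ord, id = lg_id,
                                   error_prob = error_prob)
    }
  }
  out
}

#' Generate the packaged test fixtures
#'
#' Writes small deterministic datasets used by the test suite and examples:
#' a tiny simulated GBS VCF with its truth matrix, and a synthetic
#' progenitor-trio VCF with a known mosaic target genome.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param scale `"tiny"` (default; <= 1000 sites, runs in seconds) or
#'   `"small"`.
#' @return Named list of file paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1, scale = c("tiny", "small")) {
  scale <- match.arg(scale)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_mark <- if (scale == "tiny") 40 else 200
  n_ind <- if (scale == "tiny") 24 else 96
  layout <- regular_layout(n_chrom = 2, length_bp = 1e6, length_cm = 100,
                           n_markers = n_mark)
  pop <- simulate_bc1_population(layout, n_ind, "random_chromosome",
                                 seed = seed)
  vcf <- file.path(dir, "gbs_sim.vcf")
  simulate_gbs_vcf(pop, mean_depth = 30, error_rate = 0.002,
                   seed = seed + 1L, out = vcf)
  truth <- file.path(dir, "gbs_truth.csv")
  write_truth_csv(pop, truth)
  trio <- file.path(dir, "mosaic_trio.vcf")
  write_mosaic_trio_vcf(trio, seed = seed + 2L,
                        n_sites = if (scale == "tiny") 120 else 600)
  invisible(list(vcf = vcf, truth = truth, trio = trio))
}

#' Synthetic progenitor-trio VCF with a mosaic target
#'
#' Builds a labelled-synthetic VCF of four samples — target (hybrid),
#' control (divergent sibling of the reference), and two propinquum-like
#' accessions — where the target genome is spliced from known progenitor
#' blocks, alternating bicolor-derived and propinquum-derived segments per
#' chromosome. The true block structure is attached as attribute
#' `"blocks"` of the returned path and encoded in the site IDs'
#' deterministic layout, so recovery can be checked exactly.
#'
#' @param out VCF path.
#' @param seed Integer seed (site spacing only; categories are
#'   deterministic).
#' @param n_sites Sites per chromosome (2 chromosomes).
#' @param block_size Sites per origin block (default 10).
#' @return `out` with attribute `blocks` (data.frame chrom, start_index,
#'   end_index, origin), invisibly.
#' @export
write_mosaic_trio_vcf <- function(out, seed = 1, n_sites = 120,
                                  block_size = 10) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  samples <- c("target", "control", "prop1", "prop2")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=tetrabc_mosaic_trio[synthetic]",
    sprintf("##contig=<ID=chr%d,length=%d>", 1:2, 10010000L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  blocks <- list()
  for (cc in 1:2) {
    pos <- sort(sample.int(1e7, n_sites))
    origin_of_block <- rep(c("P", "B"), length.out = ceiling(
      n_sites / block_size))
    if (cc == 2L) origin_of_block <- rev(origin_of_block)
    for (i in seq_len(n_sites)) {
      b <- ceiling(i / block_size)
      origin <- origin_of_block[b]
      # propinquum carries alt everywhere; target follows its block origin
      tgt <- if (origin == "P") "1/1" else "0/0"
      lines <- c(lines, paste(
        c(paste0("chr", cc), pos[i],
          sprintf("chr%d_s%04d", cc, i), "A", "G", "60", "PASS", ".",
          "GT:DP",
          paste0(tgt, ":30"), "0/0:30", "1/1:30", "1/1:30"),
        collapse = "\t"))
    }
    for (b in seq_along(origin_of_block)) {
      lo <- (b - 1L) * block_size + 1L
      hi <- min(b * block_size, n_sites)
      if (lo > n_sites) break
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = paste0("chr", cc), start_index = lo, end_index = hi,
        start_bp = pos[lo], end_bp = pos[hi],
        origin = origin_of_block[b])
    }
  }
  writeLines(lines, out)
  out_path <- out
  attr(out_path, "blocks") <- do.call(rbind, blocks)
  invisible(out_path)
}
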