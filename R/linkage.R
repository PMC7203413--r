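# Linkage map construction on presence/absence (AA/AB) backcross coding:
# two-point recombination fractions and LOD scores, single-linkage LOD
# clustering, physical-order 1-cM binning, de novo seriation ordering, and
# error-aware EM re-estimation of interval rfs with Kosambi distances.

#' Kosambi mapping function and its inverse
#'
#' `kosambi(r)` converts a recombination fraction to map distance,
#' d = 25 ln((1+2r)/(1-2r)) cM; `kosambi_inv(d)` converts back,
#' r = tanh(d/50)/2.
#'
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @param d Map distance(s) in cM.
#' @return Numeric vector.
#' @examples
#' kosambi(0.2)        # ~21.18 cM
#' kosambi_inv(21.18)  # ~0.2
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) stop("r must be in [0, 0.5]")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0")
  tanh(d / 50) / 2
}

# cap rfs away from 0.5 before Kosambi to keep distances finite
.RF_CAP <- 0.4995

#' Two-point linkage between two markers
#'
#' Backcross coding: an individual is a recombinant iff its calls at the two
#' markers differ. The recombination fraction estimate is
#' recombinants / informative (capped at 0.5); if it exceeds 0.5 the phase is
#' flipped (rf := 1 - rf, `phase_flip = TRUE`). The LOD score is
#' `n * (r*log10(2r) + (1-r)*log10(2(1-r)))` with the r = 0 limit
#' `n*log10(2)`.
#'
#' @param colA,colB Character vectors of calls (`"AA"`/`"AB"`/`NA`) over the
#'   same individuals.
#' @return A list of class `pair_linkage`: `rf`, `lod`, `n_informative`,
#'   `phase_flip`, `defined` (FALSE when fewer than 2 informative
#'   individuals, in which case rf = 0.5, lod = 0).
#' @examples
#' a <- rep(c("AA", "AB"), 50)
#' estimate_rf(a, a)$lod  # 100 * log10(2) ~ 30.1
#' @export
estimate_rf <- function(colA, colB) {
  inf <- !is.na(colA) & !is.na(colB)
  n <- sum(inf)
  if (n < 2L) {
    return(structure(list(rf = 0.5, lod = 0, n_informative = n,
                          phase_flip = FALSE, defined = FALSE),
                     class = "pair_linkage"))
  }
  k <- sum(colA[inf] != colB[inf])
  r <- k / n
  flip <- r > 0.5
  if (flip) r <- 1 - r
  lod <- .lod_bc(r, n)
  structure(list(rf = r, lod = lod, n_informative = n, phase_flip = flip,
                 defined = TRUE),
            class = "pair_linkage")
}

.lod_bc <- function(r, n) {
  t1 <- ifelse(r == 0, 0, r * log10(2 * r))
  t2 <- ifelse(r == 1, 0, (1 - r) * log10(2 * (1 - r)))
  n * (t1 + t2)
}

# All pairwise rf/lod/n matrices for a calls matrix (markers x individuals).
# Vectorized via cross-products of indicator matrices.
.pairwise_linkage <- function(calls) {
  ab <- t(calls == "AB"); ab[is.na(ab)] <- FALSE
  aa <- t(calls == "AA"); aa[is.na(aa)] <- FALSE
  obs <- ab | aa
  n <- crossprod(obs * 1)
  same <- crossprod(ab * 1) + crossprod(aa * 1)
  rec <- n - same
  rf <- ifelse(n > 0, rec / n, 0.5)
  flip <- rf > 0.5
  rf[flip] <- 1 - rf[flip]
  lod <- .lod_bc(rf, n)
  undef <- n < 2
  rf[undef] <- 0.5
  lod[undef] <- 0
  diag(lod) <- 0
  list(rf = rf, lod = lod, n = n, phase_flip = flip)
}

#' Cluster markers into linkage groups
#'
#' Single-linkage transitive closure over marker pairs with LOD at or above
#' `min_lod` and estimated rf below 0.5 (the rf condition prevents pure
#' segregation-distortion co-occurrence from linking markers). Every marker
#' falls in exactly one group; singletons are allowed. Groups are ordered by
#' (chromosome, position) of their first marker and markers within a group
#' by (chromosome, position).
#'
#' @param matrix A `genotype_matrix`.
#' @param min_lod Minimum LOD to join two markers (default 10).
#' @return A list of character vectors of marker ids.
#' @export
cluster_markers <- function(matrix, min_lod = 10) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (nrow(matrix$calls) == 0L) return(list())
  pw <- .pairwise_linkage(matrix$calls)
  adj <- pw$lod >= min_lod & pw$rf < 0.5
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ids <- rownames(matrix$calls)
  mk <- matrix$markers
  phys <- order(mk$chrom, mk$pos)
  rank <- match(seq_along(ids), phys)
  groups <- split(seq_along(ids), comp)
  groups <- lapply(groups, function(ix) ids[ix[order(rank[ix])]])
  first <- vapply(groups, function(g_ids) min(rank[match(g_ids, ids)]), 0)
  unname(groups[order(first)])
}

# subset a genotype_matrix to given marker ids (in the given order)
subset_markers <- function(matrix, ids) {
  ix <- match(ids, rownames(matrix$calls))
  if (anyNA(ix)) stop("unknown marker id(s): ",
                      paste(ids[is.na(ix)], collapse = ", "))
  matrix$calls <- matrix$calls[ix, , drop = FALSE]
  matrix$markers <- matrix$markers[ix, , drop = FALSE]
  rownames(matrix$markers) <- NULL
  matrix$depth <- matrix$depth[ix, , drop = FALSE]
  matrix
}

# merge calls of the markers of one bin: per individual, the unique
# non-missing call if all agree, the majority call on conflict, NA on tie
# or all-missing
.merge_bin_calls <- function(calls) {
  if (nrow(calls) == 1L) return(calls[1L, ])
  n_ab <- colSums(calls == "AB", na.rm = TRUE)
  n_aa <- colSums(calls == "AA", na.rm = TRUE)
  out <- rep(NA_character_, ncol(calls))
  out[n_ab > n_aa] <- "AB"
  out[n_aa > n_ab] <- "AA"
  out[n_aa == 0 & n_ab == 0] <- NA_character_
  out
}

#' Bin markers within a provisional genetic distance
#'
#' Provisional cM positions are computed in physical order as cumulative
#' Kosambi-transformed adjacent two-point rfs; consecutive markers within
#' `bin_cm` of the first marker of the current bin collapse into one bin.
#' The bin genotype per individual is the shared call when all non-missing
#' member calls agree, the majority call on conflict, and missing on a tie
#' or when all members are missing — merging genotypes to minimize missing
#' data points.
#'
#' @param group_matrix A `genotype_matrix` restricted to one linkage group
#'   (markers carry physical coordinates).
#' @param bin_cm Bin width in cM (default 1).
#' @return A list: `matrix` (binned `genotype_matrix`, one row per bin,
#'   named/positioned by its first marker), `bin_map` (data.frame marker ->
#'   bin id), `provisional_cm` (per input marker).
#' @export
bin_markers <- function(group_matrix, bin_cm = 1) {
  stopifnot(inherits(group_matrix, "genotype_matrix"))
  mk <- group_matrix$markers
  m <- nrow(mk)
  if (m == 0L) stop("empty group")
  ord <- order(mk$chrom, mk$pos)
  gm <- subset_markers(group_matrix, rownames(group_matrix$calls)[ord])
  mk <- gm$markers
  cm <- numeric(m)
  if (m > 1L) {
    for (i in 2:m) {
      pl <- estimate_rf(gm$calls[i - 1L, ], gm$calls[i, ])
      step <- if (mk$chrom[i] != mk$chrom[i - 1L]) 1e6 else
        kosambi(min(pl$rf, .RF_CAP))
      cm[i] <- cm[i - 1L] + step
    }
  }
  bin_id <- integer(m)
  cur <- 1L
  start_cm <- cm[1L]
  bin_id[1L] <- cur
  if (m > 1L) {
    for (i in 2:m) {
      if (cm[i] - start_cm >= bin_cm) {
        cur <- cur + 1L
        start_cm <- cm[i]
      }
      bin_id[i] <- cur
    }
  }
  reps <- tapply(seq_len(m), bin_id, function(ix) ix[1L])
  calls <- do.call(rbind, lapply(split(seq_len(m), bin_id), function(ix) {
    .merge_bin_calls(gm$calls[ix, , drop = FALSE])
  }))
  rownames(calls) <- mk$id[reps]
  colnames(calls) <- colnames(gm$calls)
  binned <- structure(list(
    calls = calls,
    markers = data.frame(id = mk$id[reps], chrom = mk$chrom[reps],
                         pos = mk$pos[reps]),
    depth = gm$depth[reps, , drop = FALSE]),
    class = "genotype_matrix")
  list(matrix = binned,
       bin_map = data.frame(marker = mk$id, bin = mk$id[reps][bin_id],
                            provisional_cm = cm),
       provisional_cm = cm)
}

# total adjacent Kosambi length of an order (indices into rf matrix)
.order_length <- function(ord, dmat) {
  if (length(ord) < 2L) return(0)
  sum(dmat[cbind(ord[-length(ord)], ord[-1L])])
}

#' De novo marker ordering within a group
#'
#' Seriation heuristic: a greedy nearest-neighbour chain seeded at the pair
#' with maximal LOD and extended at both ends by the unplaced marker with the
#' smallest rf to an end, followed by 2-opt segment reversals and single-
#' marker reinsertion passes minimizing the total adjacent Kosambi length
#' until no move improves. Ties break deterministically by (chrom, pos).
#'
#' @param group_matrix A `genotype_matrix` restricted to one group.
#' @return Character vector: ordered marker ids (a permutation of the
#'   group).
#' @export
order_markers <- function(group_matrix) {
  stopifnot(inherits(group_matrix, "genotype_matrix"))
  ids <- rownames(group_matrix$calls)
  m <- length(ids)
  if (m <= 2L) return(ids)
  pw <- .pairwise_linkage(group_matrix$calls)
  dmat <- kosambi(pmin(pw$rf, .RF_CAP))
  diag(dmat) <- 0
  # deterministic seed pair: max LOD, ties by index
  lod <- pw$lod
  diag(lod) <- -Inf
  seed <- which(lod == max(lod), arr.ind = TRUE)
  seed <- seed[order(seed[, 1], seed[, 2]), , drop = FALSE][1, ]
  chain <- c(seed[[1]], seed[[2]])
  left <- setdiff(seq_len(m), chain)
  while (length(left)) {
    d_head <- dmat[chain[1L], left]
    d_tail <- dmat[chain[length(chain)], left]
    if (min(d_head) <= min(d_tail)) {
      pick <- left[which.min(d_head)]
      chain <- c(pick, chain)
    } else {
      pick <- left[which.min(d_tail)]
      chain <- c(chain, pick)
    }
    left <- setdiff(left, pick)
  }
  # local search: 2-opt reversals + single-marker reinsertion
  improved <- TRUE
  best <- .order_length(chain, dmat)
  while (improved) {
    improved <- FALSE
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        cand <- chain
        cand[i:j] <- rev(cand[i:j])
        len <- .order_length(cand, dmat)
        if (len < best - 1e-9) {
          chain <- cand
          best <- len
          improved <- TRUE
        }
      }
    }
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (j == i) next
        cand <- append(chain[-i], chain[i], after = j - 1L)
        len <- .order_length(cand, dmat)
        if (len < best - 1e-9) {
          chain <- cand
          best <- len
          improved <- TRUE
        }
      }
    }
  }
  # canonical direction: physical position of first <= last (tie-safe)
  mk <- group_matrix$markers
  rank <- order(mk$chrom, mk$pos)
  pos_rank <- match(seq_len(m), rank)
  if (pos_rank[chain[1L]] > pos_rank[chain[length(chain)]]) {
    chain <- rev(chain)
  }
  ids[chain]
}

# forward-backward E-step for one interval structure; calls: m x n matrix,
# rf: length m-1, e: error prob. Returns list(exp_rec = expected recombinant
# counts per interval, loglik).
.hmm_estep <- function(calls, rf, e) {
  m <- nrow(calls); n <- ncol(calls)
  # emission probs for state HOM(AA) and HET(AB)
  em_hom <- matrix(1, m, n); em_het <- matrix(1, m, n)
  is_aa <- calls == "AA"; is_ab <- calls == "AB"
  em_hom[which(is_aa)] <- 1 - e; em_het[which(is_aa)] <- e
  em_hom[which(is_ab)] <- e;     em_het[which(is_ab)] <- 1 - e
  f_hom <- matrix(0, m, n); f_het <- matrix(0, m, n)
  scale <- matrix(0, m, n)
  f_hom[1, ] <- 0.5 * em_hom[1, ]; f_het[1, ] <- 0.5 * em_het[1, ]
  s <- f_hom[1, ] + f_het[1, ]
  scale[1, ] <- s
  f_hom[1, ] <- f_hom[1, ] / s; f_het[1, ] <- f_het[1, ] / s
  for (i in 2:m) {
    r <- rf[i - 1L]
    ph <- (f_hom[i - 1L, ] * (1 - r) + f_het[i - 1L, ] * r) * em_hom[i, ]
    pt <- (f_hom[i - 1L, ] * r + f_het[i - 1L, ] * (1 - r)) * em_het[i, ]
    s <- ph + pt
    scale[i, ] <- s
    f_hom[i, ] <- ph / s; f_het[i, ] <- pt / s
  }
  b_hom <- matrix(1, m, n); b_het <- matrix(1, m, n)
  exp_rec <- numeric(m - 1L)
  for (i in (m - 1L):1L) {
    r <- rf[i]
    bh_next <- b_hom[i + 1L, ] * em_hom[i + 1L, ]
    bt_next <- b_het[i + 1L, ] * em_het[i + 1L, ]
    # posterior transition probabilities (per individual)
    den <- scale[i + 1L, ]
    p_hh <- f_hom[i, ] * (1 - r) * bh_next / den
    p_ht <- f_hom[i, ] * r * bt_next / den
    p_th <- f_het[i, ] * r * bh_next / den
    p_tt <- f_het[i, ] * (1 - r) * bt_next / den
    exp_rec[i] <- sum(p_ht + p_th)
    b_hom[i, ] <- (bh_next * (1 - r) + bt_next * r) / den
    b_het[i, ] <- (bh_next * r + bt_next * (1 - r)) / den
  }
  list(exp_rec = exp_rec, loglik = sum(log(scale)))
}

#' Estimate a genetic map for an ordered group
#'
#' Interval recombination fractions are re-estimated by EM over a two-state
#' hidden chain per individual (true states HOM/HET; adjacent-marker
#' transition probability = interval rf; the observed call equals the true
#' state with probability `1 - error_prob`, and missing calls are emitted
#' uninformatively). Interval rfs are converted to cM by the Kosambi function
#' and accumulated from 0. Initial rfs come from adjacent two-point
#' estimates.
#'
#' @param group_matrix A `genotype_matrix` whose row order is the map order
#'   (see [order_markers()]).
#' @param id Group label, e.g. `"2A"`.
#' @param error_prob Genotyping-error probability (default 0.01).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 100; non-convergence warns
#'   and returns the last iterate).
#' @return An object of class `linkage_group`: list with `id`, `map`
#'   (data.frame id/chrom/pos/cm), `rf` (per interval), `loglik`, `summary`
#'   (n_markers, length_cm, avg_spacing, max_spacing, avg_aa, avg_ab,
#'   ab_aa_ratio).
#' @export
estimate_map <- function(group_matrix, id = "LG", error_prob = 0.01,
                         tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(group_matrix, "genotype_matrix"))
  calls <- group_matrix$calls
  m <- nrow(calls)
  if (m == 0L) stop("empty group")
  if (m == 1L) {
    rf <- numeric(0)
    cm <- 0
    ll <- 0
  } else {
    rf <- vapply(seq_len(m - 1L), function(i) {
      min(estimate_rf(calls[i, ], calls[i + 1L, ])$rf, .RF_CAP)
    }, 0)
    if (error_prob > 0) {
      e <- error_prob
      ll_old <- -Inf
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        es <- .hmm_estep(calls, pmax(pmin(rf, .RF_CAP), 1e-8), e)
        rf <- pmin(es$exp_rec / ncol(calls), .RF_CAP)
        if (is.finite(ll_old) &&
            abs(es$loglik - ll_old) <= tol * (abs(ll_old) + 1e-3)) {
          converged <- TRUE
          ll_old <- es$loglik
          break
        }
        ll_old <- es$loglik
      }
      if (!converged) {
        warning("EM did not converge in ", max_iter, " iterations for ", id)
      }
      ll <- ll_old
    } else {
      ll <- NA_real_
    }
    cm <- c(0, cumsum(kosambi(pmin(rf, .RF_CAP))))
  }
  n_aa <- rowSums(calls == "AA", na.rm = TRUE)
  n_ab <- rowSums(calls == "AB", na.rm = TRUE)
  map <- data.frame(id = rownames(calls),
                    chrom = group_matrix$markers$chrom,
                    pos = group_matrix$markers$pos,
                    cm = cm)
  spacing <- diff(cm)
  summary <- list(
    n_markers = m,
    length_cm = cm[m],
    avg_spacing = if (m > 1L) cm[m] / (m - 1L) else NA_real_,
    max_spacing = if (m > 1L) max(spacing) else NA_real_,
    avg_aa = mean(n_aa),
    avg_ab = mean(n_ab),
    ab_aa_ratio = mean(n_ab) / mean(n_aa)
  )
  structure(list(id = id, map = map, rf = rf, loglik = ll,
                 summary = summary, calls = calls),
            class = "linkage_group")
}

#' @export
print.linkage_group <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<linkage_group %s> %d markers, %.1f cM, AB/AA ratio %.2f\n",
    x$id, s$n_markers, s$length_cm, s$ab_aa_ratio))
  invisible(x)
}

#' Repulsion-phase merge test between two groups
#'
#' To test whether a donor-depleted (1:5-type) group is the repulsion-phase
#' complement of a donor-enriched (5:1-type) group on the same base
#' chromosome, the calls of the first group are inverted (AA <-> AB) and all
#' cross-group two-point LODs recomputed. Disomic (repulsion) inheritance
#' would make the inverted group cluster with the second.
#'
#' @param groupA,groupB `genotype_matrix` objects for the two groups over the
#'   same individuals (A is the group to invert).
#' @param min_lod Clustering threshold used for the coalescence verdict
#'   (default 10).
#' @return List: `max_lod`, `mean_lod`, `min_rf` over cross pairs, and
#'   `coalesces` — whether single-linkage clustering at `min_lod` would join
#'   the groups.
#' @export
merge_repulsion <- function(groupA, groupB, min_lod = 10) {
  stopifnot(inherits(groupA, "genotype_matrix"),
            inherits(groupB, "genotype_matrix"))
  if (nrow(groupA$calls) == 0L || nrow(groupB$calls) == 0L) {
    stop("empty group")
  }
  inv <- groupA$calls
  inv[] <- ifelse(is.na(groupA$calls), NA_character_,
                  ifelse(groupA$calls == "AA", "AB", "AA"))
  nA <- nrow(inv); nB <- nrow(groupB$calls)
  comb <- rbind(inv, groupB$calls)
  pw <- .pairwise_linkage(comb)
  cross_lod <- pw$lod[seq_len(nA), nA + seq_len(nB), drop = FALSE]
  cross_rf <- pw$rf[seq_len(nA), nA + seq_len(nB), drop = FALSE]
  link <- cross_lod >= min_lod & cross_rf < 0.5
  list(max_lod = max(cross_lod), mean_lod = mean(cross_lod),
       min_rf = min(cross_rf), coalesces = any(link))
}

#' Write per-group map files and a summary table
#'
#' One tab-separated map file per linkage group (group id, marker id, chrom,
#' pos, cM) plus a summary CSV with one row per group (LG, marker count,
#' length, average and maximum spacing, average AA and AB counts, AB/AA
#' ratio).
#'
#' @param groups List of `linkage_group` objects.
#' @param dir Output directory (created if needed).
#' @return The summary data.frame, invisibly.
#' @export
write_map_files <- function(groups, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in groups) {
    df <- cbind(data.frame(group = g$id), g$map)
    utils::write.table(df, file.path(dir, paste0("map_", g$id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary <- linkage_summary_table(groups)
  utils::write.csv(summary, file.path(dir, "map_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(summary)
}

#' Summary table across linkage groups
#'
#' @param groups List of `linkage_group` objects.
#' @return Data.frame with columns LG, n_markers, length_cm, avg_spacing_cm,
#'   max_spacing_cm, avg_AA, avg_AB, AB_AA_ratio.
#' @export
linkage_summary_table <- function(groups) {
  do.call(rbind, lapply(groups, function(g) {
    s <- g$summary
    data.frame(LG = g$id, n_markers = s$n_markers,
               length_cm = round(s$length_cm, 1),
               avg_spacing_cm = round(s$avg_spacing, 2),
               max_spacing_cm = round(s$max_spacing, 2),
               avg_AA = round(s$avg_aa, 2), avg_AB = round(s$avg_ab, 2),
               AB_AA_ratio = round(s$ab_aa_ratio, 2))
  }))
}
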