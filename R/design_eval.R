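#' Chromosome-arm table for QTL placement
#'
#' The major Drosophila chromosome arms (X, 2L, 2R, 3L, 3R) as cM
#' intervals on the simulated chromosomes; metacentric chromosomes are
#' split at their genetic midpoint.
#'
#' @param chroms chromosome table as from [drosophila_chroms()].
#' @return data frame with columns `arm`, `chrom`, `cm_lo`, `cm_hi`.
#' @export
drosophila_arms <- function(chroms = drosophila_chroms()) {
  rows <- list()
  for (i in seq_len(nrow(chroms))) {
    lab <- chroms$chrom[i]
    L <- chroms$cm[i]
    if (chroms$is_x[i]) {
      rows[[length(rows) + 1]] <- data.frame(arm = lab, chrom = lab,
                                             cm_lo = 0, cm_hi = L)
    } else {
      rows[[length(rows) + 1]] <- data.frame(arm = paste0(lab, "L"),
                                             chrom = lab, cm_lo = 0,
                                             cm_hi = L / 2)
      rows[[length(rows) + 1]] <- data.frame(arm = paste0(lab, "R"),
                                             chrom = lab, cm_lo = L / 2,
                                             cm_hi = L)
    }
  }
  do.call(rbind, rows)
}

#' Place uniformly spaced QTL with analysis zones
#'
#' With `n` QTL on an arm represented as a 0-to-1 interval, positions are
#' `(2i - 1)/(2n)` and analysis zones `[(i-1)/n, i/n]`, so the zones
#' partition the arm and each QTL sits at its zone's centre.
#'
#' @param n QTL per arm.
#' @param arms arm table as from [drosophila_arms()].
#' @return data frame with one row per QTL: `arm`, `chrom`, `cm` (QTL
#'   position), `zone_lo`, `zone_hi` (cM bounds), `rel_pos`.
#' @export
place_uniform_qtl <- function(n, arms = drosophila_arms()) {
  stopifnot(n >= 1)
  rel <- (2 * seq_len(n) - 1) / (2 * n)
  zlo <- (seq_len(n) - 1) / n
  zhi <- seq_len(n) / n
  out <- list()
  for (i in seq_len(nrow(arms))) {
    span <- arms$cm_hi[i] - arms$cm_lo[i]
    out[[i]] <- data.frame(
      arm = arms$arm[i], chrom = arms$chrom[i],
      cm = arms$cm_lo[i] + rel * span,
      zone_lo = arms$cm_lo[i] + zlo * span,
      zone_hi = arms$cm_lo[i] + zhi * span,
      rel_pos = rel, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Distance from a zone's statistic maximum to the true QTL
#'
#' Finds the window with the maximal statistic among the windows whose cM
#' midpoint lies in the zone (first window on ties) and returns its
#' genetic distance to the true position, plus whether it falls within
#' 0.5 cM (a "hit").
#'
#' @param profile per-window statistic (a_d or a_p), genome order.
#' @param gmap a [genome_map()].
#' @param chrom chromosome label of the zone.
#' @param zone_lo,zone_hi zone bounds in cM.
#' @param true_cm true QTL position in cM.
#' @param hit_cm hit radius (default 0.5 cM).
#' @return list with `distance_cm`, `hit`, `peak_cm`, `window`.
#' @export
zone_peak_distance <- function(profile, gmap, chrom, zone_lo, zone_hi,
                               true_cm, hit_cm = 0.5) {
  mp <- window_midpoints(gmap)
  ci <- match(as.character(chrom), gmap$chrom$chrom)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  sel <- which(mp$chrom_index == ci & mp$mid >= zone_lo & mp$mid <= zone_hi)
  if (length(sel) == 0) stop("zone contains no windows")
  j <- sel[which.max(profile[sel])]
  d <- abs(mp$mid[j] - true_cm)
  list(distance_cm = d, hit = d <= hit_cm, peak_cm = mp$mid[j], window = j)
}

#' Evaluate one experimental-design scenario
#'
#' Simulates replicate mapping experiments under a BSA or IM design with
#' `n_qtl` equal-effect QTL per chromosome arm (exploratory noise model:
#' residual SD equal to the design-mean trait value) and scores, per QTL,
#' the median cM distance between the statistic maximum in its analysis
#' zone and the true position, plus the fraction of replicates within
#' 0.5 cM. Multi-cross designs sum the statistic across crosses before
#' scoring.
#'
#' @param config an [experiment_config()].
#' @param gmap a [genome_map()].
#' @param n_qtl QTL per chromosome arm.
#' @param n_reps simulation replicates.
#' @param arms arm table (defaults to [drosophila_arms()] restricted to
#'   the map's chromosomes).
#' @return list with `per_qtl` (data frame: arm, cm, median_distance_cm,
#'   hit_rate) and `overall` (pooled medians), plus the raw `distances`
#'   matrix (replicates x QTL).
#' @export
run_scenario <- function(config, gmap, n_qtl = 1, n_reps = 100,
                         arms = NULL) {
  if (is.null(arms)) {
    arms <- drosophila_arms()
    arms <- arms[arms$chrom %in% gmap$chrom$chrom, , drop = FALSE]
  }
  qtl_pos <- place_uniform_qtl(n_qtl, arms)
  qtl <- qtl_model(chrom = qtl_pos$chrom, cm = qtl_pos$cm,
                   f = rep(1, nrow(qtl_pos)), noise = "exploratory")
  nq <- nrow(qtl_pos)
  dist <- matrix(NA_real_, n_reps, nq)
  hit <- matrix(NA, n_reps, nq)
  for (r in seq_len(n_reps)) {
    prof <- if (config$mode == "bsa")
      run_bsa_experiment(gmap, config, qtl)$ad
    else
      run_im_experiment(gmap, config, qtl)$ap
    for (i in seq_len(nq)) {
      z <- zone_peak_distance(prof, gmap, qtl_pos$chrom[i],
                              qtl_pos$zone_lo[i], qtl_pos$zone_hi[i],
                              qtl_pos$cm[i])
      dist[r, i] <- z$distance_cm
      hit[r, i] <- z$hit
    }
  }
  per_qtl <- data.frame(
    arm = qtl_pos$arm, chrom = qtl_pos$chrom, cm = qtl_pos$cm,
    median_distance_cm = apply(dist, 2, median),
    hit_rate = colMeans(hit), stringsAsFactors = FALSE)
  list(per_qtl = per_qtl,
       overall = list(median_distance_cm = median(dist),
                      hit_rate = mean(hit)),
       distances = dist)
}
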