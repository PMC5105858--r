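#' Null distribution of primary peak heights
#'
#' Runs no-QTL BSA simulations matched to the empirical experiment (same
#' map, population size, generations, selection proportion and depth);
#' all phenotypic variance is random with respect to genotype. Every
#' simulated profile passes through the identical smoothing and
#' peak-calling path as the data, and all primary-peak heights exceeding
#' `a_dt` are pooled.
#'
#' @param gmap a [genome_map()].
#' @param config an [experiment_config()] (`mode = "bsa"`).
#' @param thr a [thresholds()] object.
#' @param n_reps number of null replicates.
#' @return list of class `null_peak_distribution` with `heights` (pooled
#'   peak heights), `per_rep` (peak count per replicate), `n_reps`.
#' @export
null_stage <- function(gmap, config, thr = thresholds(), n_reps = 500) {
  null_qtl <- qtl_model(noise = "sibsam")
  ci <- window_midpoints(gmap)$chrom_index
  heights <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    res <- run_bsa_experiment(gmap, config, null_qtl)
    sp <- smooth_profile(res$ad, ci, thr$m)
    prim <- find_primary_peaks(sp, ci, thr)
    heights[[r]] <- prim$height
  }
  structure(list(heights = unlist(heights),
                 per_rep = lengths(heights),
                 n_reps = n_reps, thresholds = thr),
            class = "null_peak_distribution")
}

#' Primary peak P-values from null enrichment
#'
#' For a peak of height `h`, the enrichment `e` is the ratio of the
#' per-scan frequency of peaks of at least that height in the observed
#' scan (the count of such peaks among the empirical primaries) to the
#' mean per-replicate count in the null simulations. With enrichment
#' (`e > 1`) the estimated false-positive probability is `P = 1/e`;
#' otherwise `P = 1`. When no null peak reaches `h`, the finite-replicate
#' resolution floor `1/(n_reps * count_real)` is reported and flagged.
#'
#' @param primary data frame from [find_primary_peaks()] (one observed
#'   genome scan).
#' @param null a `null_peak_distribution` from [null_stage()].
#' @return the `primary` data frame with added columns `p_value` and
#'   `p_floor` (TRUE where the null ECDF ran out of resolution).
#' @export
primary_pvalues <- function(primary, null) {
  n <- nrow(primary)
  p <- numeric(n)
  floor_flag <- logical(n)
  for (i in seq_len(n)) {
    h <- primary$height[i]
    count_real <- sum(primary$height >= h)
    count_null <- sum(null$heights >= h) / null$n_reps
    if (count_null == 0) {
      p[i] <- 1 / (null$n_reps * count_real)
      floor_flag[i] <- TRUE
    } else {
      e <- count_real / count_null
      p[i] <- if (e > 1) 1 / e else 1
    }
  }
  primary$p_value <- p
  primary$p_floor <- floor_flag
  primary
}

#' Apportion a cluster strength among member QTL
#'
#' Draws member shares from a symmetric Dirichlet(1, ..., 1) (uniform on
#' the simplex, the maximally uninformative split) and scales them so the
#' member strengths sum exactly to the cluster strength.
#'
#' @param S total cluster strength.
#' @param k number of member QTL.
#' @return numeric vector of `k` member strengths summing to `S`.
#' @export
apportion_strength <- function(S, k) {
  w <- rgamma(k, shape = 1)
  S * w / sum(w)
}

# Summarise one simulated smoothed profile: global maximum, its window,
# and the maximum adjusted secondary deviation within that maximum's
# positive run.
profile_summary <- function(sp, chrom_index, thr) {
  w <- which.max(sp)
  h <- sp[w]
  max_v <- 0
  if (h > 0) {
    sel <- which(chrom_index == chrom_index[w])
    x <- sp[sel] > 0
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    local_w <- match(w, sel)
    k <- which(starts <= local_w & ends >= local_w)
    prim <- data.frame(chrom = chrom_index[w], window = w, height = h,
                       run_start = sel[starts[k]], run_end = sel[ends[k]])
    sec <- find_secondary_peaks(sp, prim, thr)
    if (nrow(sec) > 0) max_v <- max(sec$v)
  }
  list(max_ad = h, window = w, max_v = max_v)
}

#' Single-QTL prior simulations for rejection sampling
#'
#' Per replicate, one QTL strength is drawn from the uniform prior on
#' (0, 1) and one mapping population is simulated; the QTL (effect
#' `f = s/(1-s)`, residual noise 0.5 x N(0,1)) is then evaluated
#' separately at each requested genomic position, reusing the simulated
#' ancestries across positions. For each (replicate, position) the
#' maximum smoothed a_d, its window, and the maximum adjusted secondary
#' deviation are recorded.
#'
#' @param gmap a [genome_map()].
#' @param config an [experiment_config()].
#' @param positions data frame with columns `chrom` (label) and `cm`, one
#'   row per empirical primary-peak position.
#' @param thr a [thresholds()] object.
#' @param n_reps number of prior replicates.
#' @return data frame of class `single_qtl_records`: `rep`, `pos_id`,
#'   `s`, `max_ad`, `peak_window`, `peak_cm`, `max_v`.
#' @export
single_qtl_stage <- function(gmap, config, positions, thr = thresholds(),
                             n_reps = 1000) {
  stopifnot(nrow(positions) >= 1)
  mp <- window_midpoints(gmap)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s <- runif(1)
    f <- strength_to_effect(s)
    qtl_list <- lapply(seq_len(nrow(positions)), function(i)
      qtl_model(chrom = positions$chrom[i], cm = positions$cm[i], f = f,
                noise = "sibsam"))
    res <- run_bsa_population(gmap, config, qtl_list)
    rows <- lapply(seq_along(res), function(i) {
      sp <- smooth_profile(res[[i]]$ad, mp$chrom_index, thr$m)
      ps <- profile_summary(sp, mp$chrom_index, thr)
      data.frame(rep = r, pos_id = i, s = s, max_ad = ps$max_ad,
                 peak_window = ps$window, peak_cm = mp$mid[ps$window],
                 max_v = ps$max_v)
    })
    out[[r]] <- do.call(rbind, rows)
  }
  rec <- do.call(rbind, out)
  class(rec) <- c("single_qtl_records", class(rec))
  rec
}

#' Rejection-sampling posterior for one primary peak
#'
#' Accepts prior replicates whose maximum smoothed a_d falls within
#' `tolerance` of the empirical peak height. Accepted strengths give the
#' posterior point estimate (median) and credible interval (0.05 and 0.95
#' quantiles). The genomic confidence interval takes the same far
#' quantiles of the accepted peak-location offsets from the simulated QTL
#' position, re-centred on the empirical peak window - assuming the
#' simulated distances from true QTL to observed maximum transfer to the
#' empirical distances from observed maximum to true QTL. If fewer than
#' `min_accept` replicates are accepted, the tolerance is doubled once
#' with a warning; if none are accepted even then, the peak is flagged
#' and the CIs are `NA`.
#'
#' @param records `single_qtl_records` rows for this peak's position.
#' @param empirical_height observed smoothed peak height.
#' @param qtl_cm simulated QTL position (cM) for these records.
#' @param empirical_cm observed peak window position (cM).
#' @param tolerance acceptance half-width on peak height (default 0.025).
#' @param min_accept minimum accepted replicates before widening.
#' @param strength_q,genomic_q posterior quantiles reported.
#' @return list: `s_hat`, `s_ci`, `cm_ci`, `n_accept`, `tolerance_used`,
#'   `widened`, `failed`, `accepted` (the accepted record rows).
#' @export
rejection_posterior <- function(records, empirical_height, qtl_cm,
                                empirical_cm, tolerance = 0.025,
                                min_accept = 200,
                                strength_q = c(0.05, 0.5, 0.95),
                                genomic_q = c(0.05, 0.95)) {
  tol <- tolerance
  acc <- records[abs(records$max_ad - empirical_height) <= tol, , drop = FALSE]
  widened <- FALSE
  if (nrow(acc) < min_accept) {
    tol <- 2 * tolerance
    acc <- records[abs(records$max_ad - empirical_height) <= tol, , drop = FALSE]
    widened <- TRUE
    warning(sprintf(
      "only %d accepted replicates at tolerance %.3g; widened to %.3g (%d accepted)",
      sum(abs(records$max_ad - empirical_height) <= tolerance),
      tolerance, tol, nrow(acc)))
  }
  if (nrow(acc) == 0) {
    return(list(s_hat = NA_real_, s_ci = c(NA_real_, NA_real_),
                cm_ci = c(NA_real_, NA_real_), n_accept = 0L,
                tolerance_used = tol, widened = widened, failed = TRUE,
                accepted = acc))
  }
  sq <- quantile(acc$s, strength_q, names = FALSE, type = 7)
  offsets <- acc$peak_cm - qtl_cm
  cm_ci <- empirical_cm + quantile(offsets, genomic_q, names = FALSE, type = 7)
  list(s_hat = sq[2], s_ci = c(sq[1], sq[3]), cm_ci = cm_ci,
       n_accept = nrow(acc), tolerance_used = tol, widened = widened,
       failed = FALSE, accepted = acc)
}

#' Secondary peak P-values from accepted single-QTL replicates
#'
#' Conditioning on replicates whose primary height matched the data
#' removes the unknown primary strength as a nuisance parameter; the
#' P-value of an observed secondary deviation is then the proportion of
#' accepted replicates whose maximum secondary deviation exceeds it.
#'
#' @param v_obs observed (adjusted) secondary deviations.
#' @param accepted accepted rows of `single_qtl_records` for the parent
#'   primary peak.
#' @return data frame with `v`, `p_value` and `p_floor` (the ECDF
#'   resolution `1/n_accept`; reported P-values of 0 mean "below floor").
#' @export
secondary_pvalues <- function(v_obs, accepted) {
  if (length(v_obs) == 0)
    return(data.frame(v = numeric(), p_value = numeric(),
                      p_floor = numeric()))
  if (nrow(accepted) == 0)
    return(data.frame(v = v_obs, p_value = NA_real_, p_floor = NA_real_))
  p <- vapply(v_obs, function(v) mean(accepted$max_v > v), numeric(1))
  data.frame(v = v_obs, p_value = p, p_floor = 1 / nrow(accepted))
}

#' Cluster simulations for a primary peak with significant secondaries
#'
#' Simulates all member QTL of a linked cluster jointly, each fixed at
#' its empirical peak window. Per replicate a cluster strength is drawn
#' uniformly on (0, 1) and apportioned among the members by a symmetric
#' Dirichlet(1, ..., 1) draw (uniform on the simplex); member effects are
#' `f_i = s_i/(1-s_i)`. Each member owns an analysis zone bounded by the
#' empirical valleys (profile minima) between neighbouring member peaks
#' and by the chromosome ends beyond the outer members. A replicate is
#' accepted only when every zone's local maximum lies within `tolerance`
#' of the corresponding empirical height. Member posteriors (strength
#' median, 0.05/0.95 CI, genomic CI from zone-peak locations) replace the
#' single-QTL estimates.
#'
#' @param gmap a [genome_map()].
#' @param config an [experiment_config()].
#' @param members data frame with one row per cluster member (ordered or
#'   not): `window` (genome-order index), `height` (empirical smoothed
#'   height), `cm`, `chrom` (label).
#' @param sp_emp empirical smoothed profile (genome order), used for the
#'   valley boundaries.
#' @param thr a [thresholds()] object.
#' @param n_reps number of cluster replicates.
#' @param tolerance per-zone acceptance half-width (default 0.05).
#' @param min_accept minimum accepted replicates before widening once.
#' @return list: `members` (input plus posterior columns `s_hat`, `s_lo`,
#'   `s_hi`, `cm_lo`, `cm_hi`), `n_accept`, `tolerance_used`, `widened`,
#'   `failed`, `zones`, and the per-replicate `draws` (member strengths)
#'   and `zone_max` matrices.
#' @export
cluster_stage <- function(gmap, config, members, sp_emp, thr = thresholds(),
                          n_reps = 1000, tolerance = 0.05,
                          min_accept = 200) {
  ord <- order(members$window)
  members <- members[ord, , drop = FALSE]
  k <- nrow(members)
  stopifnot(k >= 2, length(unique(members$chrom)) == 1)
  mp <- window_midpoints(gmap)
  ci <- match(members$chrom[1], gmap$chrom$chrom)
  chrom_win <- which(mp$chrom_index == ci)
  # zone boundaries: valley (minimum) between adjacent member windows;
  # outer zones end at the chromosome ends
  cuts <- integer(k - 1)
  for (i in seq_len(k - 1)) {
    a <- members$window[i]; b <- members$window[i + 1]
    cuts[i] <- a + which.min(sp_emp[a:b]) - 1L
  }
  zone_lo <- c(chrom_win[1], cuts)
  zone_hi <- c(cuts, chrom_win[length(chrom_win)])

  draws <- matrix(NA_real_, n_reps, k)
  zone_max <- matrix(NA_real_, n_reps, k)
  zone_argmax_cm <- matrix(NA_real_, n_reps, k)
  for (r in seq_len(n_reps)) {
    S <- runif(1)
    s_i <- apportion_strength(S, k)
    qtl <- qtl_model(chrom = members$chrom, cm = members$cm,
                     f = strength_to_effect(s_i), noise = "sibsam")
    res <- run_bsa_population(gmap, config, list(qtl))[[1]]
    sp <- smooth_profile(res$ad, mp$chrom_index, thr$m)
    for (i in seq_len(k)) {
      seg <- zone_lo[i]:zone_hi[i]
      j <- which.max(sp[seg])
      zone_max[r, i] <- sp[seg[j]]
      zone_argmax_cm[r, i] <- mp$mid[seg[j]]
    }
    draws[r, ] <- s_i
  }

  accept_at <- function(tol) {
    ok <- rep(TRUE, n_reps)
    for (i in seq_len(k))
      ok <- ok & abs(zone_max[, i] - members$height[i]) <= tol
    ok
  }
  tol <- tolerance
  ok <- accept_at(tol)
  widened <- FALSE
  if (sum(ok) < min_accept) {
    tol <- 2 * tolerance
    ok2 <- accept_at(tol)
    warning(sprintf(
      "cluster acceptance %d below %d at tolerance %.3g; widened to %.3g (%d accepted)",
      sum(ok), min_accept, tolerance, tol, sum(ok2)))
    ok <- ok2
    widened <- TRUE
  }
  failed <- sum(ok) == 0
  for (col in c("s_hat", "s_lo", "s_hi", "cm_lo", "cm_hi"))
    members[[col]] <- NA_real_
  if (!failed) {
    for (i in seq_len(k)) {
      sq <- quantile(draws[ok, i], c(0.05, 0.5, 0.95), names = FALSE)
      members$s_hat[i] <- sq[2]
      members$s_lo[i] <- sq[1]
      members$s_hi[i] <- sq[3]
      offs <- zone_argmax_cm[ok, i] - members$cm[i]
      cmq <- members$cm[i] + quantile(offs, c(0.05, 0.95), names = FALSE)
      members$cm_lo[i] <- cmq[1]
      members$cm_hi[i] <- cmq[2]
    }
  }
  list(members = members, n_accept = sum(ok), tolerance_used = tol,
       widened = widened, failed = failed,
       zones = data.frame(lo = zone_lo, hi = zone_hi),
       draws = draws, zone_max = zone_max)
}

#' Run the full SIBSAM inference pipeline
#'
#' Given an observed ancestry-difference profile and the matching
#' experiment configuration: (1) smooth and call primary/secondary peaks;
#' (2) assign primary P-values against no-QTL null simulations; (3) for
#' each significant primary, estimate strength and genomic confidence
#' intervals by rejection sampling against single-QTL simulations, and
#' P-values for its secondary peaks; (4) for primaries with significant
#' secondaries, refine all member estimates with linked-cluster
#' simulations.
#'
#' @param ad observed per-window ancestry differences (genome order).
#' @param gmap a [genome_map()].
#' @param config an [experiment_config()] matching the experiment.
#' @param thr a [thresholds()] object.
#' @param n_null,n_single,n_cluster replicate counts for the three
#'   simulation stages.
#' @param alpha significance threshold for primary and secondary peaks.
#' @param tol_single,tol_cluster rejection tolerances.
#' @param min_accept minimum accepted replicates before widening.
#' @param null optional pre-computed [null_stage()] result to reuse.
#' @param single_records optional pre-computed [single_qtl_stage()]
#'   records (positions must match the significant primaries in order).
#' @return list of class `sibsam_result`: `peaks` (the peak set),
#'   `primary` (with P-values), `report` (final per-QTL table, see
#'   [write_report()]), `null`, and per-peak `posterior` details.
#' @export
sibsam_run <- function(ad, gmap, config, thr = thresholds(),
                       n_null = 500, n_single = 1000, n_cluster = 1000,
                       alpha = 0.05, tol_single = 0.025, tol_cluster = 0.05,
                       min_accept = 200, null = NULL,
                       single_records = NULL) {
  mp <- window_midpoints(gmap)
  pk <- find_peaks(ad, gmap, thr)
  if (is.null(null)) null <- null_stage(gmap, config, thr, n_null)
  prim <- primary_pvalues(pk$primary, null)
  sig <- prim[prim$p_value < alpha, , drop = FALSE]

  report <- NULL
  posteriors <- list()
  if (nrow(sig) > 0) {
    positions <- data.frame(
      chrom = gmap$chrom$chrom[sig$chrom],
      cm = mp$mid[sig$window],
      stringsAsFactors = FALSE)
    if (is.null(single_records))
      single_records <- single_qtl_stage(gmap, config, positions, thr,
                                         n_single)
    for (i in seq_len(nrow(sig))) {
      rec <- single_records[single_records$pos_id == i, , drop = FALSE]
      post <- rejection_posterior(rec, sig$height[i], positions$cm[i],
                                  positions$cm[i], tol_single, min_accept)
      sec <- pk$secondary[[as.character(sig$peak_id[i])]]
      sec_p <- secondary_pvalues(sec$v, post$accepted)
      sec$p_value <- sec_p$p_value
      sig_sec <- sec[!is.na(sec$p_value) & sec$p_value < alpha &
                       sec$v > thr$v_t, , drop = FALSE]
      cl <- NULL
      if (nrow(sig_sec) > 0) {
        members <- data.frame(
          window = c(sig$window[i], sig_sec$window),
          height = c(sig$height[i], sig_sec$height),
          cm = mp$mid[c(sig$window[i], sig_sec$window)],
          chrom = gmap$chrom$chrom[sig$chrom[i]],
          kind = c("primary", rep("secondary", nrow(sig_sec))),
          p_value = c(sig$p_value[i], sig_sec$p_value),
          stringsAsFactors = FALSE)
        cl <- cluster_stage(gmap, config, members, pk$smoothed, thr,
                            n_cluster, tol_cluster, min_accept)
        rows <- cl$members
        rows$parent_id <- sig$peak_id[i]
        report <- rbind(report, rows)
      } else {
        rows <- data.frame(
          window = sig$window[i], height = sig$height[i],
          cm = positions$cm[i],
          chrom = gmap$chrom$chrom[sig$chrom[i]], kind = "primary",
          p_value = sig$p_value[i],
          s_hat = post$s_hat, s_lo = post$s_ci[1], s_hi = post$s_ci[2],
          cm_lo = post$cm_ci[1], cm_hi = post$cm_ci[2],
          parent_id = sig$peak_id[i], stringsAsFactors = FALSE)
        report <- rbind(report, rows)
      }
      posteriors[[i]] <- list(single = post, secondary = sec, cluster = cl)
    }
  }
  if (!is.null(report)) {
    # attach physical coordinates of peak windows
    report$phys_start <- gmap$windows$phys_start[report$window] + 1L
    report$phys_end <- gmap$windows$phys_end[report$window]
  }
  structure(list(peaks = pk, primary = prim, report = report,
                 null = null, posterior = posteriors,
                 alpha = alpha),
            class = "sibsam_result")
}

#' Write the final QTL report
#'
#' One TSV row per significant primary or secondary peak: P-value, peak
#' window genomic coordinates, genomic confidence interval, and the
#' strength point estimate with its confidence interval. With no
#' significant peaks a header-only file is written.
#'
#' @param result a `sibsam_result` from [sibsam_run()], or the `report`
#'   data frame itself.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  rep_df <- if (inherits(result, "sibsam_result")) result$report else result
  cols <- c("parent_id", "kind", "chrom", "window", "phys_start",
            "phys_end", "cm", "height", "p_value", "cm_lo", "cm_hi",
            "s_hat", "s_lo", "s_hi")
  if (is.null(rep_df) || nrow(rep_df) == 0) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                    cols))
    write.table(empty, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  for (cc in setdiff(cols, names(rep_df))) rep_df[[cc]] <- NA
  write.table(rep_df[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.sibsam_result <- function(x, ...) {
  cat("SIBSAM result:", nrow(x$primary), "primary peak(s) called,",
      if (is.null(x$report)) 0 else nrow(x$report),
      "significant QTL reported\n")
  if (!is.null(x$report)) {
    df <- x$report
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %s chrom %s window %d: P=%.3g s=%.2f (%.2f-%.2f)\n",
                  df$kind[i], df$chrom[i], df$window[i], df$p_value[i],
                  df$s_hat[i], df$s_lo[i], df$s_hi[i]))
  }
  invisible(x)
}
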