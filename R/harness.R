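#' Focal test scenario configuration
#'
#' The reference BSA design for pipeline testing: 1200 individuals
#' interbreeding for 16 generations, 600 females phenotyped in the final
#' generation, 10% phenotypic tails selected, and 1000 informative reads
#' per window per pool. The `scale` multiplier scales population size,
#' phenotyped count and depth jointly (a scale-4 experiment phenotypes
#' 2400 individuals at depth 4000).
#'
#' @param scale experiment scale multiplier (1, 2, 4, 8, 16, ...).
#' @return an [experiment_config()].
#' @export
focal_scenario <- function(scale = 1) {
  experiment_config(mode = "bsa", N = 1200 * scale, G = 16, q = 0.10,
                    depth = 1000 * scale, n_pheno = 600 * scale,
                    females_only = TRUE)
}

#' Canonical test-QTL positions
#'
#' Fixed genomic positions used by the performance harness: an autosomal
#' position in the middle of arm 3R and an X-linked position, mirroring
#' the placement of classic pigmentation loci on those arms.
#'
#' @return data frame with columns `label`, `chrom`, `cm`.
#' @export
test_positions <- function() {
  data.frame(label = c("arm3R", "chrX"),
             chrom = c("3", "X"),
             cm = c(82.5, 30),
             stringsAsFactors = FALSE)
}

#' Define a performance-test scenario
#'
#' @param s true QTL strength(s); each is converted to a per-allele
#'   effect via [strength_to_effect()].
#' @param chrom,cm per-QTL positions (recycled against `s`).
#' @param scale experiment scale multiplier (see [focal_scenario()]).
#' @param n_reps number of test replicates.
#' @param noise_sd residual noise SD (default 0.5, the inference-stage
#'   convention; set 0 when the full variance comes from the QTL set).
#' @return list of class `test_scenario`.
#' @export
test_scenario <- function(s, chrom = "3", cm = 82.5, scale = 1,
                          n_reps = 100, noise_sd = 0.5) {
  k <- length(s)
  structure(list(s = s, chrom = rep_len(chrom, k), cm = rep_len(cm, k),
                 scale = scale, n_reps = n_reps, noise_sd = noise_sd,
                 config = focal_scenario(scale)),
            class = "test_scenario")
}

#' Generate test replicates with known ground truth
#'
#' Simulates `n_reps` BSA experiments under a [test_scenario()] and
#' returns the raw ancestry-difference profiles together with the truth
#' record. Optionally writes each profile as a window table plus a truth
#' TSV for external runs.
#'
#' @param ts a [test_scenario()].
#' @param gmap a [genome_map()].
#' @param dir optional directory to write `profile_<r>.tsv` files and
#'   `truth.tsv`.
#' @return list with `ad` (windows x replicates matrix), `truth` (data
#'   frame: `s`, `chrom`, `cm`, `f`), and `config`.
#' @export
generate_test_replicates <- function(ts, gmap, dir = NULL) {
  qtl <- qtl_model(chrom = ts$chrom, cm = ts$cm,
                   f = strength_to_effect(ts$s), noise_sd = ts$noise_sd)
  W <- nrow(gmap$windows)
  ad <- matrix(NA_real_, W, ts$n_reps)
  for (r in seq_len(ts$n_reps))
    ad[, r] <- run_bsa_experiment(gmap, ts$config, qtl)$ad
  truth <- data.frame(s = ts$s, chrom = ts$chrom, cm = ts$cm,
                      f = strength_to_effect(ts$s),
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (r in seq_len(ts$n_reps))
      write_window_table(gmap, file.path(dir, sprintf("profile_%d.tsv", r)),
                         ad = ad[, r],
                         depth_high = rep(ts$config$depth, W),
                         depth_low = rep(ts$config$depth, W))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(ad = ad, truth = truth, config = ts$config)
}

#' Smooth one profile and return its significant primary peaks
#'
#' Convenience wrapper chaining [smooth_profile()], [find_primary_peaks()]
#' and [primary_pvalues()].
#'
#' @param ad raw per-window ancestry differences.
#' @param gmap a [genome_map()].
#' @param null a [null_stage()] result.
#' @param thr a [thresholds()] object.
#' @param alpha significance level.
#' @return list with `sp` (smoothed profile), `primary` (all primaries
#'   with P-values) and `sig` (the significant subset).
#' @export
sig_primaries <- function(ad, gmap, null, thr = thresholds(),
                          alpha = 0.05) {
  ci <- window_midpoints(gmap)$chrom_index
  sp <- smooth_profile(ad, ci, thr$m)
  prim <- primary_pvalues(find_primary_peaks(sp, ci, thr), null)
  list(sp = sp, primary = prim,
       sig = prim[prim$p_value < alpha, , drop = FALSE])
}

#' Evaluate pipeline performance on single-QTL test replicates
#'
#' For each replicate: declare detection when a significant primary peak
#' (null-comparison P below `alpha`) falls inside the truth zone; for
#' detected replicates, run the rejection posterior against the supplied
#' single-QTL prior records and score the strength estimate, strength-CI
#' and genomic-CI coverage, and whether any secondary peak of the
#' detected primary is (falsely, under a one-QTL truth) significant.
#'
#' @param ad windows x replicates matrix of profiles.
#' @param truth one-row truth record (columns `s`, `chrom`, `cm`).
#' @param gmap a [genome_map()].
#' @param null a [null_stage()] result matched to the scenario.
#' @param records [single_qtl_stage()] prior records simulated at (or
#'   near) the truth position (`pos_id` 1 is used); `NULL` skips the
#'   posterior scoring.
#' @param records_cm QTL position (cM) at which `records` were simulated.
#' @param thr a [thresholds()] object.
#' @param alpha significance level.
#' @param zone_cm truth zone as `c(lo, hi)` in cM on the truth chromosome
#'   (default: the containing chromosome arm).
#' @param tolerance,min_accept rejection-sampling controls.
#' @return list with `power`, `false_secondary_rate` (among detected
#'   primaries), `median_s_hat`, `strength_ci_coverage`,
#'   `genomic_ci_coverage`, and the per-replicate data frame `per_rep`.
#' @export
evaluate_pipeline <- function(ad, truth, gmap, null, records = NULL,
                              records_cm = NULL, thr = thresholds(),
                              alpha = 0.05, zone_cm = NULL,
                              tolerance = 0.025, min_accept = 50) {
  ci_truth <- match(truth$chrom[1], gmap$chrom$chrom)
  if (is.null(zone_cm)) {
    arms <- drosophila_arms()
    arms <- arms[arms$chrom == truth$chrom[1], , drop = FALSE]
    inarm <- arms$cm_lo <= truth$cm[1] & truth$cm[1] <= arms$cm_hi
    zone_cm <- c(arms$cm_lo[inarm][1], arms$cm_hi[inarm][1])
  }
  mp <- window_midpoints(gmap)
  n_reps <- ncol(ad)
  per <- data.frame(detected = logical(n_reps),
                    peak_cm = NA_real_, height = NA_real_,
                    s_hat = NA_real_, s_cover = NA, cm_cover = NA,
                    false_secondary = NA)
  rec1 <- if (!is.null(records))
    records[records$pos_id == 1, , drop = FALSE] else NULL
  for (r in seq_len(n_reps)) {
    sg <- sig_primaries(ad[, r], gmap, null, thr, alpha)
    in_zone <- sg$sig$chrom == ci_truth &
      mp$mid[sg$sig$window] >= zone_cm[1] &
      mp$mid[sg$sig$window] <= zone_cm[2]
    hit <- sg$sig[in_zone, , drop = FALSE]
    per$detected[r] <- nrow(hit) > 0
    if (nrow(hit) == 0) next
    top <- hit[which.max(hit$height), , drop = FALSE]
    per$peak_cm[r] <- mp$mid[top$window]
    per$height[r] <- top$height
    if (is.null(rec1)) next
    post <- suppressWarnings(
      rejection_posterior(rec1, top$height, records_cm,
                          mp$mid[top$window], tolerance, min_accept))
    if (post$failed) next
    per$s_hat[r] <- post$s_hat
    per$s_cover[r] <- post$s_ci[1] <= truth$s[1] &
      truth$s[1] <= post$s_ci[2]
    per$cm_cover[r] <- post$cm_ci[1] <= truth$cm[1] &
      truth$cm[1] <= post$cm_ci[2]
    sec <- find_secondary_peaks(sg$sp, top, thr)
    sec <- sec[sec$v > thr$v_t, , drop = FALSE]
    if (nrow(sec) == 0) {
      per$false_secondary[r] <- FALSE
    } else {
      sp_v <- secondary_pvalues(sec$v, post$accepted)
      per$false_secondary[r] <- any(sp_v$p_value < alpha, na.rm = TRUE)
    }
  }
  det <- per$detected
  list(power = mean(det),
       false_secondary_rate = mean(per$false_secondary[det], na.rm = TRUE),
       median_s_hat = median(per$s_hat[det], na.rm = TRUE),
       strength_ci_coverage = mean(per$s_cover[det], na.rm = TRUE),
       genomic_ci_coverage = mean(per$cm_cover[det], na.rm = TRUE),
       per_rep = per)
}

#' Classify two-linked-QTL test replicates
#'
#' For each replicate of a two-QTL scenario, counts the significant
#' primary peaks in the joint truth region and checks whether the second
#' QTL surfaces as a secondary peak of the first QTL's primary instead of
#' as its own primary. A secondary peak (deviation above `v_t`) is
#' attributed to the other true QTL when its window lies closer to that
#' QTL's position than the primary peak does. If single-QTL prior
#' `records` are supplied, a parallel classification additionally
#' requires the attributed secondary to be significant (conditional
#' P below `alpha`).
#'
#' @param ad windows x replicates profile matrix.
#' @param truth two-row truth record (`chrom`, `cm`).
#' @param gmap,null,records,records_cm,thr,alpha,tolerance,min_accept as
#'   in [evaluate_pipeline()].
#' @param margin_cm region margin beyond the two QTL positions.
#' @return list with per-class fractions (`both_primary`,
#'   `one_secondary`, `one_only`, `none`), the per-replicate class
#'   vector, and (with `records`) `one_secondary_significant`.
#' @export
classify_two_qtl <- function(ad, truth, gmap, null, records = NULL,
                             records_cm = NULL, thr = thresholds(),
                             alpha = 0.05, tolerance = 0.025,
                             min_accept = 50, margin_cm = 15) {
  stopifnot(nrow(truth) == 2, length(unique(truth$chrom)) == 1)
  ci_truth <- match(truth$chrom[1], gmap$chrom$chrom)
  lo <- min(truth$cm) - margin_cm
  hi <- max(truth$cm) + margin_cm
  mp <- window_midpoints(gmap)
  rec1 <- if (!is.null(records))
    records[records$pos_id == 1, , drop = FALSE] else NULL
  n_reps <- ncol(ad)
  cls <- character(n_reps)
  sig_sec <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    sg <- sig_primaries(ad[, r], gmap, null, thr, alpha)
    in_region <- sg$sig$chrom == ci_truth &
      mp$mid[sg$sig$window] >= lo & mp$mid[sg$sig$window] <= hi
    hit <- sg$sig[in_region, , drop = FALSE]
    if (nrow(hit) == 0) { cls[r] <- "none"; next }
    if (nrow(hit) >= 2) { cls[r] <- "both_primary"; next }
    top <- hit[1, , drop = FALSE]
    sec <- find_secondary_peaks(sg$sp, top, thr)
    sec <- sec[sec$v > thr$v_t, , drop = FALSE]
    # attribute secondaries: nearer to the true QTL that is not the one
    # under the primary peak
    p_cm <- mp$mid[top$window]
    other_cm <- truth$cm[which.max(abs(truth$cm - p_cm))]
    attributed <- nrow(sec) > 0 &&
      any(abs(mp$mid[sec$window] - other_cm) < abs(p_cm - other_cm))
    cls[r] <- if (attributed) "one_secondary" else "one_only"
    if (attributed && !is.null(rec1)) {
      post <- suppressWarnings(
        rejection_posterior(rec1, top$height, records_cm,
                            p_cm, tolerance, min_accept))
      if (!post$failed) {
        keep <- abs(mp$mid[sec$window] - other_cm) < abs(p_cm - other_cm)
        sp_v <- secondary_pvalues(sec$v[keep], post$accepted)
        sig_sec[r] <- any(sp_v$p_value < alpha, na.rm = TRUE)
      }
    }
  }
  out <- list(both_primary = mean(cls == "both_primary"),
              one_secondary = mean(cls == "one_secondary"),
              one_only = mean(cls == "one_only"),
              none = mean(cls == "none"),
              classes = cls)
  if (!is.null(rec1)) out$one_secondary_significant <- mean(sig_sec)
  out
}
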