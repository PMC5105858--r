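test_that("primary P-values implement the enrichment rule P = 1/e", {
  # one observed peak at 0.2; null scans average 1/3 peaks >= 0.2 -> e = 3
  prim <- data.frame(peak_id = 1, chrom = 1, window = 10, height = 0.2,
                     run_start = 5, run_end = 15)
  null3 <- fake_null(heights = c(0.25, 0.15, 0.12), n_reps = 3)
  res <- primary_pvalues(prim, null3)
  expect_equal(res$p_value, 1 / 3)
  expect_false(res$p_floor)
  # no enrichment (e <= 1) pins P at 1
  null_rich <- fake_null(heights = rep(0.3, 10), n_reps = 2)
  expect_equal(primary_pvalues(prim, null_rich)$p_value, 1)
  # a peak above every null height reports the resolution floor, flagged
  null_low <- fake_null(heights = rep(0.15, 50), n_reps = 100)
  res <- primary_pvalues(prim, null_low)
  expect_equal(res$p_value, 1 / 100)
  expect_true(res$p_floor)
})

test_that("multiple observed peaks raise per-scan frequency in e", {
  prim <- data.frame(peak_id = 1:2, chrom = 1, window = c(10, 40),
                     height = c(0.3, 0.2), run_start = c(5, 35),
                     run_end = c(15, 45))
  null <- fake_null(heights = rep(c(0.21, 0.11), each = 5), n_reps = 10)
  res <- primary_pvalues(prim, null)
  # shorter peak: 2 observed >= 0.2 vs 0.5 per null scan -> e = 4
  expect_equal(res$p_value[2], 0.25)
})

test_that("rejection posterior reduces to point masses on degenerate input", {
  rec <- fake_records(s = rep(0.3, 300), max_ad = rep(0.5, 300),
                      peak_cm = rep(20, 300))
  post <- rejection_posterior(rec, empirical_height = 0.5, qtl_cm = 20,
                              empirical_cm = 35)
  expect_equal(post$n_accept, 300)
  expect_equal(post$s_hat, 0.3)
  expect_equal(post$s_ci, c(0.3, 0.3))
  # all simulated peaks landed exactly on the QTL -> zero-width genomic CI
  # re-centred on the empirical window
  expect_equal(post$cm_ci, c(35, 35))
  expect_false(post$widened)
})

test_that("acceptance starvation widens once, then flags failure", {
  rec <- fake_records(s = runif(100), max_ad = seq(0.2, 0.24, length.out = 100))
  expect_warning(
    post <- rejection_posterior(rec, empirical_height = 0.25, qtl_cm = 0,
                                empirical_cm = 0, tolerance = 0.025,
                                min_accept = 90),
    "widened")
  expect_true(post$widened)
  expect_true(post$n_accept >= 90)
  expect_warning(
    bad <- rejection_posterior(rec, empirical_height = 0.9, qtl_cm = 0,
                               empirical_cm = 0),
    "widened")
  expect_true(bad$failed)
  expect_true(is.na(bad$s_hat))
})

test_that("posterior median strength is monotone in empirical peak height", {
  set.seed(8)
  s <- runif(4000)
  rec <- fake_records(s = s, max_ad = pmin(1, s + rnorm(4000, 0, 0.03)))
  hats <- sapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(h)
    suppressWarnings(rejection_posterior(rec, h, 0, 0)$s_hat))
  expect_true(all(diff(hats) > 0))
})

test_that("strength CI coverage on synthetic posteriors is near nominal", {
  set.seed(9)
  noise <- 0.04
  s <- runif(6000)
  rec <- fake_records(s = s, max_ad = pmin(1, s + rnorm(6000, 0, noise)))
  cover <- replicate(250, {
    s_true <- runif(1, 0.2, 0.8)
    h_obs <- s_true + rnorm(1, 0, noise)
    ci <- rejection_posterior(rec, h_obs, 0, 0)$s_ci
    ci[1] <= s_true && s_true <= ci[2]
  })
  expect_gt(mean(cover), 0.78)
  expect_lt(mean(cover), 0.98)
})

test_that("secondary P-values are the conditional exceedance fractions", {
  acc <- fake_records(s = runif(200), max_ad = runif(200),
                      max_v = runif(200, 0.001, 0.2))
  res <- secondary_pvalues(0, acc)
  expect_equal(res$p_value, 1)  # every simulated deviation exceeds zero
  res <- secondary_pvalues(0.5, acc)
  expect_equal(res$p_value, 0)  # beyond all simulated deviations
  expect_equal(res$p_floor, 1 / 200)
  v <- sort(acc$max_v)[100]
  expect_equal(secondary_pvalues(v, acc)$p_value, mean(acc$max_v > v))
  empty <- acc[0, ]
  expect_true(is.na(secondary_pvalues(0.1, empty)$p_value))
})

test_that("cluster strength apportioning conserves the total exactly", {
  set.seed(10)
  for (k in c(2, 3, 6)) {
    S <- runif(1)
    s_i <- apportion_strength(S, k)
    expect_length(s_i, k)
    expect_true(all(s_i >= 0))
    expect_equal(sum(s_i), S)
  }
})

test_that("null stage pools primary heights with reproducible counts", {
  gm <- small_map(n = 10)
  cfg <- small_config(N = 80, G = 4, depth = 100, n_pheno = 80)
  set.seed(12)
  nd <- null_stage(gm, cfg, thresholds(), n_reps = 15)
  expect_s3_class(nd, "null_peak_distribution")
  expect_equal(nd$n_reps, 15)
  expect_equal(length(nd$per_rep), 15)
  expect_equal(sum(nd$per_rep), length(nd$heights))
  expect_true(all(nd$heights > 0.1))
  # pooled tail frequencies decrease monotonically with height
  hs <- sort(unique(nd$heights))
  tails <- sapply(hs, function(h) sum(nd$heights >= h))
  expect_true(all(diff(tails) <= 0))
  set.seed(12)
  nd2 <- null_stage(gm, cfg, thresholds(), n_reps = 15)
  expect_identical(nd$heights, nd2$heights)
})

test_that("single-QTL records reuse one population across positions", {
  gm <- small_map(n = 10)
  cfg <- small_config(N = 80, G = 4, depth = 300, n_pheno = 80)
  pos <- data.frame(chrom = c("3", "X"), cm = c(55, 30))
  set.seed(13)
  rec <- single_qtl_stage(gmap = gm, config = cfg, positions = pos,
                          n_reps = 10)
  expect_equal(nrow(rec), 20)
  expect_equal(unique(rec$pos_id), c(1, 2))
  # one strength draw per replicate, shared across positions
  by_rep <- tapply(rec$s, rec$rep, function(x) length(unique(x)))
  expect_true(all(by_rep == 1))
  expect_true(all(rec$max_v >= 0))
  # strong strengths must produce taller maxima (rank correlation > 0)
  r1 <- rec[rec$pos_id == 1, ]
  expect_gt(cor(r1$s, r1$max_ad, method = "spearman"), 0)
})

test_that("the full pipeline finds a strong QTL and is seed-reproducible", {
  gm <- small_map(n = 25)
  cfg <- experiment_config("bsa", N = 250, G = 8, q = 0.2, depth = 400,
                           n_pheno = 250)
  qtl <- qtl_model(chrom = "3", cm = 60, f = strength_to_effect(0.5))
  set.seed(14)
  ad <- run_bsa_experiment(gm, cfg, qtl)$ad
  run_once <- function() {
    set.seed(15)
    suppressWarnings(
      sibsam_run(ad, gm, cfg, n_null = 40, n_single = 120, n_cluster = 40,
                 min_accept = 20))
  }
  res <- run_once()
  expect_s3_class(res, "sibsam_result")
  expect_false(is.null(res$report))
  hit <- res$report[res$report$kind == "primary", ]
  expect_equal(hit$chrom[1], "3")
  expect_lt(abs(hit$cm[1] - 60), 12)
  expect_lt(hit$p_value[1], 0.05)
  expect_true(hit$s_hat[1] > 0.15 && hit$s_hat[1] < 0.95)
  expect_true(hit$cm_lo[1] <= hit$cm_hi[1])
  res2 <- run_once()
  expect_identical(res$report, res2$report)
})

test_that("reports round-trip and empty reports write a header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(NULL, path)
  empty <- read.delim(path)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("p_value", "s_hat", "cm_lo", "cm_hi") %in% names(empty)))
  df <- data.frame(parent_id = 1, kind = "primary", chrom = "3",
                   window = 120L, phys_start = 1000, phys_end = 2000,
                   cm = 60.5, height = 0.42, p_value = 0.002,
                   cm_lo = 55.1, cm_hi = 66.2, s_hat = 0.31, s_lo = 0.22,
                   s_hi = 0.44)
  write_report(df, path)
  back <- read.delim(path)
  expect_equal(back$s_hat, df$s_hat)
  expect_equal(back$cm_lo, df$cm_lo)
  expect_equal(back$p_value, df$p_value)
})

test_that("a two-QTL cluster is recovered with conserved member strengths", {
  gm <- small_map(n = 30)
  cfg <- experiment_config("bsa", N = 250, G = 8, q = 0.2, depth = 400,
                           n_pheno = 250)
  set.seed(16)
  mp <- window_midpoints(gm)
  # synthetic empirical profile with two nearby bumps on chromosome 3
  ci3 <- which(mp$chrom_index == 3)
  ad <- rnorm(nrow(gm$windows), 0, 0.01)
  for (ctr in c(40, 80)) {
    d <- abs(mp$mid[ci3] - ctr)
    ad[ci3] <- ad[ci3] + 0.45 * pmax(0, 1 - d / 18)
  }
  sp <- smooth_profile(ad, mp$chrom_index, 4)
  members <- data.frame(
    window = ci3[c(which.min(abs(mp$mid[ci3] - 40)),
                   which.min(abs(mp$mid[ci3] - 80)))],
    chrom = "3", stringsAsFactors = FALSE)
  members$height <- sp[members$window]
  members$cm <- mp$mid[members$window]
  cl <- suppressWarnings(
    cluster_stage(gm, cfg, members, sp, n_reps = 60, min_accept = 5))
  expect_equal(nrow(cl$members), 2)
  expect_equal(nrow(cl$zones), 2)
  # every replicate's member strengths stay on the simplex
  expect_true(all(rowSums(cl$draws) <= 1 + 1e-12))
  if (!cl$failed) {
    expect_true(all(cl$members$s_lo <= cl$members$s_hat + 1e-12))
    expect_true(all(cl$members$s_hat <= cl$members$s_hi + 1e-12))
  }
})
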