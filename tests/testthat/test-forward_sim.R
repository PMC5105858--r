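test_that("strength/effect conversion inverts s = f/(1+f)", {
  expect_equal(strength_to_effect(0.5), 1)
  expect_equal(strength_to_effect(0), 0)
  expect_equal(strength_to_effect(0.2), 0.25)
  expect_error(strength_to_effect(1), "\\[0, 1\\)")
  s <- seq(0, 0.95, by = 0.05)
  expect_equal(effect_to_strength(strength_to_effect(s)), s)
})

test_that("male meiosis transmits a whole copy; females recombine at map rate", {
  set.seed(101)
  hi <- pure_chromosome(100, 1)
  lo <- pure_chromosome(100, 0)
  for (i in 1:20) {
    g <- recombine_gamete(hi, lo, male = TRUE)
    expect_equal(length(g$origin), 1)
    expect_true(g$origin %in% c(0, 1))
  }
  # 1-Morgan female meiosis between fully distinct copies: every crossover
  # switches origin, so breakpoints count crossovers; mean must be ~1
  n_bp <- replicate(3000, length(recombine_gamete(hi, lo)$ends) - 1)
  expect_equal(mean(n_bp), 1, tolerance = 0.06)
  # 0 cM chromosome: gamete identical to one parental copy
  g0 <- recombine_gamete(pure_chromosome(0, 1), pure_chromosome(0, 0))
  expect_equal(length(g0$origin), 1)
})

test_that("gamete tracts tile the map with increasing breakpoints", {
  set.seed(7)
  gm <- small_map(n = 10)
  pop <- founder_f1(gm, 30)
  for (g in 1:4) pop <- breed_generation(pop, gm)
  for (ind in pop[1:10]) {
    for (lab in names(ind$haps)) {
      L <- gm$chrom$total_cm[gm$chrom$chrom == lab]
      for (h in ind$haps[[lab]]) {
        expect_equal(h$ends[length(h$ends)], L)
        expect_true(all(diff(h$ends) > 0))
        expect_true(all(h$origin %in% c(0, 1)))
        # merged representation: no two adjacent tracts share an origin
        if (length(h$origin) > 1)
          expect_true(all(diff(h$origin) != 0))
      }
    }
  }
})

test_that("F1 founders are heterozygous and breeding keeps census size", {
  set.seed(3)
  gm <- small_map(n = 10)
  pop <- founder_f1(gm, 50)
  for (ind in pop) {
    expect_equal(length(ind$haps[["2"]]), 2)
    expect_equal(ind$haps[["2"]][[1]]$origin, 1L)
    expect_equal(ind$haps[["2"]][[2]]$origin, 0L)
    expect_equal(length(ind$haps[["X"]]), if (ind$female) 2 else 1)
  }
  kids <- breed_generation(pop, gm, N = 37)
  expect_length(kids, 37)
  males <- Filter(function(i) !i$female, pop)
  expect_error(breed_generation(males, gm), "single sex")
})

test_that("phenotypes follow genotype plus the declared noise model", {
  gm <- uniform_map(n = 4, total_cm = 100, chrom = "A")
  all_high <- list(female = TRUE,
                   haps = list(A = list(pure_chromosome(100, 1),
                                        pure_chromosome(100, 1))))
  all_low <- list(female = TRUE,
                  haps = list(A = list(pure_chromosome(100, 0),
                                       pure_chromosome(100, 0))))
  five <- qtl_model(chrom = rep("A", 5), cm = seq(10, 90, by = 20),
                    f = rep(1, 5), noise = "exploratory")
  # design mean = 5, so the exploratory noise SD is also 5
  expect_equal(five$noise_sd, 5)
  set.seed(1)
  ph_hi <- replicate(400, phenotype(all_high, five))
  ph_lo <- replicate(400, phenotype(all_low, five))
  expect_equal(mean(ph_hi), 10, tolerance = 0.6)
  expect_equal(mean(ph_lo), 0, tolerance = 0.6)
  expect_equal(sd(ph_hi), 5, tolerance = 0.6)
  # inference-stage noise: 0.5 x N(0,1) on top of a zero-locus model
  noise_only <- qtl_model(noise = "sibsam")
  set.seed(2)
  ph <- replicate(2000, phenotype(all_low, noise_only))
  expect_equal(mean(ph), 0, tolerance = 0.03)
  expect_equal(sd(ph), 0.5, tolerance = 0.03)
  # f = 0 loci leave the phenotype independent of ancestry
  null_eff <- qtl_model(chrom = "A", cm = 50, f = 0, noise = "sibsam")
  set.seed(3); a <- replicate(200, phenotype(all_high, null_eff))
  set.seed(3); b <- replicate(200, phenotype(all_low, null_eff))
  expect_identical(a, b)
})

test_that("tail selection sizes, partitions and tie-breaks are exact", {
  set.seed(11)
  ph <- rnorm(600)
  tails <- select_tails(ph, 0.10)
  expect_length(tails$high, 60)
  expect_length(tails$low, 60)
  expect_equal(sort(ph[tails$high]), sort(ph, decreasing = TRUE)[60:1])
  full <- select_tails(ph, 0.5)
  expect_length(intersect(full$high, full$low), 0)
  expect_setequal(c(full$high, full$low), seq_along(ph))
  # ties broken by stable index order
  tied <- c(1, 2, 2, 2, 0)
  expect_equal(select_tails(tied, 0.4)$high, c(2, 3))
  expect_equal(select_tails(tied, 0.4)$low, c(5, 1))
  expect_error(select_tails(ph, 0.0005), "empty")
})

test_that("read sampling reproduces pool frequencies and binomial noise", {
  gm <- uniform_map(n = 5, total_cm = 50, chrom = "A")
  pop <- list(list(female = TRUE,
                   haps = list(A = list(pure_chromosome(50, 1),
                                        pure_chromosome(50, 1)))),
              list(female = TRUE,
                   haps = list(A = list(pure_chromosome(50, 0),
                                        pure_chromosome(50, 0)))))
  set.seed(5)
  all_high <- sample_pool_reads(pop, 1, gm, depth = 10)
  expect_equal(all_high$freq, rep(1, 5))
  expect_equal(all_high$est, rep(1, 5))
  mixed <- sample_pool_reads(pop, c(1, 2), gm, depth = 300)
  expect_equal(mixed$freq, rep(0.5, 5))
  # estimate SD at p = 0.5, depth 300: sqrt(p(1-p)/depth) = 0.0289
  set.seed(6)
  est <- replicate(800, sample_pool_reads(pop, c(1, 2), gm, 300)$est[1])
  expect_equal(sd(est), sqrt(0.25 / 300), tolerance = 0.1)
  expect_error(sample_pool_reads(pop, integer(), gm, 10), "empty")
})

test_that("ancestry difference and cross-combining are elementwise", {
  expect_equal(ancestry_difference(0.6, 0.4), 0.2)
  x <- c(0.2, 0.5, 0.9)
  expect_equal(ancestry_difference(x, x), rep(0, 3))
  expect_equal(ancestry_difference(1, 0), 1)
  expect_error(ancestry_difference(1:3 / 10, 1:2 / 10), "different window")
  expect_equal(combine_crosses(list(x)), x)
  expect_equal(combine_crosses(list(x, x, x)), 3 * x)
  expect_error(combine_crosses(list(x, x[1:2])), "different window")
})

test_that("neutral experiments are unbiased around 0.5 ancestry and zero a_d", {
  set.seed(21)
  gm <- small_map(n = 15)
  cfg <- small_config()
  reps <- 40
  fh <- ad <- matrix(NA_real_, nrow(gm$windows), reps)
  for (r in seq_len(reps)) {
    res <- run_bsa_experiment(gm, cfg, qtl_model())
    fh[, r] <- res$freq_high
    ad[, r] <- res$ad
  }
  # grand-mean HIGH frequency ~ Binomial mean 0.5 across replicate pools
  expect_equal(mean(fh), 0.5, tolerance = 0.02)
  expect_equal(mean(ad), 0, tolerance = 0.02)
})

test_that("experiments are bit-reproducible under a fixed seed", {
  gm <- small_map(n = 12)
  cfg <- small_config()
  q <- qtl_model(chrom = "3", cm = 50, f = 1)
  set.seed(77); a <- run_bsa_experiment(gm, cfg, q)
  set.seed(77); b <- run_bsa_experiment(gm, cfg, q)
  expect_identical(a, b)
  cfgim <- small_config(mode = "im")
  set.seed(78); ia <- run_im_experiment(gm, cfgim, q)
  set.seed(78); ib <- run_im_experiment(gm, cfgim, q)
  expect_identical(ia, ib)
})

test_that("a_d at a QTL grows with effect size", {
  set.seed(31)
  gm <- small_map(n = 15)
  cfg <- small_config()
  mean_peak <- sapply(c(0, 0.5, 2), function(f) {
    q <- qtl_model(chrom = "3", cm = 55, f = f)
    mean(replicate(12, {
      ad <- run_bsa_experiment(gm, cfg, q)$ad
      w <- window_at(gm, "3", 55) +
        sum(gm$chrom$n_windows[seq_len(which(gm$chrom$chrom == "3") - 1)])
      ad[w]
    }))
  })
  expect_true(mean_peak[2] > mean_peak[1])
  expect_true(mean_peak[3] > mean_peak[2])
})

test_that("neutral IM ancestry dilutes as 0.5 per backcross round", {
  set.seed(41)
  gm <- small_map(n = 12)
  # G = 6: backcrosses form generations 3 and 5, and the final selection
  # at generation 6 samples ancestry at 0.5^3
  cfg <- experiment_config("im", N = 300, G = 6, q = 0.2, depth = 300,
                           n_pheno = 300)
  ap <- replicate(30, mean(run_im_experiment(gm, cfg, qtl_model())$ap))
  expect_equal(mean(ap), 0.5^3, tolerance = 0.035)
  # an F2-style design with no backcross generation stays near 0.5
  cfg2 <- experiment_config("im", N = 300, G = 2, q = 0.2, depth = 300,
                            n_pheno = 300)
  ap2 <- replicate(15, mean(run_im_experiment(gm, cfg2, qtl_model())$ap))
  expect_equal(mean(ap2), 0.5, tolerance = 0.04)
})

test_that("selected IM ancestry at a strong dominant-effect locus stays high", {
  set.seed(51)
  gm <- small_map(n = 12)
  cfg <- experiment_config("im", N = 300, G = 6, q = 0.2, depth = 300,
                           n_pheno = 300)
  q <- qtl_model(chrom = "2", cm = 54, f = 4)
  w <- window_at(gm, "2", 54) + gm$chrom$n_windows[1]
  ap_qtl <- replicate(15, run_im_experiment(gm, cfg, q)$ap[w])
  expect_true(mean(ap_qtl) > 0.25)  # well above the 0.125 neutral level
})

test_that("summed null crosses scale in spread like sqrt(k)", {
  set.seed(61)
  gm <- small_map(n = 15)
  one <- small_config(crosses = 1)
  four <- small_config(crosses = 4)
  sd1 <- sd(replicate(15, run_bsa_experiment(gm, one, qtl_model())$ad[5]))
  sd4 <- sd(replicate(15, run_bsa_experiment(gm, four, qtl_model())$ad[5]))
  expect_equal(sd4 / sd1, 2, tolerance = 0.5)
})

test_that("compiled engine and R-level operations agree on null a_d spread", {
  set.seed(71)
  gm <- small_map(n = 8)
  # R-level pipeline at a small scale
  r_ad <- replicate(8, {
    pop <- founder_f1(gm, 60)
    for (g in 2:4) pop <- breed_generation(pop, gm)
    noise <- qtl_model(noise = "sibsam")
    ph <- vapply(pop, phenotype, numeric(1), qtl = noise)
    tails <- select_tails(ph, 0.2)
    hi <- sample_pool_reads(pop, tails$high, gm, 200)
    lo <- sample_pool_reads(pop, tails$low, gm, 200)
    ancestry_difference(hi$est, lo$est)
  })
  cfg <- experiment_config("bsa", N = 60, G = 4, q = 0.2, depth = 200,
                           n_pheno = 60)
  c_ad <- replicate(8, run_bsa_experiment(gm, cfg, qtl_model())$ad)
  expect_equal(mean(r_ad), mean(c_ad), tolerance = 0.05)
  expect_equal(sd(as.numeric(r_ad)), sd(as.numeric(c_ad)), tolerance = 0.4)
})
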