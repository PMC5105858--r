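#' Experiment configuration for a BSA or IM simulation
#'
#' @param mode `"bsa"` or `"im"`.
#' @param N breeding individuals per generation.
#' @param G total number of generations; generation 1 is the F1 of the
#'   combined reciprocal parental crosses.
#' @param q selected proportion per phenotypic tail (each of the high and
#'   low pools for BSA; the single selected pool for IM).
#' @param depth informative reads sampled per window per pool.
#' @param n_pheno individuals phenotyped in the final generation.
#' @param females_only phenotype (and pool) only females in the final
#'   generation.
#' @param crosses number of independent replicate crosses whose profiles
#'   are summed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("bsa", "im"), N = 600, G = 10,
                              q = 0.2, depth = 300, n_pheno = N,
                              females_only = FALSE, crosses = 1) {
  mode <- match.arg(mode)
  stopifnot(N >= 2, G >= 2, depth >= 1, crosses >= 1, n_pheno >= 2)
  if (q <= 0 || q > 0.5 && mode == "bsa")
    stop("BSA needs 0 < q <= 0.5")
  if (q <= 0 || q > 1)
    stop("need 0 < q <= 1")
  structure(list(mode = mode, N = as.integer(N), G = as.integer(G), q = q,
                 depth = depth, n_pheno = as.integer(n_pheno),
                 females_only = isTRUE(females_only),
                 crosses = as.integer(crosses)),
            class = "experiment_config")
}

#' QTL model: causative loci and the residual-noise recipe
#'
#' Each locus adds `f` to an individual's phenotype per allele inherited
#' from the high parental strain (0-2 alleles at autosomal loci, 0-1 at
#' X-linked loci in males). Residual phenotypic noise is Gaussian with
#' mean zero and an SD set by the noise model:
#' \describe{
#'   \item{`"sibsam"`}{SD 0.5 (i.e. 0.5 times a standard normal draw), the
#'     inference-stage convention under which a locus with `f = 1`
#'     corresponds to strength `s = 0.5`.}
#'   \item{`"exploratory"`}{SD equal to the design-mean trait value
#'     `sum(f)` (each locus contributes one high allele in expectation),
#'     the convention of the design-evaluation simulations.}
#' }
#'
#' @param chrom chromosome label per locus (character vector).
#' @param cm genetic position per locus (cM).
#' @param f per-allele effect per locus (non-negative).
#' @param noise `"sibsam"` or `"exploratory"`, or ignore and set
#'   `noise_sd` directly.
#' @param noise_sd explicit residual SD overriding the model choice.
#' @return list of class `qtl_model`.
#' @export
qtl_model <- function(chrom = character(), cm = numeric(), f = numeric(),
                      noise = c("sibsam", "exploratory"), noise_sd = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(chrom) == length(cm), length(cm) == length(f),
            all(f >= 0))
  if (is.null(noise_sd))
    noise_sd <- if (noise == "sibsam") 0.5 else sum(f)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(chrom = as.character(chrom), cm = as.numeric(cm),
                 f = as.numeric(f), noise = noise, noise_sd = noise_sd),
            class = "qtl_model")
}

#' Convert QTL strength to per-allele effect size
#'
#' Strength `s` is the proportion of the mapping population's phenotypic
#' variance attributed to a QTL; under the convention that the fixed
#' residual noise corresponds to a locus of effect `f = 1`, strength and
#' effect are related by `s = f / (1 + f)`, whose inverse is
#' `f = s / (1 - s)`.
#'
#' @param s strength in `[0, 1)`.
#' @return effect size `f`.
#' @export
strength_to_effect <- function(s) {
  if (any(s < 0 | s >= 1)) stop("strength must lie in [0, 1)")
  s / (1 - s)
}

#' @rdname strength_to_effect
#' @param f effect size (non-negative).
#' @export
effect_to_strength <- function(f) {
  if (any(f < 0)) stop("effect size must be non-negative")
  f / (1 + f)
}

## ---------------------------------------------------------------------
## Granular R-level operations on explicit ancestry structures. These are
## the reference semantics; the whole-experiment runners below use the
## compiled engine, which shares the same recombination code.

#' Create a single-origin ancestry chromosome
#'
#' @param total_cm genetic length.
#' @param origin 1 (high strain) or 0 (low strain).
#' @return list with `ends` (tract right boundaries, last = `total_cm`),
#'   `origin` (0/1 per tract) and `total_cm`.
#' @export
pure_chromosome <- function(total_cm, origin) {
  list(ends = total_cm, origin = as.integer(origin), total_cm = total_cm)
}

#' Recombinant gamete from a pair of ancestry chromosomes
#'
#' Crossover count is Poisson with mean `total_cm / 100` (the map length
#' in Morgans), breakpoints uniform; crossover interference is not
#' modeled. Male meioses transmit a random whole copy with no crossovers.
#'
#' @param copy1,copy2 ancestry chromosomes (see [pure_chromosome()]).
#' @param male logical; male meiosis suppresses recombination.
#' @return an ancestry chromosome.
#' @export
recombine_gamete <- function(copy1, copy2, male = FALSE) {
  if (!isTRUE(all.equal(copy1$total_cm, copy2$total_cm)))
    stop("parental copies cover different maps")
  g <- cpp_recombine(copy1$ends, copy1$origin, copy2$ends, copy2$origin,
                     copy1$total_cm, male)
  list(ends = g$ends, origin = g$origin, total_cm = copy1$total_cm)
}

#' Founder (F1) population of combined reciprocal crosses
#'
#' Autosomes are heterozygous high/low in every F1 individual; F1 females
#' are X-heterozygous while F1 males carry either parental X with equal
#' probability (the reciprocal-cross mixture).
#'
#' @param gmap a [genome_map()].
#' @param N population size.
#' @return list of individuals; each has `female` plus a list `haps` with
#'   one or two ancestry chromosomes per chromosome label.
#' @export
founder_f1 <- function(gmap, N) {
  chrom <- gmap$chrom
  lapply(seq_len(N), function(i) {
    female <- runif(1) < 0.5
    haps <- list()
    for (j in seq_len(nrow(chrom))) {
      L <- chrom$total_cm[j]
      if (chrom$is_x[j] && !female) {
        haps[[chrom$chrom[j]]] <-
          list(pure_chromosome(L, if (runif(1) < 0.5) 1L else 0L))
      } else {
        haps[[chrom$chrom[j]]] <-
          list(pure_chromosome(L, 1L), pure_chromosome(L, 0L))
      }
    }
    list(female = female, haps = haps)
  })
}

#' Breed one generation by random mating
#'
#' Each of `N` offspring draws an independent random mother and father
#' from the previous generation. Sex is assigned 50/50. Autosomes receive
#' a recombinant maternal gamete and a random (non-recombinant) paternal
#' copy; daughters receive the father's X, sons only the mother's
#' recombinant X.
#'
#' @param pop population (list of individuals as from [founder_f1()]).
#' @param gmap a [genome_map()].
#' @param N offspring count; defaults to `length(pop)`.
#' @return the next generation in the same format.
#' @export
breed_generation <- function(pop, gmap, N = length(pop)) {
  female <- vapply(pop, `[[`, logical(1), "female")
  fem <- which(female)
  mal <- which(!female)
  if (length(fem) == 0 || length(mal) == 0)
    stop("cannot breed: generation contains a single sex")
  chrom <- gmap$chrom
  lapply(seq_len(N), function(i) {
    mom <- pop[[fem[sample.int(length(fem), 1)]]]
    dad <- pop[[mal[sample.int(length(mal), 1)]]]
    kid_female <- runif(1) < 0.5
    haps <- list()
    for (j in seq_len(nrow(chrom))) {
      lab <- chrom$chrom[j]
      mh <- mom$haps[[lab]]
      mg <- recombine_gamete(mh[[1]], mh[[2]], male = FALSE)
      if (chrom$is_x[j]) {
        haps[[lab]] <- if (kid_female) list(mg, dad$haps[[lab]][[1]])
                       else list(mg)
      } else {
        dh <- dad$haps[[lab]]
        dg <- recombine_gamete(dh[[1]], dh[[2]], male = TRUE)
        haps[[lab]] <- list(mg, dg)
      }
    }
    list(female = kid_female, haps = haps)
  })
}

origin_at_position <- function(hap, pos) {
  idx <- findInterval(pos, hap$ends) + 1L
  hap$origin[min(idx, length(hap$origin))]
}

#' High-strain allele count of one individual at a locus
#'
#' @param ind individual.
#' @param chrom chromosome label.
#' @param cm genetic position.
#' @return 0-2 (0-1 for the male X).
#' @export
allele_count_at <- function(ind, chrom, cm) {
  haps <- ind$haps[[as.character(chrom)]]
  sum(vapply(haps, function(h) as.integer(origin_at_position(h, cm) == 1L),
             integer(1)))
}

#' Phenotype an individual under a QTL model
#'
#' Genetic score is the sum over loci of `f` times the high-strain allele
#' count; Gaussian noise with the model's `noise_sd` is added.
#'
#' @param ind individual.
#' @param qtl a [qtl_model()].
#' @return numeric phenotype.
#' @export
phenotype <- function(ind, qtl) {
  g <- 0
  if (length(qtl$f) > 0)
    g <- sum(qtl$f * mapply(function(ch, cm) allele_count_at(ind, ch, cm),
                            qtl$chrom, qtl$cm))
  g + qtl$noise_sd * rnorm(1)
}

#' Select phenotypic tail pools
#'
#' The high pool holds the `floor(q * n)` largest phenotypes and the low
#' pool the `floor(q * n)` smallest; ties at a cutoff are broken by stable
#' order of individual index. IM selects only the high (non-backcross
#' parent) tail.
#'
#' @param phen numeric phenotypes.
#' @param q selected proportion per tail.
#' @param mode `"bsa"` (two pools) or `"im"` (single pool).
#' @return list with integer index vectors `high` and (for BSA) `low`.
#' @export
select_tails <- function(phen, q, mode = c("bsa", "im")) {
  mode <- match.arg(mode)
  n <- length(phen)
  k <- floor(q * n)
  if (k < 1) stop("selected pool would be empty (q * n < 1)")
  hi <- order(-phen)[seq_len(k)]  # order() is stable: ties keep index order
  if (mode == "im") return(list(high = hi))
  lo <- order(phen)[seq_len(k)]
  list(high = hi, low = lo)
}

#' Sample pooled sequencing reads for one pool
#'
#' Per window, the pool's true high-strain ancestry frequency is computed
#' over all chromosome copies at the window midpoint; the number of
#' high-ancestry reads is Binomial(depth, freq) and the estimated
#' frequency is reads/depth.
#'
#' @param pop population.
#' @param pool integer indices of the pool members.
#' @param gmap a [genome_map()].
#' @param depth informative reads per window (scalar or per-window).
#' @return list with per-window `freq` (true) and `est` (read-sampled).
#' @export
sample_pool_reads <- function(pop, pool, gmap, depth) {
  if (length(pool) == 0) stop("pool is empty")
  mp <- window_midpoints(gmap)
  W <- length(mp$mid)
  depth <- rep_len(depth, W)
  high <- tot <- numeric(W)
  labs <- gmap$chrom$chrom
  for (i in pool) {
    ind <- pop[[i]]
    for (j in seq_along(labs)) {
      wsel <- which(mp$chrom_index == j)
      for (h in ind$haps[[labs[j]]]) {
        idx <- pmin(findInterval(mp$mid[wsel], h$ends) + 1L, length(h$origin))
        high[wsel] <- high[wsel] + (h$origin[idx] == 1L)
        tot[wsel] <- tot[wsel] + 1
      }
    }
  }
  freq <- high / tot
  est <- rbinom(W, depth, freq) / depth
  list(freq = freq, est = est)
}

#' Ancestry difference between high and low pools
#'
#' @param high,low per-window ancestry frequency estimates of the two
#'   pools.
#' @return per-window `a_d = high - low`, in `[-1, 1]`.
#' @export
ancestry_difference <- function(high, low) {
  if (length(high) != length(low))
    stop("high and low profiles cover different window sets")
  high - low
}

#' Sum ancestry profiles across independent crosses
#'
#' @param profiles list of equal-length numeric profiles.
#' @return element-wise sum.
#' @export
combine_crosses <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles to combine")
  W <- unique(lengths(profiles))
  if (length(W) != 1) stop("profiles cover different window sets")
  Reduce(`+`, profiles)
}

## ---------------------------------------------------------------------
## Whole-experiment runners (compiled engine)

engine_args <- function(gmap, config) {
  mp <- window_midpoints(gmap)
  W <- length(mp$mid)
  list(chrom_len = gmap$chrom$total_cm, chrom_is_x = gmap$chrom$is_x,
       win_chrom = mp$chrom_index, win_mid = mp$mid,
       depth = rep_len(config$depth, W))
}

qtl_to_engine <- function(gmap, qtl) {
  ci <- match(qtl$chrom, gmap$chrom$chrom)
  if (anyNA(ci)) stop("QTL on unknown chromosome: ",
                      paste(qtl$chrom[is.na(ci)], collapse = ", "))
  tot <- gmap$chrom$total_cm[ci]
  if (any(qtl$cm < 0 | qtl$cm > tot)) stop("QTL position outside chromosome")
  list(chrom = as.integer(ci), cm = qtl$cm, f = qtl$f,
       noise_sd = qtl$noise_sd)
}

#' Run one BSA mapping experiment
#'
#' Breeds `G` generations (F1 onward) with no phenotypic selection before
#' the last, phenotypes `n_pheno` final-generation individuals (optionally
#' females only), selects the two `q` tails, samples pooled reads, and
#' returns the per-window ancestry difference. With `crosses > 1` the
#' profile is the sum over independent replicate crosses.
#'
#' @param gmap a [genome_map()].
#' @param config an [experiment_config()] with `mode = "bsa"`.
#' @param qtl a [qtl_model()].
#' @return list with `ad` plus per-cross matrices `est_high`, `est_low`,
#'   `freq_high`, `freq_low` (windows x crosses).
#' @export
run_bsa_experiment <- function(gmap, config, qtl = qtl_model()) {
  stopifnot(inherits(config, "experiment_config"), config$mode == "bsa")
  ea <- engine_args(gmap, config)
  qe <- qtl_to_engine(gmap, qtl)
  ads <- eh <- el <- fh <- fl <- NULL
  for (r in seq_len(config$crosses)) {
    res <- cpp_bsa_engine(ea$chrom_len, ea$chrom_is_x, ea$win_chrom,
                          ea$win_mid, config$N, config$G, config$q,
                          ea$depth, ea$depth, config$n_pheno,
                          config$females_only, list(qe))[[1]]
    ads <- cbind(ads, res$ad)
    eh <- cbind(eh, res$est_high); el <- cbind(el, res$est_low)
    fh <- cbind(fh, res$freq_high); fl <- cbind(fl, res$freq_low)
  }
  list(ad = rowSums(ads), est_high = eh, est_low = el,
       freq_high = fh, freq_low = fl)
}

#' Evaluate several QTL configurations on one simulated population
#'
#' Simulates the mapping population once and then, for each QTL
#' configuration, performs phenotyping, tail selection and read sampling
#' separately. This is the ancestry-reuse device of the single-QTL and
#' cluster inference stages: one set of simulated ancestries serves every
#' candidate QTL placement.
#'
#' @param gmap a [genome_map()].
#' @param config an [experiment_config()].
#' @param qtl_list list of [qtl_model()] objects.
#' @return list (one element per configuration) of engine results, each
#'   with `ad`, `est_high`, `est_low`, `freq_high`, `freq_low`.
#' @export
run_bsa_population <- function(gmap, config, qtl_list) {
  stopifnot(config$mode == "bsa")
  ea <- engine_args(gmap, config)
  cfgs <- lapply(qtl_list, qtl_to_engine, gmap = gmap)
  cpp_bsa_engine(ea$chrom_len, ea$chrom_is_x, ea$win_chrom, ea$win_mid,
                 config$N, config$G, config$q, ea$depth, ea$depth,
                 config$n_pheno, config$females_only, cfgs)
}

#' Run one IM (introgression mapping) experiment
#'
#' Random mating in odd generations; in even generations (starting with
#' the F2) the whole generation is phenotyped, the top-`q` tail toward the
#' non-backcross parent is selected, and each selected individual is
#' crossed to a pure backcross-strain mate. In the final generation the
#' selected pool is sequenced; `ap` is its per-window high-strain ancestry
#' proportion. With `crosses > 1` profiles are summed.
#'
#' @inheritParams run_bsa_experiment
#' @return list with `ap` (summed over crosses) and per-cross matrices
#'   `est` and `freq`.
#' @export
run_im_experiment <- function(gmap, config, qtl = qtl_model()) {
  stopifnot(inherits(config, "experiment_config"), config$mode == "im")
  ea <- engine_args(gmap, config)
  qe <- qtl_to_engine(gmap, qtl)
  aps <- fr <- NULL
  for (r in seq_len(config$crosses)) {
    res <- cpp_im_engine(ea$chrom_len, ea$chrom_is_x, ea$win_chrom,
                         ea$win_mid, config$N, config$G, config$q,
                         ea$depth, config$n_pheno, qe$chrom, qe$cm, qe$f,
                         qe$noise_sd)
    aps <- cbind(aps, res$ap)
    fr <- cbind(fr, res$freq)
  }
  list(ap = rowSums(aps), est = aps, freq = fr)
}
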