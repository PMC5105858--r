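// Forward-in-time ancestry-tract simulation core for BSA and IM
// mapping experiments. Individuals carry, per chromosome copy, a list of
// ancestry tracts (parental origin HIGH = 1 or LOW = 0) delimited by
// recombination breakpoints in centimorgan coordinates. Recombination
// counts are Poisson with mean = map length in Morgans; males do not
// recombine; the X is hemizygous in males. All randomness goes through
// R's RNG so set.seed() controls every draw.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// One chromosome copy: tract i covers [ends[i-1], ends[i]) with origin
// org[i]; ends.back() equals the chromosome's genetic length.
struct Hap {
  std::vector<double> ends;
  std::vector<unsigned char> org;
};

static inline Hap pure_hap(double L, unsigned char origin) {
  Hap h;
  h.ends.push_back(L);
  h.org.push_back(origin);
  return h;
}

static inline int tract_index(const Hap& h, double pos) {
  // first end strictly greater than pos; position == L clamps to last tract
  size_t i = std::upper_bound(h.ends.begin(), h.ends.end(), pos) - h.ends.begin();
  if (i >= h.ends.size()) i = h.ends.size() - 1;
  return (int)i;
}

static inline unsigned char origin_at(const Hap& h, double pos) {
  return h.org[tract_index(h, pos)];
}

// append [a, b) of source hap onto result, merging equal-origin neighbours
static void append_segment(Hap& res, const Hap& src, double a, double b) {
  if (b <= a) return;
  size_t i = std::upper_bound(src.ends.begin(), src.ends.end(), a) - src.ends.begin();
  if (i >= src.ends.size()) i = src.ends.size() - 1;
  double pos = a;
  while (pos < b) {
    double seg_end = std::min(src.ends[i], b);
    unsigned char o = src.org[i];
    if (!res.org.empty() && res.org.back() == o) {
      res.ends.back() = seg_end;
    } else {
      res.ends.push_back(seg_end);
      res.org.push_back(o);
    }
    pos = seg_end;
    ++i;
  }
}

// Female-meiosis gamete: Poisson(L/100) crossovers at uniform positions,
// starting from a random copy. Male meiosis transmits a random whole copy.
static Hap make_gamete(const Hap& h1, const Hap& h2, double L, bool male) {
  const Hap* copies[2] = { &h1, &h2 };
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  if (male || L <= 0.0) return *copies[cur];
  int k = (int)R::rpois(L / 100.0);
  if (k == 0) return *copies[cur];
  std::vector<double> cuts(k);
  for (int i = 0; i < k; ++i) cuts[i] = unif_rand() * L;
  std::sort(cuts.begin(), cuts.end());
  Hap res;
  double pos = 0.0;
  for (int i = 0; i < k; ++i) {
    append_segment(res, *copies[cur], pos, cuts[i]);
    pos = cuts[i];
    cur = 1 - cur;
  }
  append_segment(res, *copies[cur], pos, L);
  return res;
}

struct Ind {
  bool female;
  // per chromosome: maternal copy [2c], paternal copy [2c+1];
  // males carry no paternal X ([2c+1] left empty for the X)
  std::vector<Hap> hap;
};

struct MapSpec {
  std::vector<double> len;
  std::vector<bool> is_x;
  int C;
};

static void init_f1(std::vector<Ind>& pop, int N, const MapSpec& m) {
  // F1 of combined reciprocal crosses between pure HIGH and LOW strains:
  // autosomes heterozygous; females X-heterozygous; males carry either
  // parental X with probability 1/2 (reciprocal-cross mixture).
  pop.resize(N);
  for (int i = 0; i < N; ++i) {
    Ind& ind = pop[i];
    ind.female = unif_rand() < 0.5;
    ind.hap.assign(2 * m.C, Hap());
    for (int c = 0; c < m.C; ++c) {
      double L = m.len[c];
      if (m.is_x[c] && !ind.female) {
        ind.hap[2 * c] = pure_hap(L, unif_rand() < 0.5 ? 1 : 0);
      } else {
        ind.hap[2 * c] = pure_hap(L, 1);
        ind.hap[2 * c + 1] = pure_hap(L, 0);
      }
    }
  }
}

// Make one offspring from given mother and father.
static Ind make_offspring(const Ind& mom, const Ind& dad, const MapSpec& m) {
  Ind kid;
  kid.female = unif_rand() < 0.5;
  kid.hap.assign(2 * m.C, Hap());
  for (int c = 0; c < m.C; ++c) {
    double L = m.len[c];
    if (m.is_x[c]) {
      kid.hap[2 * c] = make_gamete(mom.hap[2 * c], mom.hap[2 * c + 1], L, false);
      if (kid.female) kid.hap[2 * c + 1] = dad.hap[2 * c];
    } else {
      kid.hap[2 * c] = make_gamete(mom.hap[2 * c], mom.hap[2 * c + 1], L, false);
      kid.hap[2 * c + 1] = make_gamete(dad.hap[2 * c], dad.hap[2 * c + 1], L, true);
    }
  }
  return kid;
}

static void split_sexes(const std::vector<Ind>& pop,
                        std::vector<int>& fem, std::vector<int>& mal) {
  fem.clear(); mal.clear();
  for (size_t i = 0; i < pop.size(); ++i)
    (pop[i].female ? fem : mal).push_back((int)i);
}

static void breed_random(const std::vector<Ind>& prev, std::vector<Ind>& next,
                         int N, const MapSpec& m) {
  std::vector<int> fem, mal;
  split_sexes(prev, fem, mal);
  if (fem.empty() || mal.empty())
    stop("cannot breed: generation contains a single sex");
  next.clear();
  next.reserve(N);
  for (int i = 0; i < N; ++i) {
    const Ind& mom = prev[fem[(int)(unif_rand() * fem.size())]];
    const Ind& dad = prev[mal[(int)(unif_rand() * mal.size())]];
    next.push_back(make_offspring(mom, dad, m));
  }
}

static int allele_count(const Ind& ind, int c, double pos, const MapSpec& m) {
  int n = origin_at(ind.hap[2 * c], pos) == 1 ? 1 : 0;
  if (!(m.is_x[c] && !ind.female))
    n += origin_at(ind.hap[2 * c + 1], pos) == 1 ? 1 : 0;
  return n;
}

// Stable sort of 0..n-1 by phenotype; ties keep ascending index order.
static std::vector<int> order_stable(const std::vector<double>& v, bool decreasing) {
  std::vector<int> idx(v.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
  if (decreasing)
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return v[a] > v[b]; });
  else
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return v[a] < v[b]; });
  return idx;
}

// True HIGH-ancestry frequency per window over all chromosome copies of
// the pool members, evaluated at window cM midpoints.
static void pool_freq(const std::vector<Ind>& pop, const std::vector<int>& pool,
                      const MapSpec& m,
                      const std::vector<std::vector<double> >& win_mid,
                      std::vector<double>& freq) {
  int W = 0;
  std::vector<int> offset(m.C, 0);
  for (int c = 0; c < m.C; ++c) { offset[c] = W; W += (int)win_mid[c].size(); }
  std::vector<double> high(W, 0.0), tot(W, 0.0);
  for (size_t k = 0; k < pool.size(); ++k) {
    const Ind& ind = pop[pool[k]];
    for (int c = 0; c < m.C; ++c) {
      const std::vector<double>& mids = win_mid[c];
      int ncopy = (m.is_x[c] && !ind.female) ? 1 : 2;
      for (int cp = 0; cp < ncopy; ++cp) {
        const Hap& h = ind.hap[2 * c + cp];
        size_t t = 0;
        for (size_t w = 0; w < mids.size(); ++w) {
          while (t + 1 < h.ends.size() && h.ends[t] <= mids[w]) ++t;
          high[offset[c] + w] += h.org[t];
          tot[offset[c] + w] += 1.0;
        }
      }
    }
  }
  freq.assign(W, 0.0);
  for (int w = 0; w < W; ++w) freq[w] = tot[w] > 0 ? high[w] / tot[w] : NA_REAL;
}

static std::vector<double> sample_reads(const std::vector<double>& freq,
                                        const NumericVector& depth) {
  std::vector<double> est(freq.size());
  for (size_t w = 0; w < freq.size(); ++w) {
    double d = depth[(int)w];
    est[w] = R::rbinom(d, freq[w]) / d;
  }
  return est;
}

static MapSpec as_mapspec(NumericVector chrom_len, LogicalVector chrom_is_x) {
  MapSpec m;
  m.C = chrom_len.size();
  for (int c = 0; c < m.C; ++c) {
    m.len.push_back(chrom_len[c]);
    m.is_x.push_back(chrom_is_x[c]);
  }
  return m;
}

static std::vector<std::vector<double> > split_windows(const MapSpec& m,
                                                       IntegerVector win_chrom,
                                                       NumericVector win_mid) {
  std::vector<std::vector<double> > wm(m.C);
  for (int w = 0; w < win_chrom.size(); ++w) {
    int c = win_chrom[w] - 1;
    if (c < 0 || c >= m.C) stop("window chromosome index out of range");
    wm[c].push_back(win_mid[w]);
  }
  return wm;
}

// Phenotype, tail-select and read-sample one QTL configuration on an
// already-simulated final generation. Returns high/low estimated and true
// frequencies plus a_d.
static List eval_config(const std::vector<Ind>& pop,
                        const std::vector<int>& phen_idx,
                        const MapSpec& m,
                        const std::vector<std::vector<double> >& wm,
                        IntegerVector win_chrom,
                        double q,
                        NumericVector depth_high, NumericVector depth_low,
                        IntegerVector qchrom, NumericVector qcm,
                        NumericVector qf, double noise_sd) {
  int n = (int)phen_idx.size();
  int nq = qchrom.size();
  std::vector<double> phen(n);
  for (int i = 0; i < n; ++i) {
    double g = 0.0;
    for (int j = 0; j < nq; ++j)
      g += qf[j] * allele_count(pop[phen_idx[i]], qchrom[j] - 1, qcm[j], m);
    phen[i] = g + noise_sd * norm_rand();
  }
  int nh = (int)std::floor(q * n);
  if (nh < 1) stop("selected pool would be empty (q * n < 1)");
  std::vector<int> hi_order = order_stable(phen, true);
  std::vector<int> lo_order = order_stable(phen, false);
  std::vector<int> hi(nh), lo(nh);
  for (int i = 0; i < nh; ++i) {
    hi[i] = phen_idx[hi_order[i]];
    lo[i] = phen_idx[lo_order[i]];
  }
  std::vector<double> fh, fl;
  pool_freq(pop, hi, m, wm, fh);
  pool_freq(pop, lo, m, wm, fl);
  std::vector<double> eh = sample_reads(fh, depth_high);
  std::vector<double> el = sample_reads(fl, depth_low);
  int W = (int)fh.size();
  NumericVector ad(W), est_h(W), est_l(W), tru_h(W), tru_l(W);
  for (int w = 0; w < W; ++w) {
    est_h[w] = eh[w]; est_l[w] = el[w];
    tru_h[w] = fh[w]; tru_l[w] = fl[w];
    ad[w] = eh[w] - el[w];
  }
  return List::create(_["ad"] = ad, _["est_high"] = est_h, _["est_low"] = est_l,
                      _["freq_high"] = tru_h, _["freq_low"] = tru_l);
}

// [[Rcpp::export]]
List cpp_bsa_engine(NumericVector chrom_len, LogicalVector chrom_is_x,
                    IntegerVector win_chrom, NumericVector win_mid,
                    int N, int G, double q,
                    NumericVector depth_high, NumericVector depth_low,
                    int n_pheno, bool females_only, List qtl_configs) {
  if (N < 2 || G < 2) stop("need N >= 2 and G >= 2");
  MapSpec m = as_mapspec(chrom_len, chrom_is_x);
  std::vector<std::vector<double> > wm = split_windows(m, win_chrom, win_mid);
  std::vector<Ind> pop, next;
  init_f1(pop, N, m);
  for (int g = 2; g <= G; ++g) {
    breed_random(pop, next, N, m);
    pop.swap(next);
  }
  // phenotyping subset: offspring are exchangeable so the first n_pheno
  // candidates form a random sample
  std::vector<int> cand;
  for (int i = 0; i < N; ++i)
    if (!females_only || pop[i].female) cand.push_back(i);
  int n_phen = std::min((int)cand.size(), n_pheno);
  if (n_phen < 2) stop("not enough individuals available for phenotyping");
  std::vector<int> phen_idx(cand.begin(), cand.begin() + n_phen);
  List out(qtl_configs.size());
  for (int k = 0; k < qtl_configs.size(); ++k) {
    List cfg = qtl_configs[k];
    out[k] = eval_config(pop, phen_idx, m, wm, win_chrom, q,
                         depth_high, depth_low,
                         cfg["chrom"], cfg["cm"], cfg["f"],
                         as<double>(cfg["noise_sd"]));
  }
  return out;
}

// Introgression mapping: random mating in odd generations; in even
// generations the top-q tail (toward the HIGH, non-backcross parent) is
// selected and crossed to pure LOW-strain mates. The final generation is
// phenotyped (optionally a subset) and its selected tail is sequenced;
// a_p is the HIGH-ancestry proportion of that pool.
// [[Rcpp::export]]
List cpp_im_engine(NumericVector chrom_len, LogicalVector chrom_is_x,
                   IntegerVector win_chrom, NumericVector win_mid,
                   int N, int G, double q, NumericVector depth,
                   int n_pheno, IntegerVector qchrom, NumericVector qcm,
                   NumericVector qf, double noise_sd) {
  if (N < 2 || G < 2) stop("need N >= 2 and G >= 2");
  MapSpec m = as_mapspec(chrom_len, chrom_is_x);
  std::vector<std::vector<double> > wm = split_windows(m, win_chrom, win_mid);
  std::vector<Ind> pop, next;
  init_f1(pop, N, m);
  int nq = qchrom.size();

  for (int g = 2; g <= G; ++g) {
    int prev_gen = g - 1;
    if (prev_gen >= 2 && prev_gen % 2 == 0) {
      // phenotype the whole previous generation, keep the HIGH tail,
      // backcross each selected individual to a pure LOW mate
      int n = (int)pop.size();
      std::vector<double> phen(n);
      for (int i = 0; i < n; ++i) {
        double gscore = 0.0;
        for (int j = 0; j < nq; ++j)
          gscore += qf[j] * allele_count(pop[i], qchrom[j] - 1, qcm[j], m);
        phen[i] = gscore + noise_sd * norm_rand();
      }
      std::vector<int> ord = order_stable(phen, true);
      int nsel = std::max(1, (int)std::floor(q * n));
      std::vector<int> sel(ord.begin(), ord.begin() + nsel);
      next.clear();
      next.reserve(N);
      Ind pure_f, pure_m;
      pure_f.female = true;
      pure_m.female = false;
      pure_f.hap.assign(2 * m.C, Hap());
      pure_m.hap.assign(2 * m.C, Hap());
      for (int c = 0; c < m.C; ++c) {
        pure_f.hap[2 * c] = pure_hap(m.len[c], 0);
        pure_f.hap[2 * c + 1] = pure_hap(m.len[c], 0);
        pure_m.hap[2 * c] = pure_hap(m.len[c], 0);
        if (!m.is_x[c]) pure_m.hap[2 * c + 1] = pure_hap(m.len[c], 0);
      }
      for (int i = 0; i < N; ++i) {
        const Ind& chosen = pop[sel[(int)(unif_rand() * nsel)]];
        if (chosen.female)
          next.push_back(make_offspring(chosen, pure_m, m));
        else
          next.push_back(make_offspring(pure_f, chosen, m));
      }
      pop.swap(next);
    } else {
      breed_random(pop, next, N, m);
      pop.swap(next);
    }
  }

  // final selection and sequencing
  int n_phen = std::min((int)pop.size(), n_pheno);
  std::vector<double> phen(n_phen);
  for (int i = 0; i < n_phen; ++i) {
    double gscore = 0.0;
    for (int j = 0; j < nq; ++j)
      gscore += qf[j] * allele_count(pop[i], qchrom[j] - 1, qcm[j], m);
    phen[i] = gscore + noise_sd * norm_rand();
  }
  std::vector<int> ord = order_stable(phen, true);
  int nsel = std::max(1, (int)std::floor(q * n_phen));
  std::vector<int> pool(ord.begin(), ord.begin() + nsel);
  std::vector<double> fr;
  pool_freq(pop, pool, m, wm, fr);
  std::vector<double> est = sample_reads(fr, depth);
  int W = (int)fr.size();
  NumericVector ap(W), tru(W);
  for (int w = 0; w < W; ++w) { ap[w] = est[w]; tru[w] = fr[w]; }
  return List::create(_["ap"] = ap, _["freq"] = tru);
}

// Single female-meiosis gamete from two parental chromosome copies;
// exposed so the R-level recombination operation shares the engine's code.
// [[Rcpp::export]]
List cpp_recombine(NumericVector ends1, IntegerVector org1,
                   NumericVector ends2, IntegerVector org2,
                   double total_cm, bool male) {
  Hap h1, h2;
  for (int i = 0; i < ends1.size(); ++i) {
    h1.ends.push_back(ends1[i]);
    h1.org.push_back((unsigned char)org1[i]);
  }
  for (int i = 0; i < ends2.size(); ++i) {
    h2.ends.push_back(ends2[i]);
    h2.org.push_back((unsigned char)org2[i]);
  }
  Hap g = make_gamete(h1, h2, total_cm, male);
  NumericVector e(g.ends.size());
  IntegerVector o(g.org.size());
  for (size_t i = 0; i < g.ends.size(); ++i) {
    e[i] = g.ends[i];
    o[i] = g.org[i];
  }
  return List::create(_["ends"] = e, _["origin"] = o);
}
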