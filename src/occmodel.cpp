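// Marginalised-likelihood core of the multi-species dynamic occupancy
// model. The latent occupancy chain z[i,j,t] is integrated out by a
// scaled two-state forward recursion, so the sampler only ever works
// with the marginal likelihood of the detection histories.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double invlogit(double x) {
  if (x > 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// log(1 + exp(x)) without overflow
static inline double log1pe(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.918938533204672742 - std::log(sd) - 0.5 * z * z;
}

struct OccData {
  int nSpecies, nSites, nYears, nVisits;
  IntegerMatrix y;            // species x visits
  IntegerVector vShort, vLong, vYear;
  NumericMatrix Xosr, Xneo, Xfii; // sites x (nYears-1), lagged centred
  std::vector<std::vector<int> > visIdx; // per site*T+t: visit indices
  std::vector<int> vClass;    // 0 single, 1 short, 2 long
  // flattened per-(site,year) visit layout for the sampler hot loop
  std::vector<int> visStart;  // size nSites*nYears+1
  std::vector<int> visFlat;   // visit index, grouped by (site,year)
  std::vector<int> visFlatClass;
  std::vector<char> yT;       // detections, visit-major per species

  OccData(IntegerMatrix y_, IntegerVector vSite, IntegerVector vYear_,
          IntegerVector vShort_, IntegerVector vLong_,
          NumericMatrix Xosr_, NumericMatrix Xneo_, NumericMatrix Xfii_,
          int nSites_, int nYears_)
    : nSpecies(y_.nrow()), nSites(nSites_), nYears(nYears_),
      nVisits(y_.ncol()), y(y_), vShort(vShort_), vLong(vLong_),
      vYear(vYear_), Xosr(Xosr_), Xneo(Xneo_), Xfii(Xfii_),
      visIdx(nSites_ * nYears_), vClass(y_.ncol()) {
    for (int k = 0; k < nVisits; ++k) {
      visIdx[vSite[k] * nYears + vYear_[k]].push_back(k);
      vClass[k] = vShort_[k] ? 1 : (vLong_[k] ? 2 : 0);
    }
    visStart.resize(nSites * nYears + 1, 0);
    visFlat.reserve(nVisits);
    visFlatClass.reserve(nVisits);
    for (int s = 0; s < nSites * nYears; ++s) {
      visStart[s] = (int)visFlat.size();
      for (size_t v = 0; v < visIdx[s].size(); ++v) {
        visFlat.push_back(visIdx[s][v]);
        visFlatClass.push_back(vClass[visIdx[s][v]]);
      }
    }
    visStart[nSites * nYears] = (int)visFlat.size();
    yT.resize((size_t)nSpecies * nVisits);
    for (int i = 0; i < nSpecies; ++i)
      for (int k = 0; k < nVisits; ++k)
        yT[(size_t)i * nVisits + k] = (char)y_(i, k);
  }
};

struct Params {
  int n, T;
  std::vector<double> psi0l, lgam, b0, b1, b2, b3, b4, b5, b6, alpha;
  // hyper parameters
  double mu_gam, sd_gam, mu_b0, sd_b0, mu_b4, sd_b4, mu_b5, sd_b5,
         mu_b6, sd_b6, sd_alpha;
  double mu_cov[3][2], sd_cov[3][2]; // covariate c x group g
};

// marginal log-likelihood of species i at site j
static double site_ll(const OccData& d, const Params& p, int i, int j,
                      const std::vector<double>& pdet) {
  double psi0 = invlogit(p.psi0l[i]);
  double gam = invlogit(p.lgam[i]);
  double pr1 = psi0, pr0 = 1.0 - psi0, ll = 0.0;
  for (int t = 0; t < d.nYears; ++t) {
    if (t > 0) {
      double phi = invlogit(p.b0[i] + p.b1[i] * d.Xosr(j, t - 1) +
                            p.b2[i] * d.Xneo(j, t - 1) +
                            p.b3[i] * d.Xfii(j, t - 1));
      double n1 = pr1 * phi + pr0 * gam;
      double n0 = pr1 * (1.0 - phi) + pr0 * (1.0 - gam);
      pr1 = n1; pr0 = n0;
    }
    const std::vector<int>& vis = d.visIdx[j * d.nYears + t];
    for (size_t v = 0; v < vis.size(); ++v) {
      int k = vis[v];
      if (d.y(i, k)) { pr1 *= pdet[k]; pr0 = 0.0; }
      else           { pr1 *= 1.0 - pdet[k]; }
    }
    double s = pr1 + pr0;
    if (s <= 0.0 || !R_finite(s)) return R_NegInf;
    ll += std::log(s);
    pr1 /= s; pr0 /= s;
  }
  return ll;
}

static void detect_probs(const OccData& d, const Params& p, int i,
                         std::vector<double>& pdet) {
  for (int k = 0; k < d.nVisits; ++k)
    pdet[k] = invlogit(p.b4[i] + p.b5[i] * d.vShort[k] +
                       p.b6[i] * d.vLong[k] + p.alpha[d.vYear[k]]);
}

static double species_ll(const OccData& d, const Params& p, int i,
                         std::vector<double>& pdet) {
  detect_probs(d, p, i, pdet);
  double ll = 0.0;
  for (int j = 0; j < d.nSites; ++j) {
    ll += site_ll(d, p, i, j, pdet);
    if (ll == R_NegInf) return R_NegInf;
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector cpp_species_logliks(IntegerMatrix y, IntegerVector vSite,
    IntegerVector vYear, IntegerVector vShort, IntegerVector vLong,
    NumericMatrix Xosr, NumericMatrix Xneo, NumericMatrix Xfii,
    int nSites, int nYears, List par) {
  OccData d(y, vSite, vYear, vShort, vLong, Xosr, Xneo, Xfii,
            nSites, nYears);
  Params p;
  p.n = d.nSpecies; p.T = nYears;
  p.psi0l = as<std::vector<double> >(par["psi0l"]);
  p.lgam = as<std::vector<double> >(par["lgam"]);
  p.b0 = as<std::vector<double> >(par["b0"]);
  p.b1 = as<std::vector<double> >(par["b1"]);
  p.b2 = as<std::vector<double> >(par["b2"]);
  p.b3 = as<std::vector<double> >(par["b3"]);
  p.b4 = as<std::vector<double> >(par["b4"]);
  p.b5 = as<std::vector<double> >(par["b5"]);
  p.b6 = as<std::vector<double> >(par["b6"]);
  p.alpha = as<std::vector<double> >(par["alpha"]);
  NumericVector out(d.nSpecies);
  std::vector<double> pdet(d.nVisits);
  for (int i = 0; i < d.nSpecies; ++i)
    out[i] = species_ll(d, p, i, pdet);
  return out;
}

// ---- cached likelihood for the sampler ----------------------------
//
// The expensive pieces of the species likelihood are the logistic
// transforms. Persistence phi[j,t] only changes when beta0..beta3
// move, and detection probabilities take one of 3 (list class) x T
// (year) values per species, so both are cached and refreshed only
// for the parameter block being proposed.

struct SpCache {
  double psi0, gam;
  std::vector<double> phi;   // J*(T-1), phi[j + J*(t-1)]
  std::vector<double> pdet;  // 3*T, pdet[class + 3*t]
};

static void fill_phi(const OccData& d, double b0, double b1, double b2,
                     double b3, std::vector<double>& phi) {
  int J = d.nSites, T = d.nYears;
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < J; ++j)
      phi[j + J * (t - 1)] =
        invlogit(b0 + b1 * d.Xosr(j, t - 1) + b2 * d.Xneo(j, t - 1) +
                 b3 * d.Xfii(j, t - 1));
}

static void fill_pdet(int T, double b4, double b5, double b6,
                      const std::vector<double>& alpha,
                      std::vector<double>& pdet) {
  for (int t = 0; t < T; ++t) {
    pdet[0 + 3 * t] = invlogit(b4 + alpha[t]);
    pdet[1 + 3 * t] = invlogit(b4 + b5 + alpha[t]);
    pdet[2 + 3 * t] = invlogit(b4 + b6 + alpha[t]);
  }
}

static double site_ll_cached(const OccData& d, int i, int j,
                             double psi0, double gam,
                             const std::vector<double>& phi,
                             const std::vector<double>& pdet) {
  int J = d.nSites, T = d.nYears;
  const char* yi = &d.yT[(size_t)i * d.nVisits];
  double pr1 = psi0, pr0 = 1.0 - psi0, logScale = 0.0;
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      double ph = phi[j + J * (t - 1)];
      double n1 = pr1 * ph + pr0 * gam;
      double n0 = pr1 * (1.0 - ph) + pr0 * (1.0 - gam);
      pr1 = n1; pr0 = n0;
    }
    int s0 = d.visStart[j * T + t], s1 = d.visStart[j * T + t + 1];
    for (int v = s0; v < s1; ++v) {
      double pk = pdet[d.visFlatClass[v] + 3 * t];
      if (yi[d.visFlat[v]]) { pr1 *= pk; pr0 = 0.0; }
      else                  { pr1 *= 1.0 - pk; }
    }
    // lazy rescale: only normalise when the mass gets small
    double s = pr1 + pr0;
    if (s < 1e-280) {
      if (s <= 0.0 || !R_finite(s)) return R_NegInf;
      logScale += std::log(s);
      pr1 /= s; pr0 /= s;
    }
  }
  double s = pr1 + pr0;
  if (s <= 0.0 || !R_finite(s)) return R_NegInf;
  return logScale + std::log(s);
}

static double species_ll_cached(const OccData& d, int i, double psi0,
                                double gam,
                                const std::vector<double>& phi,
                                const std::vector<double>& pdet) {
  double ll = 0.0;
  for (int j = 0; j < d.nSites; ++j) {
    ll += site_ll_cached(d, i, j, psi0, gam, phi, pdet);
    if (ll == R_NegInf) return R_NegInf;
  }
  return ll;
}

// ---- priors -------------------------------------------------------

// logit-scale density of a Uniform(0,1) prior on the probability
static inline double lp_unif_logit(double l) {
  return -l - 2.0 * log1pe(-l);
}

static inline double lp_sd(double sd, int type, double scale) {
  // type 0 = half-Cauchy, 1 = half-normal (log density up to constant)
  if (type == 0) return -std::log1p((sd / scale) * (sd / scale));
  return -0.5 * (sd / scale) * (sd / scale);
}

struct PropSd {
  std::vector<double> s;      // log proposal sd per parameter
  std::vector<int> acc, tot;  // batch counters
  PropSd(int n, double init) : s(n, std::log(init)), acc(n, 0), tot(n, 0) {}
  void tally(int k, bool a) { tot[k]++; if (a) acc[k]++; }
  void adapt(int batch) {
    double delta = std::min(0.05, 1.0 / std::sqrt((double)batch));
    for (size_t k = 0; k < s.size(); ++k) {
      if (tot[k] == 0) continue;
      double rate = (double)acc[k] / tot[k];
      s[k] += (rate > 0.44 ? delta : -delta);
      acc[k] = 0; tot[k] = 0;
    }
  }
};

// species-level prior log density for parameter slot q of species i
static double species_lprior(const Params& p, int i, int q, double val,
                             int grp) {
  switch (q) {
  case 0: return lp_unif_logit(val);                       // psi0 logit
  case 1: return dnorm_log(val, p.mu_gam, p.sd_gam);       // lgam
  case 2: return dnorm_log(val, p.mu_b0, p.sd_b0);         // b0
  case 3: return dnorm_log(val, p.mu_cov[0][grp], p.sd_cov[0][grp]);
  case 4: return dnorm_log(val, p.mu_cov[1][grp], p.sd_cov[1][grp]);
  case 5: return dnorm_log(val, p.mu_cov[2][grp], p.sd_cov[2][grp]);
  case 6: return dnorm_log(val, p.mu_b4, p.sd_b4);
  case 7: return dnorm_log(val, p.mu_b5, p.sd_b5);
  case 8: return dnorm_log(val, p.mu_b6, p.sd_b6);
  }
  return 0.0;
}

static double* species_slot(Params& p, int i, int q) {
  switch (q) {
  case 0: return &p.psi0l[i];
  case 1: return &p.lgam[i];
  case 2: return &p.b0[i];
  case 3: return &p.b1[i];
  case 4: return &p.b2[i];
  case 5: return &p.b3[i];
  case 6: return &p.b4[i];
  case 7: return &p.b5[i];
  case 8: return &p.b6[i];
  }
  return 0;
}

// Gibbs draw for a normal hyper-mean given group values, N(0, priorSd^2)
static double gibbs_mu(const std::vector<double>& x,
                       const std::vector<int>& idx, double sd,
                       double priorSd) {
  double n = (double)idx.size(), sum = 0.0;
  for (size_t k = 0; k < idx.size(); ++k) sum += x[idx[k]];
  double prec = n / (sd * sd) + 1.0 / (priorSd * priorSd);
  double mean = (sum / (sd * sd)) / prec;
  return R::rnorm(mean, std::sqrt(1.0 / prec));
}

// random-walk update of a hyper-sd on the log scale
static double mh_sd(const std::vector<double>& x,
                    const std::vector<int>& idx, double mu, double sd,
                    int type, double scale, double step, bool* accepted) {
  double ls = std::log(sd);
  double lsNew = ls + R::rnorm(0.0, step);
  double sdNew = std::exp(lsNew);
  double cur = lp_sd(sd, type, scale) + ls;
  double prop = lp_sd(sdNew, type, scale) + lsNew;
  for (size_t k = 0; k < idx.size(); ++k) {
    cur += dnorm_log(x[idx[k]], mu, sd);
    prop += dnorm_log(x[idx[k]], mu, sdNew);
  }
  *accepted = std::log(R::runif(0.0, 1.0)) < prop - cur;
  return *accepted ? sdNew : sd;
}

// [[Rcpp::export]]
List cpp_occ_mcmc_chain(IntegerMatrix y, IntegerVector vSite,
    IntegerVector vYear, IntegerVector vShort, IntegerVector vLong,
    NumericMatrix Xosr, NumericMatrix Xneo, NumericMatrix Xfii,
    int nSites, int nYears, IntegerVector forager,
    int nIter, int nBurn, int nThin, List init, List priorCfg) {
  RNGScope scope;
  OccData d(y, vSite, vYear, vShort, vLong, Xosr, Xneo, Xfii,
            nSites, nYears);
  int n = d.nSpecies, T = nYears;

  Params p;
  p.n = n; p.T = T;
  p.psi0l = as<std::vector<double> >(init["psi0l"]);
  p.lgam = as<std::vector<double> >(init["lgam"]);
  p.b0 = as<std::vector<double> >(init["b0"]);
  p.b1 = as<std::vector<double> >(init["b1"]);
  p.b2 = as<std::vector<double> >(init["b2"]);
  p.b3 = as<std::vector<double> >(init["b3"]);
  p.b4 = as<std::vector<double> >(init["b4"]);
  p.b5 = as<std::vector<double> >(init["b5"]);
  p.b6 = as<std::vector<double> >(init["b6"]);
  p.alpha = as<std::vector<double> >(init["alpha"]);
  p.mu_gam = init["mu_gam"]; p.sd_gam = init["sd_gam"];
  p.mu_b0 = init["mu_b0"]; p.sd_b0 = init["sd_b0"];
  p.mu_b4 = init["mu_b4"]; p.sd_b4 = init["sd_b4"];
  p.mu_b5 = init["mu_b5"]; p.sd_b5 = init["sd_b5"];
  p.mu_b6 = init["mu_b6"]; p.sd_b6 = init["sd_b6"];
  p.sd_alpha = init["sd_alpha"];
  NumericMatrix muCov = init["mu_cov"], sdCov = init["sd_cov"]; // 3 x 2
  for (int c = 0; c < 3; ++c)
    for (int g = 0; g < 2; ++g) {
      p.mu_cov[c][g] = muCov(c, g);
      p.sd_cov[c][g] = sdCov(c, g);
    }

  double hmSd = priorCfg["hyperMeanSd"];
  int sdType = priorCfg["sdPriorType"]; // 0 half-Cauchy, 1 half-normal
  double sdScale = priorCfg["sdPriorScale"];

  std::vector<int> grpF, grpN, grpAll, alphaIdx;
  for (int i = 0; i < n; ++i) {
    grpAll.push_back(i);
    if (forager[i]) grpF.push_back(i); else grpN.push_back(i);
  }
  for (int t = 0; t < T; ++t) alphaIdx.push_back(t);

  // proposal scales: 9 species slots x n species, T alphas, 12 sds
  PropSd psSp(9 * n, 0.3), psAl(T, 0.15), psSd(12, 0.25);

  // per-species caches of the transformed quantities + log-likelihoods
  std::vector<SpCache> cache(n);
  std::vector<double> sll(n);
  for (int i = 0; i < n; ++i) {
    cache[i].psi0 = invlogit(p.psi0l[i]);
    cache[i].gam = invlogit(p.lgam[i]);
    cache[i].phi.resize(d.nSites * (T - 1));
    cache[i].pdet.resize(3 * T);
    fill_phi(d, p.b0[i], p.b1[i], p.b2[i], p.b3[i], cache[i].phi);
    fill_pdet(T, p.b4[i], p.b5[i], p.b6[i], p.alpha, cache[i].pdet);
    sll[i] = species_ll_cached(d, i, cache[i].psi0, cache[i].gam,
                               cache[i].phi, cache[i].pdet);
  }
  std::vector<double> phiProp(d.nSites * (T - 1)), pdetProp(3 * T);

  int nKeep = (nIter - nBurn) / nThin;
  int nPar = 9 * n + T + 10 + 12 + 1;
  NumericMatrix out(nKeep, nPar);
  int row = 0, batch = 0;
  long accSp = 0, totSp = 0, accAl = 0, totAl = 0;

  for (int it = 1; it <= nIter; ++it) {
    // --- species-level parameters, random-walk MH -------------------
    // the persistence covariate effects (slots 3..5) get a second
    // update pass per iteration: they are the inferential targets and
    // mix slowest (collinear covariates)
    static const int sweepOrder[12] = {0, 1, 2, 3, 4, 5, 6, 7, 8,
                                       3, 4, 5};
    for (int i = 0; i < n; ++i) {
      int grp = forager[i] ? 0 : 1;
      SpCache& c = cache[i];
      for (int qi = 0; qi < 12; ++qi) {
        int q = sweepOrder[qi];
        double* slot = species_slot(p, i, q);
        double old = *slot;
        double step = std::exp(psSp.s[q * n + i]);
        double prop = old + R::rnorm(0.0, step);
        double lpOld = sll[i] + species_lprior(p, i, q, old, grp);
        *slot = prop;
        // refresh only the cache block the proposal touches
        double psi0 = c.psi0, gam = c.gam;
        const std::vector<double>* phiUse = &c.phi;
        const std::vector<double>* pdetUse = &c.pdet;
        if (q == 0) psi0 = invlogit(prop);
        else if (q == 1) gam = invlogit(prop);
        else if (q >= 2 && q <= 5) {
          fill_phi(d, p.b0[i], p.b1[i], p.b2[i], p.b3[i], phiProp);
          phiUse = &phiProp;
        } else {
          fill_pdet(T, p.b4[i], p.b5[i], p.b6[i], p.alpha, pdetProp);
          pdetUse = &pdetProp;
        }
        double llNew = species_ll_cached(d, i, psi0, gam, *phiUse,
                                         *pdetUse);
        double lpNew = llNew + species_lprior(p, i, q, prop, grp);
        bool acc = std::log(R::runif(0.0, 1.0)) < lpNew - lpOld;
        if (acc) {
          sll[i] = llNew;
          c.psi0 = psi0; c.gam = gam;
          if (phiUse == &phiProp) c.phi.swap(phiProp);
          if (pdetUse == &pdetProp) c.pdet.swap(pdetProp);
        } else {
          *slot = old;
        }
        psSp.tally(q * n + i, acc);
        totSp++; if (acc) accSp++;
      }
    }
    // --- year effects ----------------------------------------------
    for (int t = 0; t < T; ++t) {
      double old = p.alpha[t];
      double step = std::exp(psAl.s[t]);
      double prop = old + R::rnorm(0.0, step);
      double lpOld = dnorm_log(old, 0.0, p.sd_alpha);
      double lpNew = dnorm_log(prop, 0.0, p.sd_alpha);
      std::vector<double> newll(n);
      p.alpha[t] = prop;
      double sumOld = 0.0, sumNew = 0.0;
      for (int i = 0; i < n; ++i) {
        // only the three detection values of year t change
        pdetProp = cache[i].pdet;
        pdetProp[0 + 3 * t] = invlogit(p.b4[i] + prop);
        pdetProp[1 + 3 * t] = invlogit(p.b4[i] + p.b5[i] + prop);
        pdetProp[2 + 3 * t] = invlogit(p.b4[i] + p.b6[i] + prop);
        newll[i] = species_ll_cached(d, i, cache[i].psi0, cache[i].gam,
                                     cache[i].phi, pdetProp);
        sumOld += sll[i]; sumNew += newll[i];
      }
      bool acc = std::log(R::runif(0.0, 1.0)) <
        (sumNew + lpNew) - (sumOld + lpOld);
      if (acc) {
        sll = newll;
        for (int i = 0; i < n; ++i) {
          cache[i].pdet[0 + 3 * t] = invlogit(p.b4[i] + prop);
          cache[i].pdet[1 + 3 * t] = invlogit(p.b4[i] + p.b5[i] + prop);
          cache[i].pdet[2 + 3 * t] = invlogit(p.b4[i] + p.b6[i] + prop);
        }
      } else {
        p.alpha[t] = old;
      }
      psAl.tally(t, acc);
      totAl++; if (acc) accAl++;
    }
    // --- sweep move on the alpha-level / detection-intercept ridge --
    // The likelihood only sees b4[i] + alpha[t], so the transformation
    // (alpha - m, b4 + m) leaves it invariant; m has a closed-form
    // normal conditional under the priors. Sampling it exactly breaks
    // the slow random-walk diffusion along this ridge.
    {
      double a2 = p.sd_alpha * p.sd_alpha;
      double b2v = p.sd_b4 * p.sd_b4;
      double sumA = 0.0, sumB = 0.0;
      for (int t = 0; t < T; ++t) sumA += p.alpha[t];
      for (int i = 0; i < n; ++i) sumB += p.b4[i] - p.mu_b4;
      double prec = T / a2 + n / b2v;
      double mean = (sumA / a2 - sumB / b2v) / prec;
      double m = R::rnorm(mean, std::sqrt(1.0 / prec));
      for (int t = 0; t < T; ++t) p.alpha[t] -= m;
      for (int i = 0; i < n; ++i) p.b4[i] += m;
      // refresh cached detection tables (probabilities are unchanged
      // in exact arithmetic; recompute to keep caches consistent)
      for (int i = 0; i < n; ++i) {
        fill_pdet(T, p.b4[i], p.b5[i], p.b6[i], p.alpha, cache[i].pdet);
        sll[i] = species_ll_cached(d, i, cache[i].psi0, cache[i].gam,
                                   cache[i].phi, cache[i].pdet);
      }
    }

    // --- hyper-parameters (no data likelihood involved) -------------
    bool a;
    p.mu_gam = gibbs_mu(p.lgam, grpAll, p.sd_gam, hmSd);
    p.sd_gam = mh_sd(p.lgam, grpAll, p.mu_gam, p.sd_gam, sdType, sdScale,
                     std::exp(psSd.s[0]), &a); psSd.tally(0, a);
    p.mu_b0 = gibbs_mu(p.b0, grpAll, p.sd_b0, hmSd);
    p.sd_b0 = mh_sd(p.b0, grpAll, p.mu_b0, p.sd_b0, sdType, sdScale,
                    std::exp(psSd.s[1]), &a); psSd.tally(1, a);
    p.mu_b4 = gibbs_mu(p.b4, grpAll, p.sd_b4, hmSd);
    p.sd_b4 = mh_sd(p.b4, grpAll, p.mu_b4, p.sd_b4, sdType, sdScale,
                    std::exp(psSd.s[2]), &a); psSd.tally(2, a);
    p.mu_b5 = gibbs_mu(p.b5, grpAll, p.sd_b5, hmSd);
    p.sd_b5 = mh_sd(p.b5, grpAll, p.mu_b5, p.sd_b5, sdType, sdScale,
                    std::exp(psSd.s[3]), &a); psSd.tally(3, a);
    p.mu_b6 = gibbs_mu(p.b6, grpAll, p.sd_b6, hmSd);
    p.sd_b6 = mh_sd(p.b6, grpAll, p.mu_b6, p.sd_b6, sdType, sdScale,
                    std::exp(psSd.s[4]), &a); psSd.tally(4, a);
    const std::vector<double>* covs[3] = { &p.b1, &p.b2, &p.b3 };
    for (int c = 0; c < 3; ++c) {
      for (int g = 0; g < 2; ++g) {
        const std::vector<int>& idx = g == 0 ? grpF : grpN;
        p.mu_cov[c][g] = gibbs_mu(*covs[c], idx, p.sd_cov[c][g], hmSd);
        p.sd_cov[c][g] = mh_sd(*covs[c], idx, p.mu_cov[c][g],
                               p.sd_cov[c][g], sdType, sdScale,
                               std::exp(psSd.s[5 + c * 2 + g]), &a);
        psSd.tally(5 + c * 2 + g, a);
      }
    }
    p.sd_alpha = mh_sd(p.alpha, alphaIdx, 0.0, p.sd_alpha, sdType, sdScale,
                       std::exp(psSd.s[11]), &a);
    psSd.tally(11, a);

    // --- adaptation during burn-in ----------------------------------
    if (it <= nBurn && it % 50 == 0) {
      batch++;
      psSp.adapt(batch); psAl.adapt(batch); psSd.adapt(batch);
    }

    // --- record ------------------------------------------------------
    if (it > nBurn && (it - nBurn) % nThin == 0) {
      int c0 = 0;
      for (int i = 0; i < n; ++i) {
        out(row, c0++) = invlogit(p.psi0l[i]);
        out(row, c0++) = invlogit(p.lgam[i]);
        out(row, c0++) = p.b0[i];
        out(row, c0++) = p.b1[i];
        out(row, c0++) = p.b2[i];
        out(row, c0++) = p.b3[i];
        out(row, c0++) = p.b4[i];
        out(row, c0++) = p.b5[i];
        out(row, c0++) = p.b6[i];
      }
      for (int t = 0; t < T; ++t) out(row, c0++) = p.alpha[t];
      out(row, c0++) = p.mu_gam; out(row, c0++) = p.sd_gam;
      out(row, c0++) = p.mu_b0;  out(row, c0++) = p.sd_b0;
      out(row, c0++) = p.mu_b4;  out(row, c0++) = p.sd_b4;
      out(row, c0++) = p.mu_b5;  out(row, c0++) = p.sd_b5;
      out(row, c0++) = p.mu_b6;  out(row, c0++) = p.sd_b6;
      for (int c = 0; c < 3; ++c)
        for (int g = 0; g < 2; ++g) {
          out(row, c0++) = p.mu_cov[c][g];
          out(row, c0++) = p.sd_cov[c][g];
        }
      out(row, c0++) = p.sd_alpha;
      row++;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["draws"] = out,
    _["acceptSpecies"] = (double)accSp / totSp,
    _["acceptAlpha"] = (double)accAl / totAl);
}
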