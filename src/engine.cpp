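// Microsimulation engine: colorectal adenoma-carcinoma natural history in
// quarterly time steps, with colonoscopy screening applied as an overlay on
// a precomputed cohort history.
//
// Design: a person's potential disease history (other-cause death time,
// every potential adenoma with its staged trajectory and malignant
// transformation time, every potential preclinical cancer with its staged
// course, symptomatic-detection time and pre-drawn fate uniforms) does not
// depend on the screening schedule -- screening only removes lesions or
// diagnoses them earlier. The history is therefore simulated once per
// (params, n, seed) and any schedule is evaluated against it cheaply. This
// gives exact common random numbers across arms (person-level pairing) and
// makes exhaustive schedule searches tractable.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <random>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const int MAXQ = 400;        // quarters 0..400 cover ages 0-100
static const int BIG = 1 << 29;     // "never happens" quarter
static const int NSEG = 8;          // cecum .. rectum
static const int N_ASTAGE = 6;      // adenoma stages
static const int N_CSTAGE = 4;      // carcinoma stages I-IV

// ---------------------------------------------------------------- RNG ----

// splitmix64: seed mixer for deterministic per-person substreams
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct MT {
  std::mt19937_64 g;
  explicit MT(uint64_t seed) : g(seed) {}
  double unif() {
    // 53-bit uniform in [0,1)
    return (g() >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    // Box-Muller (one value per call; simple and stream-stable)
    double u1 = unif(), u2 = unif();
    if (u1 <= 0) u1 = 5e-324;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

// Keyed counter-based draws for the screening overlay (splitmix64 mix of a
// per-person base and a purpose tag). Each draw is addressed by what it
// decides (which lesion, which exam, which complication type), not by its
// position in a sequential stream; schedules that differ by one age
// therefore reuse identical uniforms for corresponding decisions. This is
// common random numbers across schedules as well as across arms, and it is
// what makes brute-force landscapes smooth enough to locate flat optima.
struct KeyRNG {
  uint64_t base;
  explicit KeyRNG(uint64_t b) : base(b) {}
  double u(uint64_t tag) const {
    return (splitmix64(base ^ (tag * 0x9e3779b97f4a7c15ULL + 0xd1b54a32d192ed03ULL)) >> 11) *
           (1.0 / 9007199254740992.0);
  }
};

// draw-purpose tags (exam index e, lesion index j, type k)
static inline uint64_t tag_adherence(int invitation) { return 0x100000ULL + invitation; }
static inline uint64_t tag_attend_flag() { return 0x200000ULL; }
static inline uint64_t tag_reach(int e, int b) { return 0x300000ULL + 8ULL * e + b; }
static inline uint64_t tag_det_adenoma(int e, int j) { return 0x400000ULL + 4096ULL * e + j; }
static inline uint64_t tag_det_cancer(int e, int j) { return 0x500000ULL + 4096ULL * e + j; }
static inline uint64_t tag_compl(int e, int k, int which) {
  return 0x600000ULL + 64ULL * e + 2ULL * k + which;
}

// quarters until a geometric event with per-quarter probability e (>=1)
static inline int geom1(MT& r, double e) {
  if (e <= 0.0) return BIG;
  if (e >= 1.0) return 1;
  double u = r.unif();
  if (u <= 0) u = 5e-324;
  double s = std::floor(std::log(u) / std::log1p(-e));
  if (s > BIG) return BIG;
  return 1 + (int)s;
}

static inline int sample_cdf(MT& r, const std::vector<double>& cdf) {
  double u = r.unif();
  return (int)(std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
}

// ----------------------------------------------------------- history -----

struct Adenoma {
  int32_t init_q;
  int32_t stage_q[N_ASTAGE]; // quarter of entry into stage s+1 (BIG if never)
  int32_t transform_q;       // quarter of malignant transformation (BIG)
  int32_t cancer;            // index into cancers, -1 if none
  int16_t loc;
};

struct Cancer {
  int32_t onset_q;
  int32_t stage_q[N_CSTAGE]; // entry quarter per carcinoma stage (BIG)
  int32_t sympt_q;           // symptomatic detection quarter (BIG)
  int16_t sympt_stage;
  int16_t onset_stage;
  int16_t origin;            // 0 adenoma pathway, 1 direct path
  int16_t loc;
  int32_t adenoma;           // parent adenoma index, -1 for direct path
  double u_death, u_time;    // fate uniforms (shared across arms)
};

struct Person {
  int32_t t_oc;              // other-cause death quarter (dies end of t_oc)
  int32_t ad_b, ad_e, ca_b, ca_e;
  float risk;
  int8_t sex;                // 0 male, 1 female
};

struct History {
  int n;
  uint64_t seed;
  std::vector<Person> ppl;
  std::vector<Adenoma> ads;
  std::vector<Cancer> cas;
};

// natural-history parameters, tabulated per quarter where age-dependent
struct NHP {
  std::vector<double> init_rate[2];   // per-quarter adenoma hazard by sex
  std::vector<double> direct_rate[2]; // per-quarter direct-path hazard
  std::vector<double> loc_cdf, direct_loc_cdf, onset_stage_cdf, death_cdf;
  double prog_p[N_ASTAGE], cancer_p[N_ASTAGE];
  double pre_prog[N_CSTAGE], sympt_p[N_CSTAGE];
  double surv5[N_CSTAGE];
  double risk_sdlog;
  int adv_start;              // first advanced adenoma stage (1-based)
  int survival_anchor_dx;     // 0 = initiation-anchored window, 1 = diagnosis
};

static std::vector<double> as_vec(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}

static NHP parse_nhp(List p) {
  NHP o;
  o.init_rate[0] = as_vec(p["init_rate_m"]);
  o.init_rate[1] = as_vec(p["init_rate_f"]);
  o.direct_rate[0] = as_vec(p["direct_rate_m"]);
  o.direct_rate[1] = as_vec(p["direct_rate_f"]);
  o.loc_cdf = as_vec(p["loc_cdf"]);
  o.direct_loc_cdf = as_vec(p["direct_loc_cdf"]);
  o.onset_stage_cdf = as_vec(p["onset_stage_cdf"]);
  o.death_cdf = as_vec(p["death_time_cdf"]);
  NumericVector pp = p["prog_p"], cp = p["cancer_p"], qp = p["pre_prog"],
                sp = p["sympt_p"], sv = p["surv5"];
  for (int s = 0; s < N_ASTAGE; ++s) { o.prog_p[s] = pp[s]; o.cancer_p[s] = cp[s]; }
  for (int s = 0; s < N_CSTAGE; ++s) { o.pre_prog[s] = qp[s]; o.sympt_p[s] = sp[s]; o.surv5[s] = sv[s]; }
  o.risk_sdlog = as<double>(p["risk_sdlog"]);
  o.adv_start = as<int>(p["adv_start"]);
  o.survival_anchor_dx = as<int>(p["survival_anchor_dx"]);
  return o;
}

// staged preclinical course of one cancer, in place
static void grow_cancer(MT& r, const NHP& P, Cancer& c) {
  for (int s = 0; s < N_CSTAGE; ++s) c.stage_q[s] = BIG;
  c.sympt_q = BIG; c.sympt_stage = -1;
  int q = c.onset_q;
  int s = c.onset_stage;
  c.stage_q[s] = c.onset_q;
  while (true) {
    double d = P.sympt_p[s];
    double pr = (s < N_CSTAGE - 1) ? P.pre_prog[s] : 0.0;
    double e = d + (1.0 - d) * pr;
    int soj = geom1(r, e);
    if (soj >= BIG || q + soj > MAXQ) break;
    q += soj;
    if (e > 0 && r.unif() < d / e) { c.sympt_q = q; c.sympt_stage = (int16_t)s; break; }
    ++s;
    c.stage_q[s] = q;
  }
  c.u_death = r.unif();
  c.u_time = r.unif();
}

// [[Rcpp::export]]
SEXP cpp_simulate_history(List params, NumericVector life_cdf_m,
                          NumericVector life_cdf_f, int n,
                          double frac_male, double seed) {
  NHP P = parse_nhp(params);
  History* H = new History();
  H->n = n;
  H->seed = (uint64_t)seed;
  H->ppl.resize(n);
  H->ads.reserve((size_t)(n * 1.3) + 16);
  H->cas.reserve((size_t)(n * 0.15) + 16);
  std::vector<double> cdf[2] = {
    std::vector<double>(life_cdf_m.begin(), life_cdf_m.end()),
    std::vector<double>(life_cdf_f.begin(), life_cdf_f.end())
  };
  MT r(splitmix64(H->seed));
  for (int i = 0; i < n; ++i) {
    Person& pe = H->ppl[i];
    pe.sex = (r.unif() < frac_male) ? 0 : 1;
    pe.risk = (P.risk_sdlog > 0)
      ? (float)std::exp(r.norm() * P.risk_sdlog - 0.5 * P.risk_sdlog * P.risk_sdlog)
      : 1.0f;
    pe.t_oc = sample_cdf(r, cdf[pe.sex]);
    pe.ad_b = (int32_t)H->ads.size();
    pe.ca_b = (int32_t)H->cas.size();
    const std::vector<double>& ir = P.init_rate[pe.sex];
    const std::vector<double>& dr = P.direct_rate[pe.sex];
    int tmax = std::min(pe.t_oc, MAXQ);
    for (int t = 0; t < tmax; ++t) {
      // the individual risk multiplier acts on adenoma initiation only;
      // the direct path is not adenoma-mediated
      double ha = ir[t] * pe.risk;
      double hd = dr[t];
      if (ha <= 0 && hd <= 0) continue;
      double u = r.unif();
      if (u < ha) {
        Adenoma a;
        a.init_q = t;
        a.loc = (int16_t)sample_cdf(r, P.loc_cdf);
        a.transform_q = BIG;
        a.cancer = -1;
        for (int s = 0; s < N_ASTAGE; ++s) a.stage_q[s] = BIG;
        a.stage_q[0] = t;
        int q = t, s = 0;
        while (true) {
          double c = P.cancer_p[s];
          double pr = (s < N_ASTAGE - 1) ? P.prog_p[s] : 0.0;
          double e = c + (1.0 - c) * pr;
          int soj = geom1(r, e);
          if (soj >= BIG || q + soj > MAXQ) break;
          q += soj;
          if (e > 0 && r.unif() < c / e) {
            a.transform_q = q;
            Cancer ca;
            ca.onset_q = q; ca.onset_stage = 0; ca.origin = 0;
            ca.loc = a.loc; ca.adenoma = (int32_t)H->ads.size();
            grow_cancer(r, P, ca);
            a.cancer = (int32_t)H->cas.size();
            H->cas.push_back(ca);
            break;
          }
          ++s;
          a.stage_q[s] = q;
        }
        H->ads.push_back(a);
      } else if (u < ha + hd) {
        Cancer ca;
        ca.onset_q = t;
        ca.onset_stage = (int16_t)sample_cdf(r, P.onset_stage_cdf);
        ca.origin = 1;
        ca.loc = (int16_t)sample_cdf(r, P.direct_loc_cdf);
        ca.adenoma = -1;
        grow_cancer(r, P, ca);
        H->cas.push_back(ca);
      }
    }
    pe.ad_e = (int32_t)H->ads.size();
    pe.ca_e = (int32_t)H->cas.size();
  }
  XPtr<History> ptr(H, true);
  ptr.attr("class") = "crc_history";
  ptr.attr("n") = n;
  return ptr;
}

// ------------------------------------------------------ screening model --

struct Colo {
  double reach[3];            // pass splenic flexure, hepatic flexure, cecum
  double sens_ad[N_ASTAGE];
  double sens_cancer;
  double compl_prob[3];       // perforation, bleeding, serosa burn
  double compl_polyp_mult;
  double compl_fatal[3];
  double adherence;
  int adherence_per_person;   // 0 per invitation, 1 per person
};

struct Guide {
  double int_early;           // years, 1-2 early adenomas
  double int_adv;             // years, >=3 adenomas or any advanced
  double stop_age;            // years
};

struct Costs {
  double colonoscopy, polypectomy, compl_cost[3];
  double treat[N_CSTAGE][3];  // per quarter: initial, followup, terminal
  double death_unrelated;
};

static Colo parse_colo(List p) {
  Colo c;
  NumericVector re = p["reach"], sa = p["sens_adenoma"], cp = p["compl_prob"],
                cf = p["compl_fatal"];
  for (int i = 0; i < 3; ++i) { c.reach[i] = re[i]; c.compl_prob[i] = cp[i]; c.compl_fatal[i] = cf[i]; }
  for (int s = 0; s < N_ASTAGE; ++s) c.sens_ad[s] = sa[s];
  c.sens_cancer = as<double>(p["sens_cancer"]);
  c.compl_polyp_mult = as<double>(p["compl_polyp_mult"]);
  c.adherence = as<double>(p["adherence"]);
  c.adherence_per_person = as<int>(p["adherence_per_person"]);
  return c;
}

static Guide parse_guide(List p) {
  Guide g;
  g.int_early = as<double>(p["interval_early"]);
  g.int_adv = as<double>(p["interval_advanced"]);
  g.stop_age = as<double>(p["stop_age"]);
  return g;
}

static Costs parse_costs(List p) {
  Costs c;
  c.colonoscopy = as<double>(p["colonoscopy_cost"]);
  c.polypectomy = as<double>(p["polypectomy_surcharge"]);
  NumericVector cc = p["complication_cost"];
  for (int i = 0; i < 3; ++i) c.compl_cost[i] = cc[i];
  NumericMatrix tr = p["treatment_cost"]; // 4 x 3 (stage x period)
  for (int s = 0; s < N_CSTAGE; ++s)
    for (int j = 0; j < 3; ++j) c.treat[s][j] = tr(s, j);
  c.death_unrelated = as<double>(p["death_unrelated_terminal_cost"]);
  return c;
}

// segment visible given reach level (number of passed boundaries 0..3)
static inline bool seg_visible(int seg, int level) {
  if (seg >= 5) return true;            // descending, sigmoid, rectum
  if (seg >= 3) return level >= 1;      // transverse, splenic flexure
  if (seg >= 1) return level >= 2;      // ascending, hepatic flexure
  return level >= 3;                    // cecum
}

static inline int stage_at(const int32_t* stage_q, int nst, int q) {
  int s = 0;
  for (int j = 1; j < nst; ++j) if (stage_q[j] <= q) s = j;
  return s;
}

enum Cause { C_OTHER = 0, C_CRC = 1, C_COMPL = 2 };

// per-arm accumulators
struct Acc {
  double cases = 0, crc_deaths = 0, compl_deaths = 0;
  double colos_screen = 0, colos_surv = 0, colos_diag = 0;
  double invitations = 0, polypectomies = 0, complications = 0;
  double adenomas_removed = 0;
  double life_years = 0, disc_life_years = 0, lyl = 0, disc_lyl = 0;
  double cost = 0, disc_cost = 0;
};

static const int N_OUT = 16;
static const char* OUT_NAMES[N_OUT] = {
  "cases", "crc_deaths", "compl_deaths", "colos_screen", "colos_surv",
  "colos_diag", "invitations", "polypectomies", "complications",
  "adenomas_removed", "life_years", "disc_life_years", "lyl", "disc_lyl",
  "cost", "disc_cost"
};

struct PersonOut {
  int death_q, cause, dx_q, dx_stage, n_screen, n_surv, n_diag, n_polyp;
  double cost, disc_cost;
};

// evaluate one arm (schedule possibly empty) for one person
static void eval_person(const History& H, int i, const NHP& P, const Colo& C,
                        const Guide& G, const Costs& K,
                        const std::vector<int>& sched_q, uint64_t screen_seed,
                        const std::vector<double>& ly_pre,   // length MAXQ+2
                        const std::vector<double>& dly_pre,  // length MAXQ+2
                        const std::vector<double>& df,       // length MAXQ+1
                        Acc& A, PersonOut* po,
                        std::vector<uint8_t>& ad_removed,
                        std::vector<uint8_t>& ca_cancelled) {
  const Person& pe = H.ppl[i];
  KeyRNG r(splitmix64(screen_seed ^ splitmix64((uint64_t)i + 0x51ab1ULL)));
  int nad = pe.ad_e - pe.ad_b, nca = pe.ca_e - pe.ca_b;
  if ((int)ad_removed.size() < nad) ad_removed.resize(nad);
  if ((int)ca_cancelled.size() < nca) ca_cancelled.resize(nca);
  std::fill(ad_removed.begin(), ad_removed.begin() + nad, 0);
  std::fill(ca_cancelled.begin(), ca_cancelled.begin() + nca, 0);

  int attend_flag = -1;             // per-person adherence mode cache
  int exam_n = 0;                   // performed-colonoscopy counter
  int invitation_n = 0;             // screening-invitation counter
  size_t si = 0;                    // next screening invitation
  int surveillance_q = BIG;
  bool in_treatment = false;
  int dx_q = BIG, dx_stage = -1, crc_death_q = BIG, compl_death_q = BIG;
  int n_screen = 0, n_surv = 0, n_diag = 0, n_polyp = 0;
  double cost = 0, dcost = 0;
  int cur = 0;

  // schedule CRC death for a cancer diagnosed at quarter q with stage s
  auto set_crc_death = [&](const Cancer& ca, int q, int s) {
    dx_q = q; dx_stage = s;
    if (ca.u_death < 1.0 - P.surv5[s]) {
      int off = 1 + (int)(std::lower_bound(P.death_cdf.begin(), P.death_cdf.end(),
                                           ca.u_time) - P.death_cdf.begin());
      int anchor = P.survival_anchor_dx ? q : ca.onset_q;
      int dqq = anchor + off;
      if (dqq < q) dqq = q;                    // death cannot precede diagnosis
      if (dqq <= anchor + 20 && dqq < crc_death_q) crc_death_q = dqq;
      // otherwise the 5-year death window has closed: the person survives
    }
  };

  // one colonoscopy; returns true if person should stop screening
  auto colonoscopy = [&](int cq, int type /*0 screen 1 surv 2 diag*/,
                         const Cancer* sympt_ca) -> bool {
    if (type == 0) ++n_screen; else if (type == 1) ++n_surv; else ++n_diag;
    int e = exam_n++;
    cost += K.colonoscopy;
    dcost += K.colonoscopy * df[cq];
    int level = 0;
    for (int b = 0; b < 3; ++b) {
      if (r.u(tag_reach(e, b)) < C.reach[b]) ++level; else break;
    }
    int n_early_det = 0, n_adv_det = 0;
    bool polyp = false;
    for (int a = 0; a < nad; ++a) {
      if (ad_removed[a]) continue;
      const Adenoma& ad = H.ads[pe.ad_b + a];
      if (ad.init_q > cq || ad.transform_q <= cq) continue;
      if (!seg_visible(ad.loc, level)) continue;
      int s = stage_at(ad.stage_q, N_ASTAGE, cq);
      if (r.u(tag_det_adenoma(e, a)) < C.sens_ad[s]) {
        ad_removed[a] = 1;
        if (ad.cancer >= 0) ca_cancelled[ad.cancer - pe.ca_b] = 1;
        polyp = true;
        ++n_polyp;
        A.adenomas_removed += 1;
        if (s + 1 >= P.adv_start) ++n_adv_det; else ++n_early_det;
      }
    }
    bool cancer_found = false;
    int found_stage = -1;
    const Cancer* found = nullptr;
    if (sympt_ca) {
      cancer_found = true;
      found = sympt_ca;
      found_stage = sympt_ca->sympt_stage;
    } else {
      for (int c = 0; c < nca && !cancer_found; ++c) {
        if (ca_cancelled[c]) continue;
        const Cancer& ca = H.cas[pe.ca_b + c];
        if (ca.onset_q > cq) continue;
        if (!seg_visible(ca.loc, level)) continue;
        if (r.u(tag_det_cancer(e, c)) < C.sens_cancer) {
          cancer_found = true;
          found = &ca;
          found_stage = stage_at(ca.stage_q, N_CSTAGE, cq);
        }
      }
    }
    if (polyp) {
      cost += K.polypectomy;
      dcost += K.polypectomy * df[cq];
    }
    double mult = polyp ? C.compl_polyp_mult : 1.0;
    for (int k = 0; k < 3; ++k) {
      double pc = std::min(1.0, C.compl_prob[k] * mult);
      if (pc > 0 && r.u(tag_compl(e, k, 0)) < pc) {
        A.complications += 1;
        cost += K.compl_cost[k];
        dcost += K.compl_cost[k] * df[cq];
        if (r.u(tag_compl(e, k, 1)) < C.compl_fatal[k])
          compl_death_q = std::min(compl_death_q, cq);
      }
    }
    if (cancer_found) {
      set_crc_death(*found, cq, found_stage);
      in_treatment = true;
      return true;
    }
    if (compl_death_q < BIG) return true;
    // surveillance decision
    double age = cq / 4.0;
    if (age < G.stop_age && (n_adv_det > 0 || n_early_det + n_adv_det >= 3)) {
      surveillance_q = cq + (int)std::lround(G.int_adv * 4);
    } else if (age < G.stop_age && n_early_det > 0) {
      surveillance_q = cq + (int)std::lround(G.int_early * 4);
    } else {
      surveillance_q = BIG;  // resume screening
    }
    return false;
  };

  while (!in_treatment && compl_death_q == BIG) {
    // earliest pending symptomatic diagnosis among live cancers
    int sy_q = BIG;
    const Cancer* sy = nullptr;
    for (int c = 0; c < nca; ++c) {
      if (ca_cancelled[c]) continue;
      const Cancer& ca = H.cas[pe.ca_b + c];
      if (ca.sympt_q >= cur && ca.sympt_q < sy_q) { sy_q = ca.sympt_q; sy = &ca; }
    }
    // next colonoscopy invitation: surveillance overrides screening
    int co_q = BIG, co_type = -1;
    if (surveillance_q < BIG) {
      co_q = surveillance_q;
      co_type = 1;
      while (si < sched_q.size() && sched_q[si] <= co_q) ++si;
    } else {
      while (si < sched_q.size() && sched_q[si] < cur) ++si;
      if (si < sched_q.size()) { co_q = sched_q[si]; co_type = 0; }
    }
    int ev = std::min(sy_q, co_q);
    if (ev >= BIG || ev > pe.t_oc) break;      // dies of other causes
    if (co_q <= ev && co_type >= 0 && co_q <= sy_q) {
      // colonoscopy first on ties: prevention precedes symptomatic workup
      cur = co_q;
      bool attend = true;
      if (co_type == 0) {
        A.invitations += 1;
        ++si;
        int inv = invitation_n++;
        if (C.adherence_per_person) {
          if (attend_flag < 0)
            attend_flag = (r.u(tag_attend_flag()) < C.adherence) ? 1 : 0;
          attend = attend_flag == 1;
        } else {
          attend = r.u(tag_adherence(inv)) < C.adherence;
        }
      } else {
        surveillance_q = BIG;
      }
      if (attend) {
        if (colonoscopy(co_q, co_type, nullptr)) break;
      }
      if (co_type == 0 && surveillance_q == BIG) cur = co_q; // continue from here
    } else {
      // symptomatic diagnosis: diagnostic colonoscopy, always attended
      cur = sy_q;
      colonoscopy(sy_q, 2, sy);
      break;
    }
  }

  int death_q = pe.t_oc;
  int cause = C_OTHER;
  if (crc_death_q <= death_q) { death_q = crc_death_q; cause = C_CRC; }
  if (compl_death_q < death_q || (compl_death_q == death_q && cause == C_OTHER)) {
    death_q = compl_death_q; cause = C_COMPL;
  }
  bool is_case = dx_q <= death_q && dx_q < BIG;

  // treatment costs: quarterly, one category per quarter, terminal (last 12
  // months before CRC death) > initial (first 12 months) > follow-up;
  // nothing beyond 5 years after diagnosis
  if (is_case) {
    int last = std::min(death_q, dx_q + 19);
    for (int j = dx_q; j <= last; ++j) {
      int cat;
      if (cause == C_CRC && j >= death_q - 3) cat = 2;
      else if (j <= dx_q + 3) cat = 0;
      else cat = 1;
      double amt = K.treat[dx_stage][cat];
      cost += amt;
      dcost += amt * df[j];
    }
    if (cause != C_CRC) {
      cost += K.death_unrelated;
      dcost += K.death_unrelated * df[death_q];
    }
  }

  A.cases += is_case;
  A.crc_deaths += cause == C_CRC;
  A.compl_deaths += cause == C_COMPL;
  A.colos_screen += n_screen;
  A.colos_surv += n_surv;
  A.colos_diag += n_diag;
  A.polypectomies += n_polyp;
  A.life_years += (death_q + 1) * 0.25;
  A.disc_life_years += ly_pre.empty() ? 0 : dly_pre[death_q + 1];
  A.lyl += (pe.t_oc - death_q) * 0.25;
  A.disc_lyl += dly_pre[pe.t_oc + 1] - dly_pre[death_q + 1];
  A.cost += cost;
  A.disc_cost += dcost;

  if (po) {
    po->death_q = death_q; po->cause = cause;
    po->dx_q = is_case ? dx_q : NA_INTEGER;
    po->dx_stage = is_case ? dx_stage + 1 : NA_INTEGER;
    po->n_screen = n_screen; po->n_surv = n_surv; po->n_diag = n_diag;
    po->n_polyp = n_polyp; po->cost = cost; po->disc_cost = dcost;
  }
}

// discount prefix tables from an annual rate anchored at anchor_age; the
// factor is clamped at 1 before the anchor (flows before age 20 are not
// inflated)
static void discount_tables(double rate, double anchor,
                            std::vector<double>& dly_pre,
                            std::vector<double>& df) {
  df.assign(MAXQ + 1, 1.0);
  dly_pre.assign(MAXQ + 2, 0.0);
  for (int t = 0; t <= MAXQ; ++t) {
    double age = t / 4.0 + 0.125;
    double f = (rate > 0 && age > anchor) ? std::pow(1.0 + rate, -(age - anchor)) : 1.0;
    df[t] = f;
    dly_pre[t + 1] = dly_pre[t] + 0.25 * f;
  }
}

static std::vector<int> sched_to_quarters(NumericVector ages) {
  std::vector<int> q;
  for (double a : ages) if (!NumericVector::is_na(a)) q.push_back((int)std::lround(a * 4));
  std::sort(q.begin(), q.end());
  return q;
}

// [[Rcpp::export]]
NumericMatrix cpp_eval_schedules(SEXP hist, List nh_params, List colo_params,
                                 List guideline, List cost_params,
                                 NumericMatrix schedules, double screen_seed,
                                 double discount_rate, double anchor_age) {
  XPtr<History> H(hist);
  NHP P = parse_nhp(nh_params);
  Colo C = parse_colo(colo_params);
  Guide G = parse_guide(guideline);
  Costs K = parse_costs(cost_params);
  std::vector<double> dly_pre, df;
  discount_tables(discount_rate, anchor_age, dly_pre, df);
  int ns = schedules.nrow();
  NumericMatrix out(ns, N_OUT);
  std::vector<uint8_t> adr, cac;
  for (int s = 0; s < ns; ++s) {
    NumericVector row = schedules(s, _);
    std::vector<int> sq = sched_to_quarters(row);
    Acc A;
    for (int i = 0; i < H->n; ++i) {
      eval_person(*H, i, P, C, G, K, sq, (uint64_t)screen_seed,
                  dly_pre, dly_pre, df, A, nullptr, adr, cac);
    }
    double* o = &out(s, 0);
    double vals[N_OUT] = {
      A.cases, A.crc_deaths, A.compl_deaths, A.colos_screen, A.colos_surv,
      A.colos_diag, A.invitations, A.polypectomies, A.complications,
      A.adenomas_removed, A.life_years, A.disc_life_years, A.lyl, A.disc_lyl,
      A.cost, A.disc_cost
    };
    for (int j = 0; j < N_OUT; ++j) out(s, j) = vals[j];
    (void)o;
  }
  colnames(out) = CharacterVector(OUT_NAMES, OUT_NAMES + N_OUT);
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_eval_persons(SEXP hist, List nh_params, List colo_params,
                           List guideline, List cost_params,
                           NumericVector schedule, double screen_seed,
                           double discount_rate, double anchor_age) {
  XPtr<History> H(hist);
  NHP P = parse_nhp(nh_params);
  Colo C = parse_colo(colo_params);
  Guide G = parse_guide(guideline);
  Costs K = parse_costs(cost_params);
  std::vector<double> dly_pre, df;
  discount_tables(discount_rate, anchor_age, dly_pre, df);
  std::vector<int> sq = sched_to_quarters(schedule);
  int n = H->n;
  IntegerVector id(n), sex(n), t_oc(n), death_q(n), cause(n), dx_q(n),
      dx_stage(n), n_screen(n), n_surv(n), n_diag(n), n_polyp(n),
      n_adenomas(n), n_cancers(n);
  NumericVector risk(n), cost(n), dcost(n);
  std::vector<uint8_t> adr, cac;
  Acc A;
  for (int i = 0; i < n; ++i) {
    PersonOut po;
    eval_person(*H, i, P, C, G, K, sq, (uint64_t)screen_seed,
                dly_pre, dly_pre, df, A, &po, adr, cac);
    const Person& pe = H->ppl[i];
    id[i] = i + 1;
    sex[i] = pe.sex;
    risk[i] = pe.risk;
    t_oc[i] = pe.t_oc;
    n_adenomas[i] = pe.ad_e - pe.ad_b;
    n_cancers[i] = pe.ca_e - pe.ca_b;
    death_q[i] = po.death_q;
    cause[i] = po.cause;
    dx_q[i] = po.dx_q;
    dx_stage[i] = po.dx_stage;
    n_screen[i] = po.n_screen;
    n_surv[i] = po.n_surv;
    n_diag[i] = po.n_diag;
    n_polyp[i] = po.n_polyp;
    cost[i] = po.cost;
    dcost[i] = po.disc_cost;
  }
  return DataFrame::create(
    _["id"] = id, _["sex"] = sex, _["risk_multiplier"] = risk,
    _["other_cause_death_q"] = t_oc, _["death_q"] = death_q,
    _["cause"] = cause, _["dx_q"] = dx_q, _["dx_stage"] = dx_stage,
    _["n_adenomas"] = n_adenomas, _["n_cancers"] = n_cancers,
    _["colos_screening"] = n_screen, _["colos_surveillance"] = n_surv,
    _["colos_diagnostic"] = n_diag, _["polypectomies"] = n_polyp,
    _["cost"] = cost, _["disc_cost"] = dcost);
}

// cross-sectional benchmarks from a no-screening pass: per sex and age band,
// early/advanced adenoma prevalence at the band midpoint among persons alive
// and undiagnosed, and CRC incidence per 100,000 person-years in the band
// [[Rcpp::export]]
DataFrame cpp_benchmarks(SEXP hist, List nh_params, NumericVector band_starts,
                         double band_width) {
  XPtr<History> H(hist);
  NHP P = parse_nhp(nh_params);
  int nb = band_starts.size();
  // baseline (no screening) death and diagnosis per person
  int n = H->n;
  std::vector<int> death_q(n), dxq(n);
  for (int i = 0; i < n; ++i) {
    const Person& pe = H->ppl[i];
    int dq = BIG, dstage = -1, donset = 0;
    double ud = 0, ut = 0;
    for (int c = pe.ca_b; c < pe.ca_e; ++c) {
      const Cancer& ca = H->cas[c];
      if (ca.sympt_q < dq) {
        dq = ca.sympt_q; dstage = ca.sympt_stage; donset = ca.onset_q;
        ud = ca.u_death; ut = ca.u_time;
      }
    }
    int dthq = pe.t_oc;
    if (dq <= pe.t_oc && dstage >= 0 && ud < 1.0 - P.surv5[dstage]) {
      int off = 1 + (int)(std::lower_bound(P.death_cdf.begin(), P.death_cdf.end(), ut)
                          - P.death_cdf.begin());
      int anchor = P.survival_anchor_dx ? dq : donset;
      int cdq = anchor + off;
      if (cdq < dq) cdq = dq;
      if (cdq <= anchor + 20 && cdq < dthq) dthq = cdq;
    }
    death_q[i] = dthq;
    dxq[i] = (dq <= dthq) ? dq : BIG;
  }
  int rows = 2 * nb;
  IntegerVector sex(rows), band(rows), alive_n(rows), cases(rows);
  NumericVector early(rows), adv(rows), inc(rows), py(rows);
  for (int b = 0; b < nb; ++b) {
    int q0 = (int)std::lround(band_starts[b] * 4);
    int q1 = (int)std::lround((band_starts[b] + band_width) * 4);
    int mid = (q0 + q1) / 2;
    double aliveN[2] = {0, 0}, earlyN[2] = {0, 0}, advN[2] = {0, 0};
    double pyrs[2] = {0, 0}, cs[2] = {0, 0};
    for (int i = 0; i < n; ++i) {
      const Person& pe = H->ppl[i];
      int sx = pe.sex;
      if (death_q[i] >= mid && dxq[i] > mid) {
        aliveN[sx] += 1;
        bool any_adv = false, any_early = false;
        for (int a = pe.ad_b; a < pe.ad_e; ++a) {
          const Adenoma& ad = H->ads[a];
          if (ad.init_q <= mid && ad.transform_q > mid) {
            int s = stage_at(ad.stage_q, N_ASTAGE, mid);
            if (s + 1 >= P.adv_start) any_adv = true; else any_early = true;
          }
        }
        if (any_adv) advN[sx] += 1;
        else if (any_early) earlyN[sx] += 1;
      }
      // person-years at risk (alive, undiagnosed) and incident diagnoses
      int from = q0, to = std::min({q1 - 1, death_q[i], dxq[i]});
      if (to >= from) pyrs[sx] += (to - from + 1) * 0.25;
      if (dxq[i] >= q0 && dxq[i] < q1 && dxq[i] <= death_q[i]) cs[sx] += 1;
    }
    for (int sx = 0; sx < 2; ++sx) {
      int rr = sx * nb + b;
      sex[rr] = sx;
      band[rr] = (int)band_starts[b];
      alive_n[rr] = (int)aliveN[sx];
      cases[rr] = (int)cs[sx];
      early[rr] = aliveN[sx] > 0 ? earlyN[sx] / aliveN[sx] : 0.0;
      adv[rr] = aliveN[sx] > 0 ? advN[sx] / aliveN[sx] : 0.0;
      py[rr] = pyrs[sx];
      inc[rr] = pyrs[sx] > 0 ? cs[sx] / pyrs[sx] * 1e5 : 0.0;
    }
  }
  return DataFrame::create(
    _["sex"] = sex, _["age_band_start"] = band, _["n_alive_mid"] = alive_n,
    _["early_adenoma_prev"] = early, _["advanced_adenoma_prev"] = adv,
    _["crc_cases"] = cases, _["person_years"] = py,
    _["crc_incidence_per_100k"] = inc);
}

// summary of a raw history (for tests and inspection)
// [[Rcpp::export]]
List cpp_history_summary(SEXP hist) {
  XPtr<History> H(hist);
  double mean_risk = 0, mean_toc = 0;
  int n = H->n;
  for (int i = 0; i < n; ++i) {
    mean_risk += H->ppl[i].risk;
    mean_toc += H->ppl[i].t_oc;
  }
  return List::create(
    _["n"] = n, _["n_adenomas"] = (double)H->ads.size(),
    _["n_potential_cancers"] = (double)H->cas.size(),
    _["mean_risk_multiplier"] = mean_risk / n,
    _["mean_other_cause_death_q"] = mean_toc / n);
}

// per-person natural-history table (potential histories, pre-screening)
// [[Rcpp::export]]
DataFrame cpp_history_persons(SEXP hist) {
  XPtr<History> H(hist);
  int n = H->n;
  IntegerVector id(n), sex(n), t_oc(n), nad(n), nca(n);
  NumericVector risk(n);
  for (int i = 0; i < n; ++i) {
    const Person& pe = H->ppl[i];
    id[i] = i + 1; sex[i] = pe.sex; risk[i] = pe.risk; t_oc[i] = pe.t_oc;
    nad[i] = pe.ad_e - pe.ad_b; nca[i] = pe.ca_e - pe.ca_b;
  }
  return DataFrame::create(_["id"] = id, _["sex"] = sex,
                           _["risk_multiplier"] = risk,
                           _["other_cause_death_q"] = t_oc,
                           _["n_adenomas"] = nad, _["n_potential_cancers"] = nca);
}

// lesion-level table (for oracle tests on small cohorts)
// [[Rcpp::export]]
List cpp_history_lesions(SEXP hist) {
  XPtr<History> H(hist);
  int na = (int)H->ads.size(), nc = (int)H->cas.size();
  IntegerVector a_init(na), a_loc(na), a_transform(na), a_cancer(na);
  IntegerMatrix a_stage(na, N_ASTAGE);
  for (int a = 0; a < na; ++a) {
    const Adenoma& ad = H->ads[a];
    a_init[a] = ad.init_q; a_loc[a] = ad.loc;
    a_transform[a] = ad.transform_q >= BIG ? NA_INTEGER : ad.transform_q;
    a_cancer[a] = ad.cancer < 0 ? NA_INTEGER : ad.cancer + 1;
    for (int s = 0; s < N_ASTAGE; ++s)
      a_stage(a, s) = ad.stage_q[s] >= BIG ? NA_INTEGER : ad.stage_q[s];
  }
  IntegerVector c_onset(nc), c_stage0(nc), c_origin(nc), c_loc(nc), c_sympt(nc),
      c_sympt_stage(nc);
  NumericVector c_udeath(nc), c_utime(nc);
  IntegerMatrix c_stage(nc, N_CSTAGE);
  for (int c = 0; c < nc; ++c) {
    const Cancer& ca = H->cas[c];
    c_onset[c] = ca.onset_q; c_stage0[c] = ca.onset_stage + 1;
    c_origin[c] = ca.origin; c_loc[c] = ca.loc;
    c_sympt[c] = ca.sympt_q >= BIG ? NA_INTEGER : ca.sympt_q;
    c_sympt_stage[c] = ca.sympt_stage < 0 ? NA_INTEGER : ca.sympt_stage + 1;
    c_udeath[c] = ca.u_death; c_utime[c] = ca.u_time;
    for (int s = 0; s < N_CSTAGE; ++s)
      c_stage(c, s) = ca.stage_q[s] >= BIG ? NA_INTEGER : ca.stage_q[s];
  }
  // person index for each lesion
  IntegerVector a_person(na), c_person(nc);
  for (int i = 0; i < H->n; ++i) {
    const Person& pe = H->ppl[i];
    for (int a = pe.ad_b; a < pe.ad_e; ++a) a_person[a] = i + 1;
    for (int c = pe.ca_b; c < pe.ca_e; ++c) c_person[c] = i + 1;
  }
  return List::create(
    _["adenomas"] = DataFrame::create(
      _["person"] = a_person, _["init_q"] = a_init, _["location"] = a_loc,
      _["transform_q"] = a_transform, _["cancer"] = a_cancer,
      _["stage_entry_q"] = a_stage),
    _["cancers"] = DataFrame::create(
      _["person"] = c_person, _["onset_q"] = c_onset,
      _["onset_stage"] = c_stage0, _["origin"] = c_origin, _["location"] = c_loc,
      _["sympt_q"] = c_sympt, _["sympt_stage"] = c_sympt_stage,
      _["u_death"] = c_udeath, _["u_time"] = c_utime,
      _["stage_entry_q"] = c_stage));
}
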