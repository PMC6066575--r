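// Agent-based engine: juvenile play, maturation under the adult cap,
// foraging, pooling among fair adults, threshold/delay reproduction,
// lifespan mortality with dependent offspring, and group fission.
//
// All randomness is drawn from R's RNG (unif_rand / norm_rand) so that
// set.seed() at the R level makes every run bit-for-bit reproducible.
// The order in which draws are consumed is fixed and documented phase by
// phase; changing it is a breaking change for stored seeds.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
#include <set>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

struct Params {
  int K, G, f, g, j, alpha, d, tau, burn_in;
  int n_init_groups, n_init_per_group;
  double P, T, r, l, sd_l, R, sd_R, p, c, F0;
  double res_lo, res_hi;
  int age_lo, age_hi;
  bool learn_fairness, seed_adults_fair;
};

Params as_params(const List& x) {
  Params pr;
  pr.K = as<int>(x["K"]);
  pr.G = as<int>(x["G"]);
  pr.f = as<int>(x["f"]);
  pr.g = as<int>(x["g"]);
  pr.j = as<int>(x["j"]);
  pr.alpha = as<int>(x["alpha"]);
  pr.d = as<int>(x["d"]);
  pr.tau = as<int>(x["tau"]);
  pr.burn_in = as<int>(x["burn_in"]);
  pr.n_init_groups = as<int>(x["n_init_groups"]);
  pr.n_init_per_group = as<int>(x["n_init_per_group"]);
  pr.P = as<double>(x["P"]);
  pr.T = as<double>(x["T"]);
  pr.r = as<double>(x["r"]);
  pr.l = as<double>(x["l"]);
  pr.sd_l = as<double>(x["sd_l"]);
  pr.R = as<double>(x["R"]);
  pr.sd_R = as<double>(x["sd_R"]);
  pr.p = as<double>(x["p"]);
  pr.c = as<double>(x["c"]);
  pr.F0 = as<double>(x["F0"]);
  NumericVector rr = x["init_resource_range"];
  pr.res_lo = rr[0];
  pr.res_hi = rr[1];
  IntegerVector ar = x["init_age_range"];
  pr.age_lo = ar[0];
  pr.age_hi = ar[1];
  pr.learn_fairness = as<bool>(x["learn_fairness"]);
  pr.seed_adults_fair = as<bool>(x["seed_adults_fair"]);
  return pr;
}

struct Agent {
  int id, group, birth_step, age, lifespan, bouts, last_repro, parent;
  double resources;
  bool gene, adult, fair, played_step, played_ever, alive;
};

enum Cause { CAUSE_PLAY = 1, CAUSE_LIFESPAN = 2, CAUSE_CAP = 3, CAUSE_PARENT = 4 };

struct Pop {
  std::vector<Agent> a;
  int step, next_id, next_group;
  long long births_total, births_gene, play_deaths, played_juveniles,
      cap_deaths, lifespan_deaths, parent_deaths, fissions;
  std::vector<int> blog_step, blog_gene;
  std::vector<int> dlog_step, dlog_cause;
};

struct Counts {
  int births = 0, bouts = 0, play_deaths = 0, matured = 0, cap_deaths = 0,
      lifespan_deaths = 0, parent_deaths = 0, fissions = 0;
  double foraged_total = 0.0, credited_total = 0.0;
};

// uniform integer on [0, n)
inline int rint(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Fisher-Yates shuffle driven by R's RNG
void shuffle_vec(std::vector<int>& v) {
  for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
    int k = rint(i + 1);
    std::swap(v[i], v[k]);
  }
}

// lifespan = round(l + N(0, sd_l)), clamped below at 1
inline int draw_lifespan(const Params& pr) {
  double x = pr.l + norm_rand() * pr.sd_l;
  int ls = static_cast<int>(std::lround(x));
  return ls < 1 ? 1 : ls;
}

void kill(Pop& pop, Agent& ag, int cause, Counts* ct) {
  ag.alive = false;
  pop.dlog_step.push_back(pop.step);
  pop.dlog_cause.push_back(cause);
  switch (cause) {
    case CAUSE_PLAY:
      pop.play_deaths++;
      if (ct) ct->play_deaths++;
      break;
    case CAUSE_LIFESPAN:
      pop.lifespan_deaths++;
      if (ct) ct->lifespan_deaths++;
      break;
    case CAUSE_CAP:
      pop.cap_deaths++;
      if (ct) ct->cap_deaths++;
      break;
    case CAUSE_PARENT:
      pop.parent_deaths++;
      if (ct) ct->parent_deaths++;
      break;
  }
}

// per-group member indices, groups returned in ascending id order so the
// RNG consumption order is well defined
typedef std::vector<std::pair<int, std::vector<int>>> GroupIndex;

GroupIndex members_by_group(const Pop& pop, bool adults, bool juveniles) {
  std::unordered_map<int, std::vector<int>> m;
  m.reserve(64);
  for (size_t i = 0; i < pop.a.size(); ++i) {
    const Agent& ag = pop.a[i];
    if (!ag.alive) continue;
    if ((ag.adult && adults) || (!ag.adult && juveniles))
      m[ag.group].push_back(static_cast<int>(i));
  }
  GroupIndex out(m.begin(), m.end());
  std::sort(out.begin(), out.end(),
            [](const GroupIndex::value_type& a, const GroupIndex::value_type& b) {
              return a.first < b.first;
            });
  return out;
}

void compact(Pop& pop) {
  pop.a.erase(std::remove_if(pop.a.begin(), pop.a.end(),
                             [](const Agent& x) { return !x.alive; }),
              pop.a.end());
}

// Draw order per initial agent: resources, age, gene, lifespan.
Pop init_pop(const Params& pr) {
  Pop pop;
  pop.step = 0;
  pop.next_id = 0;
  pop.next_group = pr.n_init_groups;
  pop.births_total = pop.births_gene = pop.play_deaths = 0;
  pop.played_juveniles = pop.cap_deaths = pop.lifespan_deaths = 0;
  pop.parent_deaths = pop.fissions = 0;
  pop.a.reserve(pr.n_init_groups * pr.n_init_per_group * 2);
  for (int gi = 0; gi < pr.n_init_groups; ++gi) {
    for (int k = 0; k < pr.n_init_per_group; ++k) {
      Agent ag{};
      ag.id = pop.next_id++;
      ag.group = gi;
      ag.resources = pr.res_lo + unif_rand() * (pr.res_hi - pr.res_lo);
      ag.age = pr.age_lo + rint(pr.age_hi - pr.age_lo + 1);
      ag.gene = unif_rand() < pr.F0;
      ag.lifespan = draw_lifespan(pr);
      ag.birth_step = -ag.age;
      ag.adult = ag.age >= pr.j;
      // seed adults had no juvenile phase; treat gene carriers as already
      // fair when learning is enabled (configurable via seed_adults_fair)
      ag.fair = ag.adult && ag.gene && pr.learn_fairness && pr.seed_adults_fair;
      ag.bouts = 0;
      ag.played_step = false;
      ag.played_ever = false;
      ag.last_repro = -pr.d;  // eligible to reproduce at step 0
      ag.parent = -1;
      ag.alive = true;
      pop.a.push_back(ag);
    }
  }
  return pop;
}

void bout_mark(Pop& pop, Agent& ag) {
  ag.bouts++;
  ag.played_step = true;
  if (!ag.played_ever) {
    ag.played_ever = true;
    pop.played_juveniles++;
  }
}

// Phase 1: juvenile play. Gene-on juveniles, in random order within each
// group, each attempt at most one bout; partner search scans the group's
// other juveniles in uniformly random order and stops at the first that has
// the gene and has not yet played this step. Both participants gain a bout
// and each independently dies with probability c.
void phase_play(Pop& pop, const Params& pr, Counts& ct) {
  for (auto& ag : pop.a)
    if (ag.alive && !ag.adult) ag.played_step = false;
  auto juv = members_by_group(pop, false, true);
  for (auto& kv : juv) {
    std::vector<int>& js = kv.second;
    if (js.size() < 2) continue;
    std::vector<int> initiators;
    for (int i : js)
      if (pop.a[i].gene) initiators.push_back(i);
    if (initiators.size() < 2) continue;  // no possible pairing
    shuffle_vec(initiators);
    for (int ii : initiators) {
      {
        const Agent& J = pop.a[ii];
        if (!J.alive || J.played_step) continue;
      }
      std::vector<int> others;
      others.reserve(js.size() - 1);
      for (int o : js)
        if (o != ii) others.push_back(o);
      // lazy Fisher-Yates: visit candidates in uniformly random order but
      // stop at the first willing partner (same distribution as a full
      // shuffle followed by a scan, with far fewer RNG draws)
      int partner = -1;
      int n_others = static_cast<int>(others.size());
      for (int pos = 0; pos < n_others; ++pos) {
        int k = pos + rint(n_others - pos);
        std::swap(others[pos], others[k]);
        const Agent& Q = pop.a[others[pos]];
        if (Q.alive && Q.gene && !Q.played_step) {
          partner = others[pos];
          break;
        }
      }
      if (partner < 0) continue;
      ct.bouts++;
      bout_mark(pop, pop.a[ii]);
      bout_mark(pop, pop.a[partner]);
      if (unif_rand() < pr.c) kill(pop, pop.a[ii], CAUSE_PLAY, &ct);
      if (unif_rand() < pr.c) kill(pop, pop.a[partner], CAUSE_PLAY, &ct);
    }
  }
}

// Phase 2: maturation. Juveniles at or past age j, in random order across
// the whole population, become adults while the adult count is below K;
// otherwise they die (cap). Fairness is learned at maturation.
void phase_mature(Pop& pop, const Params& pr, Counts& ct) {
  int adults = 0;
  for (auto& ag : pop.a)
    if (ag.alive && ag.adult) adults++;
  std::vector<int> cand;
  for (size_t i = 0; i < pop.a.size(); ++i) {
    const Agent& ag = pop.a[i];
    if (ag.alive && !ag.adult && ag.age >= pr.j) cand.push_back(static_cast<int>(i));
  }
  if (cand.empty()) return;
  shuffle_vec(cand);
  for (int i : cand) {
    Agent& ag = pop.a[i];
    if (adults < pr.K) {
      ag.adult = true;
      ag.fair = pr.learn_fairness && ag.gene && ag.bouts >= pr.alpha;
      adults++;
      ct.matured++;
    } else {
      kill(pop, ag, CAUSE_CAP, &ct);
    }
  }
}

// Phases 3+4: adult foraging, then pooling and equal division of the
// CURRENT step's gains among the fair adults of each group. Selfish adults
// keep their own gains. Per-agent draw order follows agent index order
// within each group (groups in ascending id order).
void phase_forage_pool(Pop& pop, const Params& pr, Counts& ct) {
  auto ad = members_by_group(pop, true, false);
  for (auto& kv : ad) {
    std::vector<int>& as_ = kv.second;
    std::vector<double> gain(as_.size(), 0.0);
    double pool = 0.0;
    int m = 0;
    for (size_t i = 0; i < as_.size(); ++i) {
      if (unif_rand() < pr.p) {
        double x = pr.R + norm_rand() * pr.sd_R;
        gain[i] = x < 0 ? 0 : x;  // clamp guard; needs a -10 sigma deviate
      }
      ct.foraged_total += gain[i];
      if (pop.a[as_[i]].fair) {
        pool += gain[i];
        m++;
      }
    }
    double share = m > 0 ? pool / m : 0.0;
    for (size_t i = 0; i < as_.size(); ++i) {
      Agent& ag = pop.a[as_[i]];
      double credit = ag.fair ? share : gain[i];
      ag.resources += credit;
      ct.credited_total += credit;
    }
  }
}

// Create one offspring of the (living adult) parent at index pi.
// Draw order: mutation flip, then lifespan.
void spawn(Pop& pop, const Params& pr, size_t pi, Counts* ct) {
  Agent& par = pop.a[pi];
  bool gene = par.gene;
  if (unif_rand() < pr.r) gene = !gene;
  Agent ch{};
  ch.id = pop.next_id++;
  ch.group = par.group;
  ch.gene = gene;
  ch.adult = false;
  ch.fair = false;
  ch.birth_step = pop.step;
  ch.age = 0;
  ch.lifespan = draw_lifespan(pr);
  ch.resources = pr.P * par.resources;
  ch.bouts = 0;
  ch.played_step = false;
  ch.played_ever = false;
  ch.last_repro = pop.step - pr.d;  // no delay carried into adulthood
  ch.parent = par.id;
  ch.alive = true;
  par.resources *= (1.0 - pr.P);
  par.last_repro = pop.step;
  pop.a.push_back(ch);  // invalidates `par`
  pop.blog_step.push_back(pop.step);
  pop.blog_gene.push_back(gene ? 1 : 0);
  pop.births_total++;
  if (gene) pop.births_gene++;
  if (ct) ct->births++;
}

// Phase 5: reproduction. Each living adult (in index order) produces at most
// one offspring iff resources >= T and at least d steps have passed since
// its last reproduction.
void phase_reproduce(Pop& pop, const Params& pr, Counts& ct) {
  size_t n0 = pop.a.size();
  for (size_t i = 0; i < n0; ++i) {
    const Agent& ag = pop.a[i];
    if (!ag.alive || !ag.adult) continue;
    if (ag.resources >= pr.T && (pop.step - ag.last_repro) >= pr.d)
      spawn(pop, pr, i, &ct);
  }
}

// Phase 6: aging and lifespan deaths. Agents that have reached their
// lifespan die (so an agent at age lifespan - 1 survives this step and dies
// on the next); survivors then age by one step. Juvenile offspring of
// adults that die of lifespan die with them (dependent removal).
void phase_age(Pop& pop, const Params& pr, Counts& ct) {
  (void)pr;
  std::unordered_set<int> dead_parents;
  for (auto& ag : pop.a) {
    if (ag.alive && ag.age >= ag.lifespan) {
      bool was_adult = ag.adult;
      kill(pop, ag, CAUSE_LIFESPAN, &ct);
      if (was_adult) dead_parents.insert(ag.id);
    }
  }
  for (auto& ag : pop.a)
    if (ag.alive) ag.age++;
  if (!dead_parents.empty()) {
    for (auto& ag : pop.a) {
      if (ag.alive && !ag.adult && ag.parent >= 0 &&
          dead_parents.count(ag.parent))
        kill(pop, ag, CAUSE_PARENT, &ct);
    }
  }
}

// Phase 7: group fission. Each group with >= f adults, while the group count
// is below G, buds off a new group of g adults sampled uniformly without
// replacement; moved adults take their dependent juveniles along.
void phase_fission(Pop& pop, const Params& pr, Counts& ct) {
  // cheap first pass: adult counts per group, total group count, and
  // whether any group has reached the fission size
  std::unordered_map<int, int> adult_n;
  adult_n.reserve(64);
  std::unordered_set<int> groups;
  groups.reserve(64);
  bool any_at_f = false;
  for (const auto& ag : pop.a) {
    if (!ag.alive) continue;
    groups.insert(ag.group);
    if (ag.adult && ++adult_n[ag.group] >= pr.f) any_at_f = true;
  }
  int gcount = static_cast<int>(groups.size());
  if (!any_at_f || gcount >= pr.G) return;
  GroupIndex ad = members_by_group(pop, true, false);
  for (auto& kv : ad) {
    if (static_cast<int>(kv.second.size()) >= pr.f && gcount < pr.G) {
      std::vector<int> pick = kv.second;
      shuffle_vec(pick);
      int ng = pop.next_group++;
      std::unordered_set<int> moved;
      for (int i = 0; i < pr.g; ++i) {
        pop.a[pick[i]].group = ng;
        moved.insert(pop.a[pick[i]].id);
      }
      for (auto& ag : pop.a)
        if (ag.alive && !ag.adult && ag.parent >= 0 && moved.count(ag.parent))
          ag.group = ng;
      gcount++;
      ct.fissions++;
      pop.fissions++;
    }
  }
}

Counts do_step(Pop& pop, const Params& pr) {
  Counts ct;
  phase_play(pop, pr, ct);
  phase_mature(pop, pr, ct);
  phase_forage_pool(pop, pr, ct);
  phase_reproduce(pop, pr, ct);
  phase_age(pop, pr, ct);
  phase_fission(pop, pr, ct);
  compact(pop);
  return ct;
}

// ---- conversions ----------------------------------------------------------

List pop_to_list(const Pop& pop) {
  size_t n = pop.a.size();
  IntegerVector id(n), group(n), birth_step(n), age(n), lifespan(n), bouts(n),
      last_repro(n), parent(n);
  NumericVector resources(n);
  LogicalVector gene(n), adult(n), fair(n), played_step(n), played_ever(n);
  for (size_t i = 0; i < n; ++i) {
    const Agent& ag = pop.a[i];
    id[i] = ag.id;
    group[i] = ag.group;
    birth_step[i] = ag.birth_step;
    age[i] = ag.age;
    lifespan[i] = ag.lifespan;
    bouts[i] = ag.bouts;
    last_repro[i] = ag.last_repro;
    parent[i] = ag.parent < 0 ? NA_INTEGER : ag.parent;
    resources[i] = ag.resources;
    gene[i] = ag.gene;
    adult[i] = ag.adult;
    fair[i] = ag.fair;
    played_step[i] = ag.played_step;
    played_ever[i] = ag.played_ever;
  }
  DataFrame agents = DataFrame::create(
      Named("id") = id, Named("group_id") = group, Named("play_gene") = gene,
      Named("adult") = adult, Named("birth_step") = birth_step,
      Named("age") = age, Named("lifespan") = lifespan,
      Named("resources") = resources, Named("bouts_played") = bouts,
      Named("is_fair") = fair, Named("played_step") = played_step,
      Named("played_ever") = played_ever,
      Named("last_repro_step") = last_repro, Named("parent_id") = parent);
  List counters = List::create(
      Named("births_total") = static_cast<double>(pop.births_total),
      Named("births_gene") = static_cast<double>(pop.births_gene),
      Named("play_deaths") = static_cast<double>(pop.play_deaths),
      Named("played_juveniles") = static_cast<double>(pop.played_juveniles),
      Named("cap_deaths") = static_cast<double>(pop.cap_deaths),
      Named("lifespan_deaths") = static_cast<double>(pop.lifespan_deaths),
      Named("parent_deaths") = static_cast<double>(pop.parent_deaths),
      Named("fissions") = static_cast<double>(pop.fissions));
  DataFrame blog =
      DataFrame::create(Named("step") = IntegerVector(pop.blog_step.begin(),
                                                      pop.blog_step.end()),
                        Named("gene") = IntegerVector(pop.blog_gene.begin(),
                                                      pop.blog_gene.end()));
  DataFrame dlog =
      DataFrame::create(Named("step") = IntegerVector(pop.dlog_step.begin(),
                                                      pop.dlog_step.end()),
                        Named("cause") = IntegerVector(pop.dlog_cause.begin(),
                                                       pop.dlog_cause.end()));
  List out = List::create(
      Named("agents") = agents, Named("step") = pop.step,
      Named("next_id") = pop.next_id, Named("next_group_id") = pop.next_group,
      Named("counters") = counters, Named("birth_log") = blog,
      Named("death_log") = dlog);
  out.attr("class") = "fairplay_pop";
  return out;
}

Pop pop_from_list(const List& x) {
  Pop pop;
  DataFrame agents = as<DataFrame>(x["agents"]);
  IntegerVector id = agents["id"], group = agents["group_id"],
                birth_step = agents["birth_step"], age = agents["age"],
                lifespan = agents["lifespan"], bouts = agents["bouts_played"],
                last_repro = agents["last_repro_step"],
                parent = agents["parent_id"];
  NumericVector resources = agents["resources"];
  LogicalVector gene = agents["play_gene"], adult = agents["adult"],
                fair = agents["is_fair"], played_step = agents["played_step"],
                played_ever = agents["played_ever"];
  size_t n = id.size();
  pop.a.resize(n);
  for (size_t i = 0; i < n; ++i) {
    Agent& ag = pop.a[i];
    ag.id = id[i];
    ag.group = group[i];
    ag.birth_step = birth_step[i];
    ag.age = age[i];
    ag.lifespan = lifespan[i];
    ag.bouts = bouts[i];
    ag.last_repro = last_repro[i];
    ag.parent = parent[i] == NA_INTEGER ? -1 : parent[i];
    ag.resources = resources[i];
    ag.gene = gene[i];
    ag.adult = adult[i];
    ag.fair = fair[i];
    ag.played_step = played_step[i];
    ag.played_ever = played_ever[i];
    ag.alive = true;
  }
  pop.step = as<int>(x["step"]);
  pop.next_id = as<int>(x["next_id"]);
  pop.next_group = as<int>(x["next_group_id"]);
  List ctr = x["counters"];
  pop.births_total = static_cast<long long>(as<double>(ctr["births_total"]));
  pop.births_gene = static_cast<long long>(as<double>(ctr["births_gene"]));
  pop.play_deaths = static_cast<long long>(as<double>(ctr["play_deaths"]));
  pop.played_juveniles =
      static_cast<long long>(as<double>(ctr["played_juveniles"]));
  pop.cap_deaths = static_cast<long long>(as<double>(ctr["cap_deaths"]));
  pop.lifespan_deaths =
      static_cast<long long>(as<double>(ctr["lifespan_deaths"]));
  pop.parent_deaths = static_cast<long long>(as<double>(ctr["parent_deaths"]));
  pop.fissions = static_cast<long long>(as<double>(ctr["fissions"]));
  DataFrame blog = as<DataFrame>(x["birth_log"]);
  IntegerVector bs = blog["step"], bg = blog["gene"];
  pop.blog_step.assign(bs.begin(), bs.end());
  pop.blog_gene.assign(bg.begin(), bg.end());
  DataFrame dlog = as<DataFrame>(x["death_log"]);
  IntegerVector ds = dlog["step"], dc = dlog["cause"];
  pop.dlog_step.assign(ds.begin(), ds.end());
  pop.dlog_cause.assign(dc.begin(), dc.end());
  return pop;
}

NumericVector report_vec(const Pop& pop, const Counts& ct) {
  int adults = 0, alive = 0, geneon = 0;
  for (const auto& ag : pop.a) {
    if (!ag.alive) continue;
    alive++;
    if (ag.adult) adults++;
    if (ag.gene) geneon++;
  }
  NumericVector rep = NumericVector::create(
      Named("step") = pop.step, Named("births") = ct.births,
      Named("play_bouts") = ct.bouts, Named("play_deaths") = ct.play_deaths,
      Named("matured") = ct.matured, Named("cap_deaths") = ct.cap_deaths,
      Named("lifespan_deaths") = ct.lifespan_deaths,
      Named("parent_deaths") = ct.parent_deaths,
      Named("fissions") = ct.fissions, Named("adult_count") = adults,
      Named("living_count") = alive,
      Named("living_gene_frequency") =
          alive > 0 ? static_cast<double>(geneon) / alive : NA_REAL,
      Named("foraged_total") = ct.foraged_total,
      Named("credited_total") = ct.credited_total);
  return rep;
}

}  // namespace

// [[Rcpp::export]]
List cpp_init_population(List params) {
  Params pr = as_params(params);
  Pop pop = init_pop(pr);
  return pop_to_list(pop);
}

// [[Rcpp::export]]
List cpp_step(List pop_list, List params) {
  Params pr = as_params(params);
  Pop pop = pop_from_list(pop_list);
  Counts ct = do_step(pop, pr);
  NumericVector rep = report_vec(pop, ct);
  pop.step += 1;
  return List::create(Named("population") = pop_to_list(pop),
                      Named("report") = rep);
}

// [[Rcpp::export]]
List cpp_phase(List pop_list, List params, std::string phase) {
  Params pr = as_params(params);
  Pop pop = pop_from_list(pop_list);
  Counts ct;
  if (phase == "play")
    phase_play(pop, pr, ct);
  else if (phase == "mature")
    phase_mature(pop, pr, ct);
  else if (phase == "forage")
    phase_forage_pool(pop, pr, ct);
  else if (phase == "reproduce")
    phase_reproduce(pop, pr, ct);
  else if (phase == "age")
    phase_age(pop, pr, ct);
  else if (phase == "fission")
    phase_fission(pop, pr, ct);
  else
    stop("unknown phase: " + phase);
  compact(pop);
  NumericVector rep = report_vec(pop, ct);
  return List::create(Named("population") = pop_to_list(pop),
                      Named("report") = rep);
}

// [[Rcpp::export]]
List cpp_run(List params, bool record_trajectory) {
  Params pr = as_params(params);
  Pop pop = init_pop(pr);
  bool extinct = false;
  int ext_step = NA_INTEGER;
  NumericMatrix traj(record_trajectory ? pr.tau : 0, 14);
  int rows = 0;
  for (int s = 0; s < pr.tau; ++s) {
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
    pop.step = s;
    Counts ct = do_step(pop, pr);
    int adults = 0;
    for (const auto& ag : pop.a)
      if (ag.alive && ag.adult) adults++;
    if (record_trajectory) {
      NumericVector rep = report_vec(pop, ct);
      for (int cidx = 0; cidx < 14; ++cidx) traj(rows, cidx) = rep[cidx];
    }
    rows++;
    if (adults == 0) {
      extinct = true;
      ext_step = s;
      break;
    }
  }
  pop.step = rows;
  List out = List::create(Named("population") = pop_to_list(pop),
                          Named("extinct") = extinct,
                          Named("extinction_step") = ext_step,
                          Named("steps_run") = rows);
  if (record_trajectory) {
    NumericMatrix tr(rows, 14);
    for (int i = 0; i < rows; ++i)
      for (int cidx = 0; cidx < 14; ++cidx) tr(i, cidx) = traj(i, cidx);
    colnames(tr) = CharacterVector::create(
        "step", "births", "play_bouts", "play_deaths", "matured", "cap_deaths",
        "lifespan_deaths", "parent_deaths", "fissions", "adult_count",
        "living_count", "living_gene_frequency", "foraged_total",
        "credited_total");
    out["trajectory"] = tr;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_find_partner(List pop_list, int juvenile_id) {
  Pop pop = pop_from_list(pop_list);
  int idx = -1;
  for (size_t i = 0; i < pop.a.size(); ++i)
    if (pop.a[i].id == juvenile_id) idx = static_cast<int>(i);
  if (idx < 0) stop("no agent with that id");
  const Agent& J = pop.a[idx];
  if (J.adult) stop("agent is not a juvenile");
  std::vector<int> others;
  for (size_t i = 0; i < pop.a.size(); ++i) {
    const Agent& Q = pop.a[i];
    if (static_cast<int>(i) != idx && Q.alive && !Q.adult &&
        Q.group == J.group)
      others.push_back(static_cast<int>(i));
  }
  shuffle_vec(others);
  for (int o : others) {
    const Agent& Q = pop.a[o];
    if (Q.gene && !Q.played_step) return Q.id;
  }
  return NA_INTEGER;
}

// [[Rcpp::export]]
List cpp_spawn_offspring(List pop_list, List params, int parent_id) {
  Params pr = as_params(params);
  Pop pop = pop_from_list(pop_list);
  int idx = -1;
  for (size_t i = 0; i < pop.a.size(); ++i)
    if (pop.a[i].id == parent_id) idx = static_cast<int>(i);
  if (idx < 0) stop("no agent with that id");
  if (!pop.a[idx].adult) stop("parent is not an adult");
  spawn(pop, pr, idx, nullptr);
  return pop_to_list(pop);
}

// [[Rcpp::export]]
List cpp_remove_agent(List pop_list, int agent_id, std::string cause) {
  Pop pop = pop_from_list(pop_list);
  int code;
  if (cause == "play")
    code = CAUSE_PLAY;
  else if (cause == "lifespan")
    code = CAUSE_LIFESPAN;
  else if (cause == "cap")
    code = CAUSE_CAP;
  else if (cause == "parent_death")
    code = CAUSE_PARENT;
  else
    stop("unknown death cause: " + cause);
  int idx = -1;
  for (size_t i = 0; i < pop.a.size(); ++i)
    if (pop.a[i].id == agent_id) idx = static_cast<int>(i);
  if (idx < 0) stop("no agent with that id");
  bool dependent_removal = pop.a[idx].adult && code == CAUSE_LIFESPAN;
  kill(pop, pop.a[idx], code, nullptr);
  if (dependent_removal) {
    for (auto& ag : pop.a)
      if (ag.alive && !ag.adult && ag.parent == agent_id)
        kill(pop, ag, CAUSE_PARENT, nullptr);
  }
  compact(pop);
  return pop_to_list(pop);
}

// [[Rcpp::export]]
NumericVector cpp_forage(int n, double p, double R, double sdR) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (unif_rand() < p) {
      double x = R + norm_rand() * sdR;
      out[i] = x < 0 ? 0 : x;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_assign_lifespan(int n, double l, double sd) {
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = l + norm_rand() * sd;
    int ls = static_cast<int>(std::lround(x));
    out[i] = ls < 1 ? 1 : ls;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pool_credits(NumericVector gains, LogicalVector fair) {
  if (gains.size() != fair.size()) stop("gains and fair must match in length");
  double pool = 0.0;
  int m = 0;
  for (int i = 0; i < gains.size(); ++i) {
    if (fair[i]) {
      pool += gains[i];
      m++;
    }
  }
  double share = m > 0 ? pool / m : 0.0;
  NumericVector out(gains.size());
  for (int i = 0; i < gains.size(); ++i) out[i] = fair[i] ? share : gains[i];
  return out;
}
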