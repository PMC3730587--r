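#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gillespie birth-death simulation started from 2 lineages (the ancestor of
// a sister pair is by construction a bifurcation), run for t_sim time units.
// The extant-only (reconstructed) tree is rebuilt, every surviving internal
// node receives an exponential "lag to species recognition" with mean phi,
// and nodes younger than their lag are collapsed tipward-to-rootward. Ages
// of the cherries (nodes whose both daughters are recognized species) that
// survive the collapse are returned, pooled over n_trees replicates.
//
// Uses R's RNG so set.seed() in R gives reproducible (common random number)
// streams. A per-tree node cap guards against runaway growth at high
// lambda * t_sim; overrun is reported via the "overflow" flag so the caller
// can treat the parameter point as infeasible.

struct Lineage {
  int parent;
  double t_birth;
  double t_end;
  int child1, child2;  // -1 for none
  bool extant;         // alive at t_sim
};

// status codes for the lag-collapse pass
static const int ST_LEAF = 0;
static const int ST_INTERNAL = 1;

// Recursively resolve the reconstructed-tree descendant of lineage `i`,
// collapse young nodes, and append surviving cherry ages.
// Returns ST_LEAF if the subtree rooted at i is (after collapsing) a single
// recognized species, ST_INTERNAL otherwise, or -1 if no extant descendant.
static int resolve(const std::vector<Lineage>& lin,
                   const std::vector<char>& has_extant,
                   int i, double t_sim, double phi,
                   std::vector<double>& cherry_ages) {
  // walk down chains of splits where only one side survives
  while (true) {
    if (lin[i].child1 < 0) {             // terminal segment
      return lin[i].extant ? ST_LEAF : -1;
    }
    bool s1 = has_extant[lin[i].child1];
    bool s2 = has_extant[lin[i].child2];
    if (s1 && s2) break;                 // a reconstructed-tree node
    if (!s1 && !s2) return -1;
    i = s1 ? lin[i].child1 : lin[i].child2;
  }
  double age = t_sim - lin[i].t_end;
  int a = resolve(lin, has_extant, lin[i].child1, t_sim, phi, cherry_ages);
  int b = resolve(lin, has_extant, lin[i].child2, t_sim, phi, cherry_ages);
  // both sides have extant descendants by construction here
  if (a == ST_LEAF && b == ST_LEAF) {
    double lag = (phi > 0.0) ? R::rexp(phi) : 0.0;
    if (age < lag) return ST_LEAF;       // split not yet recognized
    cherry_ages.push_back(age);
    return ST_INTERNAL;
  }
  // an uncollapsible node (a recognized split survives below it); its own
  // lag is irrelevant because its daughters are not both single species
  return ST_INTERNAL;
}

// [[Rcpp::export(name = ".bd_cherry_ages")]]
List bd_cherry_ages(double lambda, double mu, double phi, double t_sim,
                    int n_trees, int max_nodes = 100000) {
  std::vector<double> ages;
  ages.reserve(1024);
  bool overflow = false;
  int n_surviving = 0;

  std::vector<Lineage> lin;
  std::vector<int> alive;
  std::vector<char> has_extant;

  for (int tree = 0; tree < n_trees && !overflow; ++tree) {
    lin.clear();
    alive.clear();
    Lineage root1 = {-1, 0.0, -1.0, -1, -1, false};
    Lineage root2 = {-1, 0.0, -1.0, -1, -1, false};
    lin.push_back(root1); lin.push_back(root2);
    alive.push_back(0); alive.push_back(1);

    double t = 0.0;
    while (!alive.empty()) {
      int n_alive = (int)alive.size();
      double total_rate = n_alive * (lambda + mu);
      t += R::rexp(1.0 / total_rate);
      if (t >= t_sim) break;
      int pick = (int)(unif_rand() * n_alive);
      if (pick >= n_alive) pick = n_alive - 1;
      int j = alive[pick];
      if (unif_rand() < lambda / (lambda + mu)) {   // speciation
        if ((int)lin.size() + 2 > max_nodes) { overflow = true; break; }
        lin[j].t_end = t;
        int c1 = (int)lin.size();
        Lineage ch = {j, t, -1.0, -1, -1, false};
        lin.push_back(ch); lin.push_back(ch);
        lin[j].child1 = c1; lin[j].child2 = c1 + 1;
        alive[pick] = c1;
        alive.push_back(c1 + 1);
      } else {                                      // extinction
        lin[j].t_end = t;
        alive[pick] = alive.back();
        alive.pop_back();
      }
    }
    if (overflow) break;
    for (size_t a = 0; a < alive.size(); ++a) {
      lin[alive[a]].t_end = t_sim;
      lin[alive[a]].extant = true;
    }
    if (alive.size() < 2) continue;   // condition on >= 2 extant tips
    ++n_surviving;

    // children always have larger indices than parents
    has_extant.assign(lin.size(), 0);
    for (int i = (int)lin.size() - 1; i >= 0; --i) {
      if (lin[i].child1 >= 0)
        has_extant[i] = has_extant[lin[i].child1] ||
                        has_extant[lin[i].child2];
      else
        has_extant[i] = lin[i].extant ? 1 : 0;
    }

    if (has_extant[0] && has_extant[1]) {
      // the initial bifurcation is itself a reconstructed node of age t_sim
      double age = t_sim;
      int a = resolve(lin, has_extant, 0, t_sim, phi, ages);
      int b = resolve(lin, has_extant, 1, t_sim, phi, ages);
      if (a == ST_LEAF && b == ST_LEAF) {
        double lag = (phi > 0.0) ? R::rexp(phi) : 0.0;
        if (age >= lag) ages.push_back(age);
      }
    } else {
      int side = has_extant[0] ? 0 : 1;
      resolve(lin, has_extant, side, t_sim, phi, ages);
    }
  }

  return List::create(_["ages"] = NumericVector(ages.begin(), ages.end()),
                      _["n_surviving"] = n_surviving,
                      _["overflow"] = overflow);
}
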