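#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-based birth-death-mutation event loop with a logistic carrying
// capacity. Equivalent to drawing an exponential waiting time for every
// living cell x event type (rate = modulated birth, death, or mutation rate)
// and firing the minimum: the minimum of independent exponentials is an
// exponential with the summed rate, and the firing pair is chosen with
// probability proportional to its rate. Uses R's RNG so results are
// reproducible under set.seed().

struct Cell {
  int node;                    // index into the node log
  std::vector<unsigned char> seq;
  double affinity;
  bool functional;
  double lambda;               // intrinsic birth rate (sigmoid of affinity)
  double mu;                   // death rate (functional vs stop)
  double mutrate;              // multiplier * sum of site mutabilities
};

static inline double sigmoid_rate(double x, double xc, double xh,
                                  double yc, double yh) {
  double z = -xc * (x - xh);
  if (z > 745.0) z = 745.0;
  if (z < -745.0) z = -745.0;
  return yc / (1.0 + std::exp(z)) + yh;
}

static inline bool seq_functional(const std::vector<unsigned char>& s, int frame0) {
  // stop codons TAA, TAG, TGA with A=0,C=1,G=2,T=3
  int L = (int)s.size();
  for (int i = frame0; i + 2 < L; i += 3) {
    if (s[i] != 3) continue;
    if (s[i + 1] == 0 && (s[i + 2] == 0 || s[i + 2] == 2)) return false;  // TAA, TAG
    if (s[i + 1] == 2 && s[i + 2] == 0) return false;                     // TGA
  }
  return true;
}

// Fenwick (binary indexed) tree over cell slots, for O(log N) rate updates
// and weighted selection
struct Fenwick {
  std::vector<double> t;
  int n;
  void init(int cap) { n = cap; t.assign(cap + 1, 0.0); }
  void add(int i, double delta) { for (++i; i <= n; i += i & (-i)) t[i] += delta; }
  double total() const { double s = 0; for (int i = n; i > 0; i -= i & (-i)) s += t[i]; return s; }
  // smallest index with prefix sum >= target
  int select(double target) const {
    int pos = 0; double acc = 0;
    int logn = 1; while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << (logn - 1); pw > 0; pw >>= 1) {
      int np = pos + pw;
      if (np <= n && acc + t[np] < target) { pos = np; acc += t[np]; }
    }
    return pos;  // 0-based slot
  }
};

static inline double seq_mut_sum(const std::vector<unsigned char>& s,
                                 const NumericVector& mutab) {
  int L = (int)s.size();
  double tot = 0.0;
  for (int i = 2; i + 2 < L; ++i) {
    int code = s[i - 2] + 4 * (s[i - 1] + 4 * (s[i] + 4 * (s[i + 1] + 4 * s[i + 2])));
    tot += mutab[code];
  }
  return tot;
}

// [[Rcpp::export(name = ".simulate_gc_cpp")]]
List simulate_gc_cpp(IntegerVector naive, NumericMatrix effects,
                     NumericVector mutability, NumericMatrix subprob,
                     double multiplier, int frame0,
                     double xscale, double xshift, double yscale, double yshift,
                     int init_pop, double capacity, int capacity_method,
                     double t_final, double death_rate, double stop_death_rate,
                     int max_events) {
  const int L = naive.size();
  std::vector<Cell> cells;
  cells.reserve((size_t)(capacity * 2 + 16));

  // node log
  std::vector<int> parent;       // 0-based, -1 for root
  std::vector<double> btime;     // node creation time
  std::vector<int> mut_site, mut_from, mut_to;  // -1 unless a mutation node
  std::vector<int> status;       // 0 split(birth) 1 mutated 2 dead 3 alive at T
  std::vector<double> etime;     // time the node ended (or t_final)

  auto new_node = [&](int par, double t, int ms, int mf, int mt) -> int {
    parent.push_back(par); btime.push_back(t);
    mut_site.push_back(ms); mut_from.push_back(mf); mut_to.push_back(mt);
    status.push_back(3); etime.push_back(t);
    return (int)parent.size() - 1;
  };

  std::vector<unsigned char> nseq(L);
  for (int i = 0; i < L; ++i) nseq[i] = (unsigned char)naive[i];

  // root + zero-time binary expansion: split leaves in breadth-first
  // (creation) order, so non-power-of-two initial populations come from a
  // binary expansion truncated mid-level
  int root = new_node(-1, 0.0, -1, -1, -1);
  {
    std::vector<int> q; q.push_back(root);
    size_t head = 0;
    int count = 1;
    while (count < init_pop) {
      int u = q[head++];
      status[u] = 0; etime[u] = 0.0;
      q.push_back(new_node(u, 0.0, -1, -1, -1));
      q.push_back(new_node(u, 0.0, -1, -1, -1));
      ++count;
    }
    Cell proto;
    proto.seq = nseq;
    proto.affinity = 0.0;
    proto.functional = seq_functional(nseq, frame0);
    proto.lambda = sigmoid_rate(0.0, xscale, xshift, yscale, yshift);
    proto.mu = proto.functional ? death_rate : stop_death_rate;
    proto.mutrate = multiplier * seq_mut_sum(nseq, mutability);
    for (size_t i = head; i < q.size(); ++i) {
      Cell c = proto; c.node = q[i];
      cells.push_back(c);
    }
  }

  double sumLam = 0, sumMu = 0, sumMut = 0;
  for (auto& c : cells) { sumLam += c.lambda; sumMu += c.mu; sumMut += c.mutrate; }

  Fenwick fenLam, fenMu, fenMut;
  int fcap = (int)(capacity * 4 + init_pop + 64);
  auto fen_rebuild = [&](int cap) {
    fcap = cap;
    fenLam.init(fcap); fenMu.init(fcap); fenMut.init(fcap);
    for (int i = 0; i < (int)cells.size(); ++i) {
      fenLam.add(i, cells[i].lambda);
      fenMu.add(i, cells[i].mu);
      fenMut.add(i, cells[i].mutrate);
    }
  };
  fen_rebuild(fcap);

  std::vector<double> traj_t, traj_n, traj_m;
  double t = 0.0;
  int n_events = 0;
  bool overflow = false;

  while (!cells.empty()) {
    int N = (int)cells.size();
    double m = 1.0;
    if (sumLam > 0) m = std::pow(sumMu / sumLam, (double)N / capacity);

    double B, D;
    if (capacity_method == 0) {        // birth-modulated
      B = m * sumLam; D = sumMu;
    } else if (capacity_method == 1) { // death-modulated (inverse factor)
      B = sumLam; D = (m > 0) ? sumMu / m : R_PosInf;
    } else {                            // hard
      B = sumLam; D = sumMu;
    }
    double M = sumMut;
    double total = B + D + M;
    if (!(total > 0)) break;  // frozen state: no event can occur

    double dt = exp_rand() / total;
    if (t + dt >= t_final) { t = t_final; break; }
    t += dt;

    double u = unif_rand() * total;
    if (u < B) {
      // birth: pick cell proportional to lambda (modulation is uniform)
      double target = (u / B) * sumLam;
      int k = fenLam.select(target);
      if (k >= N) k = N - 1;
      Cell c = cells[k];
      status[c.node] = 0; etime[c.node] = t;
      int n1 = new_node(c.node, t, -1, -1, -1);
      int n2 = new_node(c.node, t, -1, -1, -1);
      cells[k].node = n1;
      Cell c2 = cells[k]; c2.node = n2;
      cells.push_back(c2);
      sumLam += c.lambda; sumMu += c.mu; sumMut += c.mutrate;
      if ((int)cells.size() > fcap) fen_rebuild(fcap * 2);
      else {
        int j = (int)cells.size() - 1;
        fenLam.add(j, c.lambda); fenMu.add(j, c.mu); fenMut.add(j, c.mutrate);
      }
      if (capacity_method == 2 && (int)cells.size() > (int)capacity) {
        // hard constraint: immediately kill a uniformly random living cell
        int j = (int)std::floor(unif_rand() * cells.size());
        if (j >= (int)cells.size()) j = (int)cells.size() - 1;
        Cell& v = cells[j];
        status[v.node] = 2; etime[v.node] = t;
        sumLam -= v.lambda; sumMu -= v.mu; sumMut -= v.mutrate;
        int last = (int)cells.size() - 1;
        fenLam.add(j, cells[last].lambda - v.lambda);
        fenMu.add(j, cells[last].mu - v.mu);
        fenMut.add(j, cells[last].mutrate - v.mutrate);
        fenLam.add(last, -cells[last].lambda);
        fenMu.add(last, -cells[last].mu);
        fenMut.add(last, -cells[last].mutrate);
        cells[j] = cells.back(); cells.pop_back();
      }
    } else if (u < B + D) {
      // death: pick cell proportional to mu
      double target = ((u - B) / D) * sumMu;
      int k = fenMu.select(target);
      if (k >= N) k = N - 1;
      Cell& c = cells[k];
      status[c.node] = 2; etime[c.node] = t;
      sumLam -= c.lambda; sumMu -= c.mu; sumMut -= c.mutrate;
      int last = (int)cells.size() - 1;
      fenLam.add(k, cells[last].lambda - c.lambda);
      fenMu.add(k, cells[last].mu - c.mu);
      fenMut.add(k, cells[last].mutrate - c.mutrate);
      fenLam.add(last, -cells[last].lambda);
      fenMu.add(last, -cells[last].mu);
      fenMut.add(last, -cells[last].mutrate);
      cells[k] = cells.back(); cells.pop_back();
    } else {
      // mutation: pick cell proportional to mutrate, then site/base by 5-mer
      double target = ((u - B - D) / M) * sumMut;
      int k = fenMut.select(target);
      if (k >= N) k = N - 1;
      Cell& c = cells[k];
      double site_tot = c.mutrate / multiplier;
      double starget = unif_rand() * site_tot;
      int pos = -1; double sacc = 0;
      int code = 0;
      for (int i = 2; i + 2 < L; ++i) {
        code = c.seq[i - 2] + 4 * (c.seq[i - 1] + 4 * (c.seq[i] + 4 * (c.seq[i + 1] + 4 * c.seq[i + 2])));
        sacc += mutability[code];
        if (sacc >= starget) { pos = i; break; }
      }
      if (pos < 0) {
        // numerical edge: fall back to the last informative site
        pos = L - 3;
        code = c.seq[pos - 2] + 4 * (c.seq[pos - 1] + 4 * (c.seq[pos] + 4 * (c.seq[pos + 1] + 4 * c.seq[pos + 2])));
      }
      double bu = unif_rand();
      int newb = 3; double bacc = 0;
      for (int b = 0; b < 4; ++b) { bacc += subprob(code, b); if (bacc >= bu) { newb = b; break; } }
      int oldb = c.seq[pos];
      sumLam -= c.lambda; sumMu -= c.mu; sumMut -= c.mutrate;
      fenLam.add(k, -c.lambda); fenMu.add(k, -c.mu); fenMut.add(k, -c.mutrate);
      status[c.node] = 1; etime[c.node] = t;
      int n1 = new_node(c.node, t, pos, oldb, newb);
      c.node = n1;
      c.seq[pos] = (unsigned char)newb;
      c.affinity += effects(newb, pos) - effects(oldb, pos);
      c.functional = seq_functional(c.seq, frame0);
      c.lambda = sigmoid_rate(c.affinity, xscale, xshift, yscale, yshift);
      c.mu = c.functional ? death_rate : stop_death_rate;
      c.mutrate = multiplier * seq_mut_sum(c.seq, mutability);
      sumLam += c.lambda; sumMu += c.mu; sumMut += c.mutrate;
      fenLam.add(k, c.lambda); fenMu.add(k, c.mu); fenMut.add(k, c.mutrate);
    }

    traj_t.push_back(t); traj_n.push_back((double)cells.size());
    traj_m.push_back(sumLam > 0 ? std::pow(sumMu / sumLam, (double)cells.size() / capacity) : NA_REAL);

    if (++n_events >= max_events) { overflow = true; break; }
  }

  int n_living = (int)cells.size();
  IntegerVector living(n_living);
  NumericVector living_aff(n_living), living_lambda(n_living), living_mu(n_living),
      living_mutrate(n_living);
  LogicalVector living_fun(n_living);
  for (int i = 0; i < n_living; ++i) {
    etime[cells[i].node] = t_final;
    living[i] = cells[i].node + 1;  // 1-based for R
    living_aff[i] = cells[i].affinity;
    living_lambda[i] = cells[i].lambda;
    living_mu[i] = cells[i].mu;
    living_mutrate[i] = cells[i].mutrate;
    living_fun[i] = cells[i].functional;
  }

  int n_nodes = (int)parent.size();
  IntegerVector pv(n_nodes), msv(n_nodes), mfv(n_nodes), mtv(n_nodes), stv(n_nodes);
  NumericVector btv(n_nodes), etv(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    pv[i] = parent[i] + 1;  // 0 for root
    btv[i] = btime[i]; etv[i] = etime[i];
    msv[i] = mut_site[i] + 1; mfv[i] = mut_from[i]; mtv[i] = mut_to[i];
    stv[i] = status[i];
  }

  return List::create(
      _["parent"] = pv, _["time"] = btv, _["end_time"] = etv,
      _["mut_site"] = msv, _["mut_from"] = mfv, _["mut_to"] = mtv,
      _["status"] = stv,
      _["living"] = living, _["living_affinity"] = living_aff,
      _["living_lambda"] = living_lambda, _["living_mu"] = living_mu,
      _["living_mutrate"] = living_mutrate, _["living_functional"] = living_fun,
      _["traj_time"] = NumericVector(traj_t.begin(), traj_t.end()),
      _["traj_n"] = NumericVector(traj_n.begin(), traj_n.end()),
      _["traj_m"] = NumericVector(traj_m.begin(), traj_m.end()),
      _["final_time"] = t, _["n_events"] = n_events, _["overflow"] = overflow);
}
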