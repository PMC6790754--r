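// Discrete-time engine for the protocell / replicator model.
//
// One time step = reaction (per cell: complex formation -> synthesis with
// mutation -> decay), then global substrate diffusion, then cell division
// and removal. All randomness is drawn from R's RNG stream so that
// set.seed() at the R level makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <array>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// column index of k^c_pt in the fixed order
// [c=P:(pp,pq,qp,qq), c=Q:(pp,pq,qp,qq)], with P=0, Q=1
static inline int kidx(int c, int p, int t) { return 4 * c + 2 * p + t; }
static inline double eff(double k) { return k > 0.0 ? k : 0.0; }

static inline int rint(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

struct Rep {
  double k[8];
  int id;
  int type;        // 0 = P, 1 = Q
  int birth_step;  // step of first decay trial
  int anc_id;      // window-ancestor bookkeeping (-1 until the window)
  int anc_type;
  int anc_cell;
};

struct Cell {
  int id;
  int parent;
  long sub;     // substrate count
  int anc_id;   // window-ancestor cell
  std::vector<Rep> reps;
};

struct Engine {
  // parameters
  int V;
  double m, d, delta_mut, k_max;
  long n_tot;
  int init_cells;
  bool density_collisions;

  // options
  int t_max, record_every, snapshot_every;
  int log_from, log_to;       // replicator event-log window (-1 = off)
  bool log_cells;
  int ancestor_at;            // -1 = off
  int max_lifetimes, max_mutations;

  // state
  std::vector<Cell> cells;
  int step;
  int next_rep_id, next_cell_id;

  // logs
  std::vector<int> b_step, b_id, b_type, b_tmpl, b_cat, b_cell;
  std::vector<int> d_step, d_id, d_type, d_cell;
  std::vector<int> ce_step, ce_event, ce_id, ce_parent; // event 0=birth 1=removal
  std::vector<int> lifetimes;
  std::vector<double> mut_pre, mut_inc;
  long cum_births = 0, cum_deaths = 0;
  int violations = 0;
  bool extinct = false;

  // window snapshot stats for ancestor tracking
  bool anc_recorded = false;
  long anc_nP = 0, anc_nQ = 0;
  double anc_AP = 0.0, anc_AQ = 0.0;

  // trajectory (flat rows, 18 columns)
  std::vector<double> traj;
  enum { TRAJ_COLS = 18 };

  // scratch
  std::vector<int> perm;
  std::vector<int> cx_cat, cx_tmpl, cx_prod;

  bool rep_logging() const {
    return log_from >= 0 && step >= log_from && step <= log_to;
  }

  void log_cell_birth(int id, int parent) {
    if (!log_cells) return;
    ce_step.push_back(step); ce_event.push_back(0);
    ce_id.push_back(id); ce_parent.push_back(parent);
  }
  void log_cell_removal(int id) {
    if (!log_cells) return;
    ce_step.push_back(step); ce_event.push_back(1);
    ce_id.push_back(id); ce_parent.push_back(NA_INTEGER);
  }

  Rep make_child(const Rep &tmpl, int prod_type) {
    Rep child;
    std::memcpy(child.k, tmpl.k, sizeof(child.k));
    child.type = prod_type;
    child.id = next_rep_id++;
    child.birth_step = step;
    child.anc_id = tmpl.anc_id;
    child.anc_type = tmpl.anc_type;
    child.anc_cell = tmpl.anc_cell;
    if (m > 0.0) {
      for (int e = 0; e < 8; ++e) {
        if (unif_rand() < m) {
          double inc = (2.0 * unif_rand() - 1.0) * delta_mut;
          double pre = child.k[e];
          double v = pre + inc;
          if (v > k_max) v = 2.0 * k_max - v;
          child.k[e] = v;
          if ((int)mut_pre.size() < max_mutations) {
            mut_pre.push_back(pre);
            mut_inc.push_back(inc);
          }
        }
      }
    }
    return child;
  }

  void react_cell(Cell &cell) {
    int n = (int)cell.reps.size();

    // random disjoint pairing of all (free) replicators
    perm.resize(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(perm[i], perm[rint(i + 1)]);

    cx_cat.clear(); cx_tmpl.clear(); cx_prod.clear();
    double denom = 4.0 * k_max;
    // mass-action collision factor: the chance that a paired encounter
    // actually happens scales with replicator density in the cell (volume
    // set by the division threshold V); a full cell reacts at full rate
    double cfac = density_collisions
      ? std::min(1.0, (double)(n - 1) / (double)V) : 1.0;
    for (int i = 0; i + 1 < n; i += 2) {
      int a = perm[i], b = perm[i + 1];
      const Rep &A = cell.reps[a];
      const Rep &B = cell.reps[b];
      double r[4];
      r[0] = eff(A.k[kidx(A.type, 0, B.type)]); // A catalyses, product P
      r[1] = eff(A.k[kidx(A.type, 1, B.type)]); // A catalyses, product Q
      r[2] = eff(B.k[kidx(B.type, 0, A.type)]); // B catalyses, product P
      r[3] = eff(B.k[kidx(B.type, 1, A.type)]); // B catalyses, product Q
      double tot = r[0] + r[1] + r[2] + r[3];
      if (tot <= 0.0) continue;
      if (unif_rand() * denom < tot * cfac) {
        double u = unif_rand() * tot;
        int ch = 0;
        double acc = r[0];
        while (ch < 3 && u >= acc) acc += r[++ch];
        int cat  = (ch < 2) ? a : b;
        int tmpl = (ch < 2) ? b : a;
        int prod = ch % 2;
        cx_cat.push_back(cat); cx_tmpl.push_back(tmpl); cx_prod.push_back(prod);
      }
    }

    // synthesis: random order over complexes, one substrate per birth
    int ncx = (int)cx_cat.size();
    if (ncx > 0 && cell.sub > 0) {
      for (int i = ncx - 1; i > 0; --i) {
        int j = rint(i + 1);
        std::swap(cx_cat[i], cx_cat[j]);
        std::swap(cx_tmpl[i], cx_tmpl[j]);
        std::swap(cx_prod[i], cx_prod[j]);
      }
      for (int i = 0; i < ncx && cell.sub > 0; ++i) {
        cell.sub--;
        Rep child = make_child(cell.reps[cx_tmpl[i]], cx_prod[i]);
        cum_births++;
        if (rep_logging()) {
          b_step.push_back(step); b_id.push_back(child.id);
          b_type.push_back(child.type);
          b_tmpl.push_back(cell.reps[cx_tmpl[i]].id);
          b_cat.push_back(cell.reps[cx_cat[i]].id);
          b_cell.push_back(cell.id);
        }
        cell.reps.push_back(child);
      }
    }
    // all complexes dissociate here (they are never carried across steps)

    // decay: every replicator, newborns included, dies with probability d;
    // drawn as a binomial count plus a uniform choice of the victims
    // (equivalent in law to independent per-replicator trials)
    int nr = (int)cell.reps.size();
    int ndie = (int)R::rbinom((double)nr, d);
    for (int j = 0; j < ndie; ++j) {
      int i = rint(nr);               // victims are exchangeable
      const Rep &r = cell.reps[i];
      cum_deaths++;
      if (rep_logging()) {
        d_step.push_back(step); d_id.push_back(r.id);
        d_type.push_back(r.type); d_cell.push_back(cell.id);
      }
      if ((int)lifetimes.size() < max_lifetimes)
        lifetimes.push_back(step - r.birth_step + 1);
      cell.sub++;
      cell.reps[i] = cell.reps.back();
      cell.reps.pop_back();
      nr--;
    }
  }

  void diffuse() {
    long totS = 0, totR = 0;
    for (const Cell &c : cells) { totS += c.sub; totR += (long)c.reps.size(); }
    if (totS == 0 || totR == 0) return; // degenerate: substrate stays put
    long rem = totS, remR = totR;
    for (Cell &c : cells) {
      long ni = (long)c.reps.size();
      if (ni == 0) { c.sub = 0; continue; }
      if (ni == remR) { c.sub = rem; rem = 0; remR = 0; }
      else {
        long x = (long)R::rbinom((double)rem, (double)ni / (double)remR);
        c.sub = x; rem -= x; remR -= ni;
      }
    }
  }

  void divide_and_cull() {
    std::vector<Cell> out;
    out.reserve(cells.size() + 8);
    for (Cell &c : cells) {
      long particles = (long)c.reps.size() + c.sub;
      if (particles == 0) { log_cell_removal(c.id); continue; }
      if (particles <= V) { out.push_back(std::move(c)); continue; }
      Cell a, b;
      a.id = next_cell_id++; b.id = next_cell_id++;
      a.parent = c.id; b.parent = c.id;
      a.anc_id = c.anc_id; b.anc_id = c.anc_id;
      a.sub = (long)R::rbinom((double)c.sub, 0.5);
      b.sub = c.sub - a.sub;
      for (Rep &r : c.reps) {
        if (unif_rand() < 0.5) a.reps.push_back(r); else b.reps.push_back(r);
      }
      log_cell_birth(a.id, c.id);
      log_cell_birth(b.id, c.id);
      log_cell_removal(c.id);
      if ((long)a.reps.size() + a.sub > 0) out.push_back(std::move(a));
      else log_cell_removal(a.id);
      if ((long)b.reps.size() + b.sub > 0) out.push_back(std::move(b));
      else log_cell_removal(b.id);
    }
    cells = std::move(out);
  }

  void mark_ancestors() {
    long nP = 0, nQ = 0;
    double sAP = 0.0, sAQ = 0.0;
    for (Cell &c : cells) {
      c.anc_id = c.id;
      for (Rep &r : c.reps) {
        r.anc_id = r.id; r.anc_type = r.type; r.anc_cell = c.id;
        if (r.type == 0) nP++; else nQ++;
        sAP += (r.k[0] + r.k[1] + r.k[2] + r.k[3]) / 4.0;
        sAQ += (r.k[4] + r.k[5] + r.k[6] + r.k[7]) / 4.0;
      }
    }
    long n = nP + nQ;
    anc_nP = nP; anc_nQ = nQ;
    anc_AP = n > 0 ? sAP / n : NA_REAL;
    anc_AQ = n > 0 ? sAQ / n : NA_REAL;
    anc_recorded = true;
  }

  void record_trajectory() {
    double ksum[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    long nP = 0, nQ = 0, nS = 0;
    double minsum = 0.0;
    long mincells = 0;
    for (const Cell &c : cells) {
      nS += c.sub;
      long cP = 0, cQ = 0;
      for (const Rep &r : c.reps) {
        if (r.type == 0) cP++; else cQ++;
        for (int e = 0; e < 8; ++e) ksum[e] += r.k[e];
      }
      nP += cP; nQ += cQ;
      long particles = (long)c.reps.size() + c.sub;
      if (2 * particles >= V && (cP + cQ) > 0) {
        minsum += (double)std::min(cP, cQ) / (double)(cP + cQ);
        mincells++;
      }
    }
    long n = nP + nQ;
    traj.push_back((double)step);
    for (int e = 0; e < 8; ++e) traj.push_back(n > 0 ? ksum[e] / n : NA_REAL);
    traj.push_back((double)cells.size());
    traj.push_back((double)nP / (double)n_tot);
    traj.push_back((double)nQ / (double)n_tot);
    traj.push_back((double)nS / (double)n_tot);
    traj.push_back(mincells > 0 ? minsum / mincells : NA_REAL);
    traj.push_back((double)n);
    traj.push_back((double)nS);
    traj.push_back((double)cum_births);
    traj.push_back((double)cum_deaths);
  }

  void check_conservation() {
    long tot = 0;
    for (const Cell &c : cells) tot += (long)c.reps.size() + c.sub;
    if (tot != n_tot) violations++;
  }

  List snapshot_list() const {
    long n = 0;
    for (const Cell &c : cells) n += (long)c.reps.size();
    IntegerVector cell_id(n), rep_id(n), rtype(n), birth(n);
    NumericMatrix k(n, 8);
    IntegerVector cid(cells.size()), csub(cells.size());
    long j = 0;
    for (size_t ci = 0; ci < cells.size(); ++ci) {
      const Cell &c = cells[ci];
      cid[ci] = c.id; csub[ci] = (int)c.sub;
      for (const Rep &r : c.reps) {
        cell_id[j] = c.id; rep_id[j] = r.id; rtype[j] = r.type;
        birth[j] = r.birth_step;
        for (int e = 0; e < 8; ++e) k(j, e) = r.k[e];
        j++;
      }
    }
    return List::create(
      _["step"] = step, _["cell_id"] = cell_id, _["rep_id"] = rep_id,
      _["rtype"] = rtype, _["birth_step"] = birth, _["k"] = k,
      _["cells_id"] = cid, _["cells_substrate"] = csub);
  }

  List ancestor_list() const {
    // tally window ancestors over the surviving population
    std::map<int, std::array<long, 3>> tab; // id -> {count, type, cell}
    std::set<int> cell_anc;
    for (const Cell &c : cells) {
      cell_anc.insert(c.anc_id);
      for (const Rep &r : c.reps) {
        auto &e = tab[r.anc_id];
        e[0]++; e[1] = r.anc_type; e[2] = r.anc_cell;
      }
    }
    size_t na = tab.size();
    IntegerVector aid(na), atype(na), acell(na), acount(na);
    size_t i = 0;
    for (auto &kv : tab) {
      aid[i] = kv.first; acount[i] = (int)kv.second[0];
      atype[i] = (int)kv.second[1]; acell[i] = (int)kv.second[2];
      i++;
    }
    IntegerVector canc(cell_anc.begin(), cell_anc.end());
    return List::create(
      _["at_step"] = ancestor_at,
      _["pop_nP"] = (double)anc_nP, _["pop_nQ"] = (double)anc_nQ,
      _["pop_A_P"] = anc_AP, _["pop_A_Q"] = anc_AQ,
      _["anc_id"] = aid, _["anc_type"] = atype, _["anc_cell"] = acell,
      _["anc_count"] = acount, _["surviving_cell_ancestors"] = canc);
  }

  List state_list() const {
    List cl(cells.size());
    for (size_t ci = 0; ci < cells.size(); ++ci) {
      const Cell &c = cells[ci];
      size_t n = c.reps.size();
      IntegerVector rid(n), rt(n), bs(n);
      NumericMatrix k(n, 8);
      for (size_t j = 0; j < n; ++j) {
        rid[j] = c.reps[j].id; rt[j] = c.reps[j].type;
        bs[j] = c.reps[j].birth_step;
        for (int e = 0; e < 8; ++e) k(j, e) = c.reps[j].k[e];
      }
      cl[ci] = List::create(
        _["id"] = c.id, _["parent"] = c.parent, _["substrate"] = (double)c.sub,
        _["rep_id"] = rid, _["rtype"] = rt, _["birth_step"] = bs, _["k"] = k);
    }
    return List::create(
      _["step"] = step, _["next_rep_id"] = next_rep_id,
      _["next_cell_id"] = next_cell_id, _["cells"] = cl);
  }
};

// [[Rcpp::export]]
List cpp_run(List params, List opts, Nullable<List> init_state) {
  Engine E;
  E.V = as<int>(params["V"]);
  E.m = as<double>(params["m"]);
  E.d = as<double>(params["d"]);
  E.delta_mut = as<double>(params["delta_mut"]);
  E.k_max = as<double>(params["k_max"]);
  E.n_tot = (long)as<double>(params["n_tot"]);
  E.init_cells = as<int>(params["init_cells"]);
  E.density_collisions = as<bool>(params["density_collisions"]);

  E.t_max = as<int>(opts["t_max"]);
  E.record_every = as<int>(opts["record_every"]);
  E.snapshot_every = as<int>(opts["snapshot_every"]);
  E.log_from = as<int>(opts["log_events_from"]);
  E.log_to = as<int>(opts["log_events_to"]);
  E.log_cells = as<bool>(opts["log_cell_events"]);
  E.ancestor_at = as<int>(opts["ancestor_at"]);
  E.max_lifetimes = as<int>(opts["max_lifetimes"]);
  E.max_mutations = as<int>(opts["max_mutations"]);

  RNGScope rng;

  int start_step = 0;
  if (init_state.isNotNull()) {
    List st(init_state);
    start_step = as<int>(st["step"]);
    E.next_rep_id = as<int>(st["next_rep_id"]);
    E.next_cell_id = as<int>(st["next_cell_id"]);
    List cl = st["cells"];
    for (int ci = 0; ci < cl.size(); ++ci) {
      List c = cl[ci];
      Cell cell;
      cell.id = as<int>(c["id"]);
      cell.parent = as<int>(c["parent"]);
      cell.sub = (long)as<double>(c["substrate"]);
      cell.anc_id = -1;
      IntegerVector rid = c["rep_id"], rt = c["rtype"], bs = c["birth_step"];
      NumericMatrix k = c["k"];
      for (int j = 0; j < rid.size(); ++j) {
        Rep r;
        r.id = rid[j]; r.type = rt[j]; r.birth_step = bs[j];
        r.anc_id = -1; r.anc_type = -1; r.anc_cell = -1;
        for (int e = 0; e < 8; ++e) r.k[e] = k(j, e);
        cell.reps.push_back(r);
      }
      E.cells.push_back(std::move(cell));
    }
  } else {
    // standard initial condition: init_cells cells of (nearly) equal size,
    // all profile entries at k_max, alternating types, no substrate
    long base = E.n_tot / E.init_cells;
    long extra = E.n_tot - base * E.init_cells;
    int rep_id = 1, cell_id = 1;
    for (int ci = 0; ci < E.init_cells; ++ci) {
      Cell cell;
      cell.id = cell_id++;
      cell.parent = NA_INTEGER;
      cell.sub = 0;
      cell.anc_id = -1;
      long sz = base + (ci < extra ? 1 : 0);
      for (long j = 0; j < sz; ++j) {
        Rep r;
        r.id = rep_id++;
        r.type = (int)((j + ci) % 2); // alternate, staggered across cells
        r.birth_step = 1;             // first decay trial is in step 1
        r.anc_id = -1; r.anc_type = -1; r.anc_cell = -1;
        for (int e = 0; e < 8; ++e) r.k[e] = E.k_max;
        cell.reps.push_back(r);
      }
      E.cells.push_back(std::move(cell));
    }
    E.next_rep_id = rep_id;
    E.next_cell_id = cell_id;
  }
  E.step = start_step;

  if (E.log_cells) {
    for (const Cell &c : E.cells) E.log_cell_birth(c.id, c.parent);
  }

  std::vector<List> snapshots;
  E.record_trajectory();
  if (E.snapshot_every > 0) snapshots.push_back(E.snapshot_list());
  if (E.ancestor_at == E.step) E.mark_ancestors();

  for (int t = start_step + 1; t <= E.t_max; ++t) {
    E.step = t;
    for (Cell &c : E.cells) E.react_cell(c);
    E.diffuse();
    E.divide_and_cull();
    E.check_conservation();
    if (E.ancestor_at == t) E.mark_ancestors();
    if (t % E.record_every == 0) E.record_trajectory();
    if (E.snapshot_every > 0 && t % E.snapshot_every == 0 && t != E.t_max)
      snapshots.push_back(E.snapshot_list());
    if (E.cells.empty()) { E.extinct = true; break; }
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  if (E.snapshot_every >= 0 && !E.cells.empty()) snapshots.push_back(E.snapshot_list());

  // trajectory matrix
  size_t nrow = E.traj.size() / Engine::TRAJ_COLS;
  NumericMatrix tm(nrow, Engine::TRAJ_COLS);
  for (size_t r = 0; r < nrow; ++r)
    for (int cidx = 0; cidx < Engine::TRAJ_COLS; ++cidx)
      tm(r, cidx) = E.traj[r * Engine::TRAJ_COLS + cidx];
  CharacterVector cn = CharacterVector::create(
    "step", "kP.PP", "kP.PQ", "kP.QP", "kP.QQ", "kQ.PP", "kQ.PQ", "kQ.QP",
    "kQ.QQ", "cell_count", "freq_P", "freq_Q", "freq_S", "minority_mean",
    "n_replicators", "n_substrate", "cum_births", "cum_deaths");
  colnames(tm) = cn;

  DataFrame births = DataFrame::create(
    _["step"] = E.b_step, _["rep_id"] = E.b_id, _["rtype"] = E.b_type,
    _["template_id"] = E.b_tmpl, _["catalyst_id"] = E.b_cat,
    _["cell_id"] = E.b_cell);
  DataFrame deaths = DataFrame::create(
    _["step"] = E.d_step, _["rep_id"] = E.d_id, _["rtype"] = E.d_type,
    _["cell_id"] = E.d_cell);
  DataFrame cell_events = DataFrame::create(
    _["step"] = E.ce_step, _["event"] = E.ce_event, _["cell_id"] = E.ce_id,
    _["parent_id"] = E.ce_parent);

  NumericMatrix mut(E.mut_pre.size(), 2);
  for (size_t i = 0; i < E.mut_pre.size(); ++i) {
    mut(i, 0) = E.mut_pre[i]; mut(i, 1) = E.mut_inc[i];
  }
  colnames(mut) = CharacterVector::create("pre", "increment");

  return List::create(
    _["trajectory"] = tm,
    _["births"] = births,
    _["deaths"] = deaths,
    _["cell_events"] = cell_events,
    _["snapshots"] = wrap(snapshots),
    _["lifetimes"] = wrap(E.lifetimes),
    _["mutations"] = mut,
    _["ancestors"] = (E.ancestor_at >= 0 && E.anc_recorded)
                       ? (RObject)E.ancestor_list() : (RObject)R_NilValue,
    _["final_state"] = E.cells.empty() ? (RObject)R_NilValue
                                       : (RObject)E.state_list(),
    _["extinct"] = E.extinct,
    _["conservation_violations"] = E.violations,
    _["steps_run"] = E.step);
}
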