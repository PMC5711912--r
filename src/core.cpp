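// Simulation engine: maze generation, gate evaluation, feedback updates,
// synchronous brain stepping and episode evaluation. R-level wrappers in R/
// own the user-facing contracts; node indices here are 0-based throughout.
#include <Rcpp.h>
#include <queue>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 stream, independent of R's RNG so that every evaluation can
// be replayed from a scalar seed regardless of call order.
struct MbRng {
  uint64_t s;
  explicit MbRng(double seed) {
    s = (uint64_t)(seed < 1 ? 1 : seed);
    s ^= 0x9E3779B97F4A7C15ULL;
    next(); next();
  }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int randint(int n) { return (int)(next() % (uint64_t)n); }
};

// ---------------------------------------------------------------------------
// Maze: 64x64 grid, border walls, interior filled w.p. 1/7, BFS distance
// field from the goal, arrows toward a uniformly chosen closest neighbour,
// spawn set = tiles at distance 32. Linear index = col*size + row, matching
// R's column-major matrices.
static const int DX[4] = {-1, 0, 1, 0}; // up, right, down, left (row delta)
static const int DY[4] = {0, 1, 0, -1}; // col delta

struct MazeC {
  int size;
  std::vector<uint8_t> walls;
  std::vector<int> dist;   // -1 = wall or unreachable
  std::vector<int> arrow;  // -1 = none
  int goal;
  std::vector<int> spawns; // dist == spawn_dist
};

static void maze_label(MazeC &m, MbRng &rng) {
  int n = m.size * m.size;
  m.dist.assign(n, -1);
  m.arrow.assign(n, -1);
  std::queue<int> q;
  m.dist[m.goal] = 0;
  q.push(m.goal);
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int x = cur % m.size, y = cur / m.size;
    for (int k = 0; k < 4; ++k) {
      int nx = x + DX[k], ny = y + DY[k];
      if (nx < 0 || ny < 0 || nx >= m.size || ny >= m.size) continue;
      int ni = ny * m.size + nx;
      if (m.walls[ni] || m.dist[ni] >= 0) continue;
      m.dist[ni] = m.dist[cur] + 1;
      q.push(ni);
    }
  }
  for (int i = 0; i < n; ++i) {
    if (m.dist[i] <= 0) continue;
    int x = i % m.size, y = i / m.size;
    int best = m.dist[i], cand[4], nc = 0;
    for (int k = 0; k < 4; ++k) {
      int nx = x + DX[k], ny = y + DY[k];
      int ni = ny * m.size + nx; // interior guaranteed: border is wall
      if (m.walls[ni] || m.dist[ni] < 0) continue;
      if (m.dist[ni] < best) { best = m.dist[ni]; nc = 0; cand[nc++] = k; }
      else if (m.dist[ni] == best) cand[nc++] = k;
    }
    if (nc > 0) m.arrow[i] = cand[rng.randint(nc)];
  }
}

static MazeC maze_generate(MbRng &rng, int size, double fill, int spawn_dist,
                           int max_tries) {
  MazeC m;
  m.size = size;
  int n = size * size;
  for (int tr = 0; tr < max_tries; ++tr) {
    m.walls.assign(n, 0);
    for (int y = 0; y < size; ++y)
      for (int x = 0; x < size; ++x) {
        int i = y * size + x;
        if (x == 0 || y == 0 || x == size - 1 || y == size - 1) m.walls[i] = 1;
        else if (rng.unif() < fill) m.walls[i] = 1;
      }
    std::vector<int> empty;
    for (int i = 0; i < n; ++i) if (!m.walls[i]) empty.push_back(i);
    if (empty.empty()) continue;
    m.goal = empty[rng.randint((int)empty.size())];
    maze_label(m, rng);
    m.spawns.clear();
    for (int i = 0; i < n; ++i) if (m.dist[i] == spawn_dist) m.spawns.push_back(i);
    if (!m.spawns.empty()) return m;
  }
  stop("maze generation failed: no tile at the spawn distance after %d tries",
       max_tries);
  return m; // unreached
}

static List maze_to_list(const MazeC &m) {
  int n = m.size * m.size;
  LogicalMatrix walls(m.size, m.size);
  IntegerMatrix dist(m.size, m.size), arrow(m.size, m.size);
  for (int i = 0; i < n; ++i) {
    walls[i] = m.walls[i] != 0;
    dist[i] = m.dist[i] < 0 ? NA_INTEGER : m.dist[i];
    arrow[i] = m.arrow[i] < 0 ? NA_INTEGER : m.arrow[i];
  }
  IntegerMatrix spawns((int)m.spawns.size(), 2);
  for (int k = 0; k < (int)m.spawns.size(); ++k) {
    spawns(k, 0) = m.spawns[k] % m.size + 1; // row, 1-based for R
    spawns(k, 1) = m.spawns[k] / m.size + 1;
  }
  return List::create(_["size"] = m.size, _["walls"] = walls,
                      _["goal"] = IntegerVector::create(m.goal % m.size + 1,
                                                        m.goal / m.size + 1),
                      _["dist"] = dist, _["arrows"] = arrow,
                      _["spawns"] = spawns);
}

static MazeC maze_from_list(List L) {
  MazeC m;
  m.size = as<int>(L["size"]);
  LogicalMatrix walls = L["walls"];
  IntegerMatrix dist = L["dist"], arrow = L["arrows"];
  IntegerVector goal = L["goal"];
  int n = m.size * m.size;
  m.walls.resize(n); m.dist.resize(n); m.arrow.resize(n);
  for (int i = 0; i < n; ++i) {
    m.walls[i] = walls[i] ? 1 : 0;
    m.dist[i] = dist[i] == NA_INTEGER ? -1 : dist[i];
    m.arrow[i] = arrow[i] == NA_INTEGER ? -1 : arrow[i];
  }
  m.goal = (goal[1] - 1) * m.size + (goal[0] - 1);
  IntegerMatrix spawns = L["spawns"];
  for (int k = 0; k < spawns.nrow(); ++k)
    m.spawns.push_back((spawns(k, 1) - 1) * m.size + (spawns(k, 0) - 1));
  return m;
}

// [[Rcpp::export]]
List cpp_generate_maze(double seed, int size, double fill, int spawn_dist,
                       int max_tries) {
  MbRng rng(seed);
  MazeC m = maze_generate(rng, size, fill, spawn_dist, max_tries);
  return maze_to_list(m);
}

// ---------------------------------------------------------------------------
// Feedback update on one probability row: shift the credited entry by u,
// clamp to [0.01, 0.99] (and to row feasibility), rescale the remaining
// entries proportionally, then iteratively floor any entry below 0.01.
static const double P_LO = 0.01, P_HI = 0.99;

static void apply_one(double *row, int cols, int o, double u, int sign) {
  double t = row[o] + sign * u;
  if (t < P_LO) t = P_LO;
  if (t > P_HI) t = P_HI;
  double cap = 1.0 - P_LO * (cols - 1);
  if (t > cap) t = cap;
  double rest = 0.0;
  for (int c = 0; c < cols; ++c) if (c != o) rest += row[c];
  if (rest <= 0) {
    double v = (1.0 - t) / (cols - 1);
    for (int c = 0; c < cols; ++c) if (c != o) row[c] = v;
  } else {
    double f = (1.0 - t) / rest;
    for (int c = 0; c < cols; ++c) if (c != o) row[c] *= f;
  }
  row[o] = t;
  std::vector<char> fixed(cols, 0);
  fixed[o] = 1;
  for (int it = 0; it < cols; ++it) {
    bool changed = false;
    double fixed_sum = 0.0; int n_free = 0; double free_sum = 0.0;
    for (int c = 0; c < cols; ++c) {
      if (!fixed[c] && row[c] < P_LO - 1e-12) { row[c] = P_LO; fixed[c] = 1; changed = true; }
    }
    for (int c = 0; c < cols; ++c) {
      if (fixed[c]) fixed_sum += row[c];
      else { ++n_free; free_sum += row[c]; }
    }
    if (!changed) break;
    if (n_free == 0) break; // t capped at feasibility, sum is exactly 1
    double f = (1.0 - fixed_sum) / free_sum;
    for (int c = 0; c < cols; ++c) if (!fixed[c]) row[c] *= f;
  }
}

// [[Rcpp::export]]
NumericVector cpp_apply_one(NumericVector row, int o, double u, int sign) {
  NumericVector out = clone(row);
  apply_one(out.begin(), out.size(), o, u, sign);
  return out;
}

// ---------------------------------------------------------------------------
// Gates and brains.
struct GateC {
  int kind; // 0 deterministic, 1 probabilistic, 2 feedback
  std::vector<int> in, out;
  int rows, cols;
  std::vector<int> dtable;
  std::vector<double> P, Pbirth; // row-major
  int pos_node, neg_node, depth;
  std::vector<double> dpos, dneg;
  std::vector<std::pair<int, int>> hist; // front = most recent
};

struct BrainC {
  std::vector<GateC> gates;
  int n_nodes;
  std::vector<int> state;
  bool feedback_enabled;
};

static void gate_feedback(GateC &g, int sign, MbRng &rng) {
  for (size_t k = 0; k < g.hist.size(); ++k) {
    double delta = sign > 0 ? g.dpos[k] : g.dneg[k];
    double u = rng.unif() * delta;
    apply_one(&g.P[g.hist[k].first * g.cols], g.cols, g.hist[k].second, u, sign);
  }
}

static int gate_sample(GateC &g, int i, MbRng &rng) {
  if (g.kind == 0) return g.dtable[i];
  const double *row = &g.P[i * g.cols];
  double r = rng.unif(), acc = 0.0;
  int o = g.cols - 1;
  for (int c = 0; c < g.cols; ++c) { acc += row[c]; if (r < acc) { o = c; break; } }
  if (g.kind == 2) {
    g.hist.insert(g.hist.begin(), std::make_pair(i, o));
    if ((int)g.hist.size() > g.depth) g.hist.pop_back();
  }
  return o;
}

static void brain_step_c(BrainC &b, const int *sensors, MbRng &rng) {
  for (int k = 0; k < 4 && k < b.n_nodes; ++k) b.state[k] = sensors[k];
  for (size_t gi = 0; gi < b.gates.size(); ++gi) {
    GateC &g = b.gates[gi];
    if (g.kind != 2) continue;
    int pos = b.state[g.pos_node], neg = b.state[g.neg_node];
    if (b.feedback_enabled) {
      if (pos) gate_feedback(g, +1, rng);
      if (neg) gate_feedback(g, -1, rng);
    }
  }
  std::vector<int> next(b.n_nodes, 0);
  for (size_t gi = 0; gi < b.gates.size(); ++gi) {
    GateC &g = b.gates[gi];
    int i = 0;
    for (size_t k = 0; k < g.in.size(); ++k) i |= b.state[g.in[k]] << k;
    int o = gate_sample(g, i, rng);
    for (size_t k = 0; k < g.out.size(); ++k)
      if ((o >> k) & 1) next[g.out[k]] = 1;
  }
  for (int k = 4; k < b.n_nodes; ++k) b.state[k] = next[k];
}

static GateC gate_from_list(List g, int n_nodes) {
  GateC out;
  std::string kind = as<std::string>(g["kind"]);
  out.kind = kind == "deterministic" ? 0 : (kind == "probabilistic" ? 1 : 2);
  out.in = as<std::vector<int>>(g["input_nodes"]);
  out.out = as<std::vector<int>>(g["output_nodes"]);
  for (size_t k = 0; k < out.in.size(); ++k)
    if (out.in[k] < 0 || out.in[k] >= n_nodes) stop("input node out of range");
  for (size_t k = 0; k < out.out.size(); ++k)
    if (out.out[k] < 0 || out.out[k] >= n_nodes) stop("output node out of range");
  out.rows = 1 << out.in.size();
  out.cols = 1 << out.out.size();
  if (out.kind == 0) {
    out.dtable = as<std::vector<int>>(g["table"]);
    if ((int)out.dtable.size() != out.rows) stop("deterministic table size mismatch");
  } else {
    NumericMatrix P = g["table"];
    if (P.nrow() != out.rows || P.ncol() != out.cols) stop("probability table shape mismatch");
    out.P.resize(out.rows * out.cols);
    for (int i = 0; i < out.rows; ++i)
      for (int c = 0; c < out.cols; ++c) out.P[i * out.cols + c] = P(i, c);
    out.Pbirth = out.P;
  }
  if (out.kind == 2) {
    out.pos_node = as<int>(g["pos_node"]);
    out.neg_node = as<int>(g["neg_node"]);
    out.depth = as<int>(g["depth"]);
    out.dpos = as<std::vector<double>>(g["delta_pos"]);
    out.dneg = as<std::vector<double>>(g["delta_neg"]);
    if ((int)out.dpos.size() < out.depth || (int)out.dneg.size() < out.depth)
      stop("delta schedule shorter than buffer depth");
  }
  return out;
}

// [[Rcpp::export]]
SEXP cpp_build_brain(List gates, int n_nodes, bool feedback_enabled) {
  BrainC *b = new BrainC();
  b->n_nodes = n_nodes;
  b->state.assign(n_nodes, 0);
  b->feedback_enabled = feedback_enabled;
  for (int k = 0; k < gates.size(); ++k)
    b->gates.push_back(gate_from_list(gates[k], n_nodes));
  XPtr<BrainC> ptr(b, true);
  return ptr;
}

static BrainC *get_brain(SEXP p) {
  XPtr<BrainC> ptr(p);
  return ptr.get();
}

// [[Rcpp::export]]
void cpp_reset_brain(SEXP p) {
  BrainC *b = get_brain(p);
  std::fill(b->state.begin(), b->state.end(), 0);
  for (size_t k = 0; k < b->gates.size(); ++k) {
    GateC &g = b->gates[k];
    if (g.kind != 0) g.P = g.Pbirth;
    g.hist.clear();
  }
}

// [[Rcpp::export]]
void cpp_set_feedback(SEXP p, bool flag) { get_brain(p)->feedback_enabled = flag; }

// [[Rcpp::export]]
bool cpp_get_feedback(SEXP p) { return get_brain(p)->feedback_enabled; }

// [[Rcpp::export]]
IntegerVector cpp_brain_state(SEXP p) {
  BrainC *b = get_brain(p);
  return wrap(b->state);
}

// [[Rcpp::export]]
IntegerVector cpp_brain_step(SEXP p, IntegerVector sensors, double seed) {
  BrainC *b = get_brain(p);
  MbRng rng(seed);
  int s[4] = {0, 0, 0, 0};
  for (int k = 0; k < 4 && k < sensors.size(); ++k) s[k] = sensors[k] ? 1 : 0;
  brain_step_c(*b, s, rng);
  return IntegerVector::create(b->state[4], b->state[5]);
}

// [[Rcpp::export]]
List cpp_gate_tables(SEXP p) {
  BrainC *b = get_brain(p);
  List out(b->gates.size());
  for (size_t k = 0; k < b->gates.size(); ++k) {
    GateC &g = b->gates[k];
    List e;
    if (g.kind == 0) {
      e = List::create(_["kind"] = "deterministic", _["table"] = wrap(g.dtable));
    } else {
      NumericMatrix P(g.rows, g.cols), Pb(g.rows, g.cols);
      for (int i = 0; i < g.rows; ++i)
        for (int c = 0; c < g.cols; ++c) {
          P(i, c) = g.P[i * g.cols + c];
          Pb(i, c) = g.Pbirth[i * g.cols + c];
        }
      IntegerMatrix H((int)g.hist.size(), 2);
      for (int h = 0; h < (int)g.hist.size(); ++h) {
        H(h, 0) = g.hist[h].first;
        H(h, 1) = g.hist[h].second;
      }
      e = List::create(
        _["kind"] = g.kind == 1 ? "probabilistic" : "feedback",
        _["table"] = P, _["table_birth"] = Pb, _["history"] = H);
    }
    out[k] = e;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Episode: T updates on one option-to-action mapping. Action codes:
// 0 forward, 1 nothing, 2 turn-left, 3 turn-right.
// [[Rcpp::export]]
List cpp_evaluate_mapping(SEXP p, IntegerVector action_map, int T, double b,
                          double seed, bool reset, bool want_trace,
                          Nullable<List> maze, int size, double fill,
                          int spawn_dist, int max_tries) {
  BrainC *br = get_brain(p);
  MbRng rng(seed);
  MazeC m;
  if (maze.isNotNull()) m = maze_from_list(maze.get());
  else m = maze_generate(rng, size, fill, spawn_dist, max_tries);
  if (m.spawns.empty()) stop("maze has no tile at the spawn distance");
  if (reset) {
    std::fill(br->state.begin(), br->state.end(), 0);
    for (size_t k = 0; k < br->gates.size(); ++k) {
      GateC &g = br->gates[k];
      if (g.kind != 0) g.P = g.Pbirth;
      g.hist.clear();
    }
  }
  int pos = m.spawns[rng.randint((int)m.spawns.size())];
  int heading = rng.randint(4);
  double score = 0.0;
  int goals = 0;
  IntegerVector action_counts(4);
  IntegerMatrix trace(want_trace ? T : 0, 7);
  for (int t = 0; t < T; ++t) {
    int s[4] = {0, 0, 0, 0};
    int ar = m.arrow[pos];
    if (ar >= 0) s[(ar - heading + 4) % 4] = 1;
    brain_step_c(*br, s, rng);
    int option = br->state[4] + 2 * br->state[5]; // node 4 = low bit
    int action = action_map[option];
    action_counts[action]++;
    if (action == 0) {
      int x = pos % m.size + DX[heading], y = pos / m.size + DY[heading];
      int ni = y * m.size + x;
      if (!m.walls[ni]) pos = ni;
    } else if (action == 2) heading = (heading + 3) % 4;
    else if (action == 3) heading = (heading + 1) % 4;
    int d = m.dist[pos];
    score += 1.0 / (1.0 + d);
    if (want_trace) {
      trace(t, 0) = t + 1;
      trace(t, 1) = pos % m.size + 1;
      trace(t, 2) = pos / m.size + 1;
      trace(t, 3) = heading;
      trace(t, 4) = option;
      trace(t, 5) = action;
      trace(t, 6) = d;
    }
    if (pos == m.goal) {
      ++goals;
      pos = m.spawns[rng.randint((int)m.spawns.size())];
      heading = rng.randint(4);
    }
  }
  score += goals * b;
  List fb_tables = List::create();
  std::vector<int> fb_idx;
  for (size_t k = 0; k < br->gates.size(); ++k)
    if (br->gates[k].kind == 2) fb_idx.push_back((int)k);
  List tabs((int)fb_idx.size());
  IntegerVector which_fb((int)fb_idx.size());
  for (int k = 0; k < (int)fb_idx.size(); ++k) {
    GateC &g = br->gates[fb_idx[k]];
    NumericMatrix P(g.rows, g.cols);
    for (int i = 0; i < g.rows; ++i)
      for (int c = 0; c < g.cols; ++c) P(i, c) = g.P[i * g.cols + c];
    tabs[k] = P;
    which_fb[k] = fb_idx[k] + 1;
  }
  List out = List::create(
    _["score"] = score, _["goal_count"] = goals,
    _["action_counts"] = action_counts, _["fb_tables"] = tabs,
    _["fb_gates"] = which_fb);
  if (want_trace) out["trace"] = trace;
  return out;
}
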