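// Exact event-driven simulation of the continuous-time Markov SIR process
// on a static undirected graph. On infection of v at time t, v's recovery
// time is drawn Exp(gamma); for each currently susceptible neighbor u a
// first-transmission time Exp(beta) is drawn and the infection event
// (t + Exp(beta), u) is scheduled only if it precedes v's recovery. Events
// are delivered in time order and discarded if the target is no longer
// susceptible. Because reinfection is impossible, keeping only the first
// transmission attempt per directed edge is an exact reduction of the
// per-edge Poisson processes.
//
// RNG: one xorshift128+ stream per (seed node, run), seeded via splitmix64
// from the root seed, so results do not depend on the order in which nodes
// or runs are executed.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xorshift128p {
  uint64_t s0, s1;
  explicit Xorshift128p(uint64_t seed) {
    uint64_t x = seed;
    s0 = splitmix64_next(x);
    s1 = splitmix64_next(x);
    if ((s0 | s1) == 0) s1 = 0x1ULL;
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double expo(double rate) {
    return -std::log(1.0 - unif()) / rate;
  }
};

static inline uint64_t stream_seed(uint64_t root, uint64_t node, uint64_t run) {
  uint64_t x = root;
  uint64_t h = splitmix64_next(x);
  x = h ^ (node * 0xD6E8FEB86659FD93ULL + 0x9E3779B97F4A7C15ULL);
  h = splitmix64_next(x);
  x = h ^ (run * 0xCA5A826395121157ULL + 0x165667B19E3779F9ULL);
  return splitmix64_next(x);
}

typedef std::pair<double, int> Event;

static int run_outbreak(const std::vector<int> &ptr, const std::vector<int> &idx,
                        int seed_node, double beta, double gamma,
                        Xorshift128p &rng,
                        std::vector<uint8_t> &state, std::vector<int> &touched) {
  std::priority_queue<Event, std::vector<Event>, std::greater<Event> > q;
  int size = 0;

  // infect seed
  {
    state[seed_node] = 1;
    touched.push_back(seed_node);
    ++size;
    double rec = rng.expo(gamma);
    for (int e = ptr[seed_node]; e < ptr[seed_node + 1]; ++e) {
      int u = idx[e];
      double tt = rng.expo(beta);
      if (tt < rec) q.push(Event(tt, u));
    }
  }

  while (!q.empty()) {
    Event ev = q.top();
    q.pop();
    int v = ev.second;
    if (state[v] != 0) continue;
    double t = ev.first;
    state[v] = 1;
    touched.push_back(v);
    ++size;
    double rec = t + rng.expo(gamma);
    for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
      int u = idx[e];
      if (state[u] == 0) {
        double tt = t + rng.expo(beta);
        if (tt < rec) q.push(Event(tt, u));
      }
    }
  }

  for (size_t i = 0; i < touched.size(); ++i) state[touched[i]] = 0;
  touched.clear();
  return size;
}

// Outbreak sizes for `runs` independent realizations seeded at one node.
// ptr/idx: CSR adjacency (0-based); seed_node 0-based.
// [[Rcpp::export]]
IntegerVector sir_outbreaks_cpp(IntegerVector ptr, IntegerVector idx,
                                int seed_node, int runs,
                                double beta, double gamma, double root_seed) {
  std::vector<int> p(ptr.begin(), ptr.end());
  std::vector<int> a(idx.begin(), idx.end());
  int n = (int)p.size() - 1;
  if (seed_node < 0 || seed_node >= n) stop("seed node out of range");
  std::vector<uint8_t> state(n, 0);
  std::vector<int> touched;
  touched.reserve(n);
  IntegerVector out(runs);
  uint64_t root = (uint64_t)root_seed;
  for (int r = 0; r < runs; ++r) {
    if ((r & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    Xorshift128p rng(stream_seed(root, (uint64_t)seed_node, (uint64_t)r));
    out[r] = run_outbreak(p, a, seed_node, beta, gamma, rng, state, touched);
  }
  return out;
}

// Mean and sample SD of outbreak size for each seed node in `seeds`
// (0-based). Returns an n x 2 matrix (mean, sd).
// [[Rcpp::export]]
NumericMatrix sir_influence_cpp(IntegerVector ptr, IntegerVector idx,
                                IntegerVector seeds, int runs,
                                double beta, double gamma, double root_seed) {
  std::vector<int> p(ptr.begin(), ptr.end());
  std::vector<int> a(idx.begin(), idx.end());
  int n = (int)p.size() - 1;
  std::vector<uint8_t> state(n, 0);
  std::vector<int> touched;
  touched.reserve(n);
  uint64_t root = (uint64_t)root_seed;
  NumericMatrix out(seeds.size(), 2);
  for (int i = 0; i < seeds.size(); ++i) {
    int s = seeds[i];
    if (s < 0 || s >= n) stop("seed node out of range");
    double sum = 0.0, sumsq = 0.0;
    for (int r = 0; r < runs; ++r) {
      if ((r & 0x3FF) == 0) Rcpp::checkUserInterrupt();
      Xorshift128p rng(stream_seed(root, (uint64_t)s, (uint64_t)r));
      int sz = run_outbreak(p, a, s, beta, gamma, rng, state, touched);
      sum += sz;
      sumsq += (double)sz * sz;
    }
    double mean = sum / runs;
    double sd = runs > 1 ? std::sqrt(std::max(0.0, (sumsq - runs * mean * mean) / (runs - 1))) : 0.0;
    out(i, 0) = mean;
    out(i, 1) = sd;
  }
  return out;
}
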