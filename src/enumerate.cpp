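#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// A cassette state is a signed element-id vector; flanking loxP sites are
// implied (they always alternate and the leftmost site survives every
// event). Key format matches R's canonical_key(): "+1-3+2".

static std::string state_key(const std::vector<int> &s) {
  std::string k;
  k.reserve(s.size() * 3);
  for (int v : s) {
    k += (v > 0 ? '+' : '-');
    k += std::to_string(v > 0 ? v : -v);
  }
  return k;
}

// Append all legal children of s to out. Sites are 1..n+1; the gap between
// sites i<j is the sum of intervening element lengths plus one loxP length
// per intervening site. Odd spans join opposite-orientation sites
// (inversion), even spans same-orientation sites (excision). Excisions
// that would remove a required element id are skipped (used for targeted
// complexity search; required ids can never be lost to an inversion).
static void expand_state(const std::vector<int> &s,
                         const std::vector<int> &len, int loxp, int min_dist,
                         const std::vector<bool> &required,
                         std::vector<std::vector<int>> &out) {
  const int n = (int)s.size();
  std::vector<int> cum(n + 1, 0);
  for (int k = 0; k < n; ++k)
    cum[k + 1] = cum[k] + len[std::abs(s[k]) - 1];
  for (int i = 1; i <= n; ++i) {
    for (int j = i + 1; j <= n + 1; ++j) {
      const int gap = cum[j - 1] - cum[i - 1] + loxp * (j - i - 1);
      if (gap < min_dist) continue;
      const bool inversion = ((j - i) % 2) == 1;
      std::vector<int> t;
      if (inversion) {
        t.reserve(n);
        for (int k = 0; k < i - 1; ++k) t.push_back(s[k]);
        for (int k = j - 2; k >= i - 1; --k) t.push_back(-s[k]);
        for (int k = j - 1; k < n; ++k) t.push_back(s[k]);
      } else {
        bool ok = true;
        for (int k = i - 1; k <= j - 2 && ok; ++k)
          if (required[std::abs(s[k]) - 1]) ok = false;
        if (!ok) continue;
        t.reserve(n - (j - i));
        for (int k = 0; k < i - 1; ++k) t.push_back(s[k]);
        for (int k = j - 1; k < n; ++k) t.push_back(s[k]);
      }
      out.push_back(std::move(t));
    }
  }
}

// Breadth-first closure from the unrecombined reference. Generation-
// synchronous, so the first generation at which a key appears is its
// complexity (minimal number of recombination events).
//
// max_depth < 0 means unbounded (run to the fixed point). If the table
// would exceed max_states an error is thrown. target_keys, when
// non-empty, are looked up as the table grows; with stop_at_targets the
// search ends after the first complete generation in which all targets
// have been seen (depths of any still-unseen targets are NA).
// [[Rcpp::export]]
List cpp_enumerate(IntegerVector element_lengths, int loxp_length,
                   int min_dist, int max_depth, double max_states,
                   IntegerVector required_ids, CharacterVector target_keys,
                   bool stop_at_targets) {
  const int n = element_lengths.size();
  std::vector<int> len(element_lengths.begin(), element_lengths.end());
  std::vector<bool> required(n, false);
  for (int id : required_ids) {
    if (id < 1 || id > n) stop("required id out of range");
    required[id - 1] = true;
  }

  std::unordered_map<std::string, int> seen;
  std::vector<std::string> keys_out;
  std::vector<int> depth_out, size_out;

  std::unordered_map<std::string, int> want;
  for (int i = 0; i < target_keys.size(); ++i)
    want[as<std::string>(target_keys[i])] = i;
  IntegerVector target_depth(target_keys.size(), NA_INTEGER);
  int n_found = 0;

  std::vector<int> ref(n);
  for (int k = 0; k < n; ++k) ref[k] = k + 1;
  std::vector<std::vector<int>> frontier{ref};
  {
    std::string k0 = state_key(ref);
    seen.emplace(k0, 0);
    keys_out.push_back(k0);
    depth_out.push_back(0);
    size_out.push_back(n);
    auto it = want.find(k0);
    if (it != want.end()) { target_depth[it->second] = 0; ++n_found; }
  }

  int depth = 0;
  bool closed = false;
  while (!frontier.empty()) {
    if (stop_at_targets && target_depth.size() > 0 &&
        n_found == (int)target_depth.size()) break;
    if (max_depth >= 0 && depth >= max_depth) break;
    ++depth;
    std::vector<std::vector<int>> next;
    std::vector<std::vector<int>> children;
    for (const auto &s : frontier) {
      children.clear();
      expand_state(s, len, loxp_length, min_dist, required, children);
      for (auto &t : children) {
        std::string k = state_key(t);
        auto ins = seen.emplace(std::move(k), depth);
        if (ins.second) {
          keys_out.push_back(ins.first->first);
          depth_out.push_back(depth);
          size_out.push_back((int)t.size());
          auto it = want.find(ins.first->first);
          if (it != want.end()) { target_depth[it->second] = depth; ++n_found; }
          next.push_back(std::move(t));
        }
      }
      if ((double)seen.size() > max_states)
        stop("state count exceeded max_states (%.0f); raise the cap or bound the depth", max_states);
    }
    if (next.empty()) { closed = true; break; }
    frontier = std::move(next);
    Rcpp::checkUserInterrupt();
  }
  if (max_depth >= 0 && depth >= max_depth && !frontier.empty()) {
    // depth cap reached with unexpanded frontier: not known to be closed
    closed = false;
  }

  return List::create(
      _["key"] = wrap(keys_out), _["complexity"] = wrap(depth_out),
      _["size"] = wrap(size_out), _["closed"] = closed,
      _["max_depth_built"] = depth, _["target_depth"] = target_depth);
}
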