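// Core engine: flat-coded typed expressions, best-first enumeration of
// stochastic execution paths, prefix likelihood, and PCFG sampling.
//
// Expressions are encoded pre-order as integer opcode vectors; the layout
// must match the R-side table built in R/context.R:
//   1 pair(S,C)->S     2 first(S)->C     3 rest(S)->S     4 insert(S,S)->S
//   5 append(S,S)->S   6 flip(P)->B      7 equals(S,S)->B 8 empty(S)->B
//   9 if:S            10 if:SET         11 if:P          12 and  13 or  14 not
//  15 union           16 setminus       17 {s}           18 sample(SET)->S
//  19 eps             20 x              21 Sigma         22..26 prob consts
//  27..58 alphabet characters           59..62 F0..F3    63..66 Fm0..Fm3
// Types: 1=STRING 2=CHAR 3=BOOL 4=STRSET 5=PROB

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <queue>
#include <string>
#include <vector>

using namespace Rcpp;

static const int OP_PAIR = 1, OP_FIRST = 2, OP_REST = 3, OP_INSERT = 4,
                 OP_APPEND = 5, OP_FLIP = 6, OP_EQUALS = 7, OP_EMPTY = 8,
                 OP_IFS = 9, OP_IFT = 10, OP_IFP = 11, OP_AND = 12,
                 OP_OR = 13, OP_NOT = 14, OP_UNION = 15, OP_SETMINUS = 16,
                 OP_SETSINGLE = 17, OP_SAMPLE = 18, OP_EPS = 19, OP_X = 20,
                 OP_SIGMA = 21, OP_PROB0 = 22, OP_CHAR0 = 27, OP_F0 = 59,
                 OP_FM0 = 63, OP_MAX = 66;

static const double PROB_CONSTS[5] = {0.25, 1.0 / 3.0, 0.5, 2.0 / 3.0, 0.75};

static const int T_STR = 1, T_CHAR = 2, T_BOOL = 3, T_SET = 4, T_PROB = 5;

struct OpInfo {
  int arity;
  int ret;
  int child[2];
};

// Static signature table; character/prob/factor blocks handled by range.
static OpInfo op_info(int op) {
  switch (op) {
    case OP_PAIR:      return {2, T_STR,  {T_STR, T_CHAR}};
    case OP_FIRST:     return {1, T_CHAR, {T_STR, 0}};
    case OP_REST:      return {1, T_STR,  {T_STR, 0}};
    case OP_INSERT:    return {2, T_STR,  {T_STR, T_STR}};
    case OP_APPEND:    return {2, T_STR,  {T_STR, T_STR}};
    case OP_FLIP:      return {1, T_BOOL, {T_PROB, 0}};
    case OP_EQUALS:    return {2, T_BOOL, {T_STR, T_STR}};
    case OP_EMPTY:     return {1, T_BOOL, {T_STR, 0}};
    case OP_IFS:       return {3, T_STR,  {T_BOOL, T_STR}};   // 3rd = 2nd
    case OP_IFT:       return {3, T_SET,  {T_BOOL, T_SET}};
    case OP_IFP:       return {3, T_PROB, {T_BOOL, T_PROB}};
    case OP_AND:       return {2, T_BOOL, {T_BOOL, T_BOOL}};
    case OP_OR:        return {2, T_BOOL, {T_BOOL, T_BOOL}};
    case OP_NOT:       return {1, T_BOOL, {T_BOOL, 0}};
    case OP_UNION:     return {2, T_SET,  {T_SET, T_SET}};
    case OP_SETMINUS:  return {2, T_SET,  {T_SET, T_STR}};
    case OP_SETSINGLE: return {1, T_SET,  {T_STR, 0}};
    case OP_SAMPLE:    return {1, T_STR,  {T_SET, 0}};
    case OP_EPS:       return {0, T_STR,  {0, 0}};
    case OP_X:         return {0, T_STR,  {0, 0}};
    case OP_SIGMA:     return {0, T_SET,  {0, 0}};
    default:
      if (op >= OP_PROB0 && op < OP_PROB0 + 5) return {0, T_PROB, {0, 0}};
      if (op >= OP_CHAR0 && op < OP_CHAR0 + 32) return {0, T_CHAR, {0, 0}};
      if (op >= OP_F0 && op < OP_F0 + 4) return {1, T_STR, {T_STR, 0}};
      if (op >= OP_FM0 && op < OP_FM0 + 4) return {1, T_STR, {T_STR, 0}};
      stop("unknown opcode %d", op);
  }
}

static int child_type(const OpInfo& oi, int j) {
  if (oi.arity == 3) return j == 0 ? oi.child[0] : oi.child[1];
  return oi.child[j];
}

// end position (one past) of the subtree rooted at pos
static int subtree_end(const std::vector<int>& code, int pos) {
  int need = 1, i = pos;
  while (need > 0) {
    need += op_info(code[i]).arity - 1;
    ++i;
  }
  return i;
}

// ---------------------------------------------------------------------------
// Path-enumeration machinery

struct Val {
  int tag = T_STR;
  std::string s;
  bool b = false;
  double p = 0.0;
  std::vector<std::string> set;  // kept sorted & unique
};

// Run status: 0 = ok, 1 = hit a fresh choice point (fork), 2 = path error
static const int ST_OK = 0, ST_FORK = 1, ST_ERR = 2;

struct RunCtx {
  const std::vector<std::vector<int>>* factors;
  const std::vector<std::string>* sigma;
  const std::vector<int>* prefix;   // recorded choices to replay
  size_t cidx = 0;
  double logp = 0.0;
  long steps = 0;
  int depth = 0;
  int status = ST_OK;
  long max_steps;
  int max_rec;
  long max_len;                      // string length cap
  long* work;                        // total steps across all replays
  std::vector<double>* fork_probs;   // branch log-probs of a fresh choice
  std::map<std::pair<int, std::string>, Val> memo;
};

// returns the branch index, or -1 when the run must stop (fork)
static int take_choice(RunCtx& rc, const std::vector<double>& branch_logp) {
  if (branch_logp.size() == 1) return 0;  // forced choice, probability one
  if (rc.cidx < rc.prefix->size()) {
    int b = (*rc.prefix)[rc.cidx++];
    rc.logp += branch_logp[b];
    return b;
  }
  *rc.fork_probs = branch_logp;
  rc.status = ST_FORK;
  return -1;
}

static bool count_step(RunCtx& rc) {
  ++(*rc.work);
  if (++rc.steps > rc.max_steps) {
    rc.status = ST_ERR;
    return false;
  }
  return true;
}

static Val eval_node(const std::vector<int>& code, int& pos,
                     const std::string& x, RunCtx& rc);

static Val eval_factor(int idx, const std::string& arg, RunCtx& rc) {
  if (++rc.depth > rc.max_rec) {
    rc.status = ST_ERR;
    return Val();
  }
  int pos = 0;
  Val v = eval_node((*rc.factors)[idx], pos, arg, rc);
  --rc.depth;
  return v;
}

static std::string as_string(const Val& v) {
  // CHAR values promote to one-character strings where a string is required
  return v.s;
}

#define EVAL_CHILD(var)                              \
  Val var = eval_node(code, pos, x, rc);             \
  if (rc.status != ST_OK) return Val();

static Val eval_node(const std::vector<int>& code, int& pos,
                     const std::string& x, RunCtx& rc) {
  int op = code[pos++];
  OpInfo oi = op_info(op);
  (void)oi;
  if (!count_step(rc)) return Val();
  Val out;
  switch (op) {
    case OP_PAIR: {
      EVAL_CHILD(l)
      EVAL_CHILD(c)
      out.tag = T_STR;
      out.s = l.s + c.s;
      if ((long)out.s.size() > rc.max_len) rc.status = ST_ERR;
      return out;
    }
    case OP_FIRST: {
      EVAL_CHILD(l)
      if (l.s.empty()) { rc.status = ST_ERR; return out; }
      out.tag = T_CHAR;
      out.s = l.s.substr(0, 1);
      return out;
    }
    case OP_REST: {
      EVAL_CHILD(l)
      if (l.s.empty()) { rc.status = ST_ERR; return out; }
      out.tag = T_STR;
      out.s = l.s.substr(1);
      return out;
    }
    case OP_INSERT: {
      // insert(A,B): B goes into the middle of A, split at floor(|A|/2)
      EVAL_CHILD(a)
      EVAL_CHILD(b)
      size_t mid = a.s.size() / 2;
      out.tag = T_STR;
      out.s = a.s.substr(0, mid) + b.s + a.s.substr(mid);
      if ((long)out.s.size() > rc.max_len) rc.status = ST_ERR;
      return out;
    }
    case OP_APPEND: {
      EVAL_CHILD(a)
      EVAL_CHILD(b)
      out.tag = T_STR;
      out.s = a.s + b.s;
      if ((long)out.s.size() > rc.max_len) rc.status = ST_ERR;
      return out;
    }
    case OP_FLIP: {
      EVAL_CHILD(p)
      std::vector<double> lp = {std::log(p.p), std::log1p(-p.p)};
      int b = take_choice(rc, lp);
      if (b < 0) return out;
      out.tag = T_BOOL;
      out.b = (b == 0);
      return out;
    }
    case OP_EQUALS: {
      EVAL_CHILD(a)
      EVAL_CHILD(b)
      out.tag = T_BOOL;
      out.b = (a.s == b.s);
      return out;
    }
    case OP_EMPTY: {
      EVAL_CHILD(a)
      out.tag = T_BOOL;
      out.b = a.s.empty();
      return out;
    }
    case OP_IFS:
    case OP_IFT:
    case OP_IFP: {
      EVAL_CHILD(cond)
      if (cond.b) {
        EVAL_CHILD(v)
        pos = subtree_end(code, pos);  // skip unevaluated alternative
        return v;
      }
      pos = subtree_end(code, pos);
      return eval_node(code, pos, x, rc);
    }
    case OP_AND: {
      EVAL_CHILD(a)
      if (!a.b) {                      // short circuit: skip second argument
        pos = subtree_end(code, pos);
        out.tag = T_BOOL;
        out.b = false;
        return out;
      }
      return eval_node(code, pos, x, rc);
    }
    case OP_OR: {
      EVAL_CHILD(a)
      if (a.b) {
        pos = subtree_end(code, pos);
        out.tag = T_BOOL;
        out.b = true;
        return out;
      }
      return eval_node(code, pos, x, rc);
    }
    case OP_NOT: {
      EVAL_CHILD(a)
      out.tag = T_BOOL;
      out.b = !a.b;
      return out;
    }
    case OP_UNION: {
      EVAL_CHILD(a)
      EVAL_CHILD(b)
      out.tag = T_SET;
      out.set = a.set;
      out.set.insert(out.set.end(), b.set.begin(), b.set.end());
      std::sort(out.set.begin(), out.set.end());
      out.set.erase(std::unique(out.set.begin(), out.set.end()),
                    out.set.end());
      return out;
    }
    case OP_SETMINUS: {
      EVAL_CHILD(a)
      EVAL_CHILD(b)
      out.tag = T_SET;
      for (const auto& e : a.set)
        if (e != b.s) out.set.push_back(e);
      return out;
    }
    case OP_SETSINGLE: {
      EVAL_CHILD(a)
      out.tag = T_SET;
      out.set.push_back(a.s);
      return out;
    }
    case OP_SAMPLE: {
      EVAL_CHILD(sv)
      if (sv.set.empty()) { rc.status = ST_ERR; return out; }
      std::vector<double> lp(sv.set.size(),
                             -std::log((double)sv.set.size()));
      int b = take_choice(rc, lp);
      if (b < 0) return out;
      out.tag = T_STR;
      out.s = sv.set[b];
      return out;
    }
    case OP_EPS: {
      out.tag = T_STR;
      return out;
    }
    case OP_X: {
      out.tag = T_STR;
      out.s = x;
      return out;
    }
    case OP_SIGMA: {
      out.tag = T_SET;
      out.set = *rc.sigma;
      return out;
    }
    default: {
      if (op >= OP_PROB0 && op < OP_PROB0 + 5) {
        out.tag = T_PROB;
        out.p = PROB_CONSTS[op - OP_PROB0];
        return out;
      }
      if (op >= OP_CHAR0 && op < OP_CHAR0 + 32) {
        out.tag = T_CHAR;
        out.s = (*rc.sigma)[op - OP_CHAR0];
        return out;
      }
      if (op >= OP_F0 && op < OP_F0 + 4) {
        EVAL_CHILD(a)
        return eval_factor(op - OP_F0, a.s, rc);
      }
      if (op >= OP_FM0 && op < OP_FM0 + 4) {
        EVAL_CHILD(a)
        std::pair<int, std::string> key(op - OP_FM0, a.s);
        auto hit = rc.memo.find(key);
        if (hit != rc.memo.end()) return hit->second;
        Val v = eval_factor(op - OP_FM0, a.s, rc);
        if (rc.status == ST_OK) rc.memo[key] = v;
        return v;
      }
      stop("unknown opcode %d", op);
    }
  }
}

// Choice prefixes live in a parent-pointer trie so frontier items are
// constant size; the prefix is reconstructed on pop.
struct TrieNode {
  int parent;  // -1 for root
  int branch;
  int depth;
};
struct FrontierItem {
  double logp;
  long seq;
  int node;  // index into the trie (-1 = empty prefix)
};
struct FrontierCmp {  // max logp first; FIFO among ties
  bool operator()(const FrontierItem& a, const FrontierItem& b) const {
    if (a.logp != b.logp) return a.logp < b.logp;
    return a.seq > b.seq;
  }
};

struct EnumResult {
  std::vector<std::string> outputs;
  std::vector<double> probs;
  double unexplored = 0.0;
  double error = 0.0;
  std::vector<double> path_probs;  // completed-path probabilities, in order
  long n_paths = 0;
};

static EnumResult enumerate_paths(const std::vector<std::vector<int>>& factors,
                                  int entry, const std::string& input,
                                  const std::vector<std::string>& sigma,
                                  double min_log_prob, int max_rec,
                                  long max_steps, int max_outputs,
                                  long max_paths, long max_work,
                                  long max_len) {
  EnumResult res;
  std::map<std::string, double> outcome;
  std::priority_queue<FrontierItem, std::vector<FrontierItem>, FrontierCmp> pq;
  std::vector<TrieNode> trie;
  std::vector<int> prefix;
  std::vector<double> fork_probs;
  long seq = 0;
  long work = 0;
  pq.push({0.0, seq++, -1});
  bool truncated = false;
  while (!pq.empty()) {
    FrontierItem it = pq.top();
    pq.pop();
    if (it.logp < min_log_prob) {
      res.unexplored += std::exp(it.logp);
      continue;
    }
    if (res.n_paths >= max_paths || work >= max_work) {
      res.unexplored += std::exp(it.logp);
      truncated = true;
      continue;
    }
    ++res.n_paths;
    int depth = it.node < 0 ? 0 : trie[it.node].depth;
    prefix.resize(depth);
    for (int n = it.node; n >= 0; n = trie[n].parent)
      prefix[trie[n].depth - 1] = trie[n].branch;
    RunCtx rc;
    rc.factors = &factors;
    rc.sigma = &sigma;
    rc.prefix = &prefix;
    rc.max_steps = max_steps;
    rc.max_rec = max_rec;
    rc.max_len = max_len;
    rc.work = &work;
    rc.fork_probs = &fork_probs;
    int pos = 0;
    Val v = eval_node(factors[entry], pos, input, rc);
    if (rc.status == ST_OK) {
      double p = std::exp(it.logp);
      bool is_new = outcome.find(v.s) == outcome.end();
      outcome[v.s] += p;
      res.path_probs.push_back(p);
      if (is_new && (int)outcome.size() >= max_outputs) {
        while (!pq.empty()) {
          res.unexplored += std::exp(pq.top().logp);
          pq.pop();
        }
        break;
      }
    } else if (rc.status == ST_FORK) {
      for (size_t b = 0; b < fork_probs.size(); ++b) {
        double nlp = it.logp + fork_probs[b];
        if (nlp < min_log_prob) {
          res.unexplored += std::exp(nlp);
        } else {
          trie.push_back({it.node, (int)b, depth + 1});
          pq.push({nlp, seq++, (int)trie.size() - 1});
        }
      }
    } else {
      res.error += std::exp(it.logp);
    }
  }
  (void)truncated;
  // outputs sorted by probability desc, then length, then lexicographic
  std::vector<std::pair<std::string, double>> v(outcome.begin(), outcome.end());
  std::stable_sort(v.begin(), v.end(),
                   [](const std::pair<std::string, double>& a,
                      const std::pair<std::string, double>& b) {
                     if (a.second != b.second) return a.second > b.second;
                     if (a.first.size() != b.first.size())
                       return a.first.size() < b.first.size();
                     return a.first < b.first;
                   });
  for (auto& kv : v) {
    res.outputs.push_back(kv.first);
    res.probs.push_back(kv.second);
  }
  return res;
}

static std::vector<std::vector<int>> factors_from_list(List factors) {
  std::vector<std::vector<int>> out;
  for (int i = 0; i < factors.size(); ++i) {
    IntegerVector cv = factors[i];
    out.emplace_back(cv.begin(), cv.end());
  }
  return out;
}

static std::vector<std::string> sigma_from_cv(CharacterVector sigma) {
  std::vector<std::string> out;
  for (int i = 0; i < sigma.size(); ++i) out.push_back(as<std::string>(sigma[i]));
  return out;
}

// [[Rcpp::export]]
List cpp_enumerate(List factors, int entry, std::string input,
                   CharacterVector sigma, double min_log_prob,
                   int max_recursion, int max_steps, int max_outputs,
                   int max_paths, double max_work, int max_length) {
  std::vector<std::vector<int>> fac = factors_from_list(factors);
  std::vector<std::string> sg = sigma_from_cv(sigma);
  EnumResult r =
      enumerate_paths(fac, entry - 1, input, sg, min_log_prob, max_recursion,
                      max_steps, max_outputs, max_paths, (long)max_work,
                      (long)max_length);
  return List::create(
      _["outputs"] = wrap(r.outputs), _["probs"] = wrap(r.probs),
      _["unexplored"] = r.unexplored, _["error"] = r.error,
      _["path_probs"] = wrap(r.path_probs), _["n_paths"] = r.n_paths);
}

// ---------------------------------------------------------------------------
// Prefix likelihood: delete then append, per-character rates

static double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static double transform_ll(const std::string& d, const std::string& o,
                           double del, double gam, int nsigma) {
  int lo = (int)o.size(), ld = (int)d.size();
  double lg_del = del > 0 ? std::log(del) : R_NegInf;
  double lg_keep = std::log1p(-del);
  double lg_app = gam > 0 ? std::log(gam / nsigma) : R_NegInf;
  double lg_stop = std::log1p(-gam);
  double total = R_NegInf;
  int lcp = 0;                  // longest common prefix of d and o
  while (lcp < lo && lcp < ld && o[lcp] == d[lcp]) ++lcp;
  for (int k = lo - std::min(lcp, ld); k <= lo; ++k) {
    int keep = lo - k;          // surviving prefix length of o (<= lcp)
    int m = ld - keep;          // appended characters
    if (m < 0) continue;
    // deletion part: del^k (1-del) for k < |o|; del^|o| once everything is
    // gone (nothing left to try to delete), which normalises the channel
    double lp = 0.0;
    if (k > 0) {
      if (del == 0) continue;
      lp += k * lg_del;
    }
    if (k < lo) lp += lg_keep;
    if (m > 0) {
      if (gam == 0) continue;
      lp += m * lg_app;
    }
    lp += lg_stop;
    total = logsumexp2(total, lp);
  }
  return total;
}

// [[Rcpp::export]]
double cpp_transform_ll(std::string d, std::string o, double del, double gam,
                        int nsigma) {
  return transform_ll(d, o, del, gam, nsigma);
}

static double data_ll(const EnumResult& r,
                      const std::vector<std::string>& dstr,
                      const std::vector<double>& dcnt, double del, double gam,
                      int nsigma) {
  if (r.outputs.empty()) return R_NegInf;
  double total = 0.0;
  std::vector<double> lg_out(r.probs.size());
  for (size_t i = 0; i < r.probs.size(); ++i) lg_out[i] = std::log(r.probs[i]);
  for (size_t j = 0; j < dstr.size(); ++j) {
    double tok = R_NegInf;
    for (size_t i = 0; i < r.outputs.size(); ++i) {
      tok = logsumexp2(tok,
                       lg_out[i] + transform_ll(dstr[j], r.outputs[i], del,
                                                gam, nsigma));
    }
    if (tok == R_NegInf) return R_NegInf;
    total += dcnt[j] * tok;
  }
  return total;
}

// [[Rcpp::export]]
double cpp_data_loglik(CharacterVector outputs, NumericVector probs,
                       CharacterVector dstrings, NumericVector dcounts,
                       double del, double gam, int nsigma) {
  EnumResult r;
  r.outputs = sigma_from_cv(outputs);
  r.probs = std::vector<double>(probs.begin(), probs.end());
  std::vector<std::string> ds = sigma_from_cv(dstrings);
  std::vector<double> dc(dcounts.begin(), dcounts.end());
  return data_ll(r, ds, dc, del, gam, nsigma);
}

// Enumerate + likelihood in one call (MCMC hot path)
// [[Rcpp::export]]
double cpp_score(List factors, int entry, CharacterVector sigma,
                 double min_log_prob, int max_recursion, int max_steps,
                 int max_outputs, int max_paths, double max_work,
                 int max_length, CharacterVector dstrings,
                 NumericVector dcounts, double del, double gam) {
  std::vector<std::vector<int>> fac = factors_from_list(factors);
  std::vector<std::string> sg = sigma_from_cv(sigma);
  EnumResult r = enumerate_paths(fac, entry - 1, "", sg, min_log_prob,
                                 max_recursion, max_steps, max_outputs,
                                 max_paths, (long)max_work, (long)max_length);
  std::vector<std::string> ds = sigma_from_cv(dstrings);
  std::vector<double> dc(dcounts.begin(), dcounts.end());
  return data_ll(r, ds, dc, del, gam, (int)sg.size());
}

// ---------------------------------------------------------------------------
// PCFG sampling over flat codes (uses R's RNG stream)

// gspec: list of 5 elements (by type id); each is list(ops = integer vector,
// prob = normalised production probabilities)
// [[Rcpp::export]]
IntegerVector cpp_sample_code(List gspec, int type, int max_depth) {
  std::vector<int> out;
  // explicit stack of (type, depth)
  std::vector<std::pair<int, int>> todo;
  todo.push_back({type, 0});
  while (!todo.empty()) {
    std::pair<int, int> t = todo.back();
    todo.pop_back();
    if (t.second > max_depth) stop("lot_depth_error");
    List spec = gspec[t.first - 1];
    IntegerVector ops = spec["ops"];
    NumericVector prob = spec["prob"];
    if (ops.size() == 0) stop("no productions for nonterminal type %d", t.first);
    double u = unif_rand(), acc = 0.0;
    int op = ops[ops.size() - 1];
    for (int i = 0; i < ops.size(); ++i) {
      acc += prob[i];
      if (u <= acc) {
        op = ops[i];
        break;
      }
    }
    out.push_back(op);
    OpInfo oi = op_info(op);
    for (int j = oi.arity - 1; j >= 0; --j)
      todo.push_back({child_type(oi, j), t.second + 1});
  }
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export]]
IntegerVector cpp_subtree_end(IntegerVector code, int pos) {
  std::vector<int> c(code.begin(), code.end());
  return IntegerVector::create(subtree_end(c, pos - 1) + 1);  // 1-based, past
}

// return type of every node (for proposal site typing)
// [[Rcpp::export]]
IntegerVector cpp_node_types(IntegerVector code) {
  IntegerVector out(code.size());
  for (int i = 0; i < code.size(); ++i) out[i] = op_info(code[i]).ret;
  return out;
}
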