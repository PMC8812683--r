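# Shared fixtures: canonical worked-example programs, a small suite of
# stochastic programs for enumerator-vs-sampler checks, and independent
# re-derivations used as oracles.

EPS <- "\u03f5"
SIG <- "\u03a3"

# the geometric a^n generator: F0(x) := pair(if(flip(1/3), eps, F0(eps)), a)
an_hypothesis <- function() {
  ctx <- lot_context("a", 1)
  lot_hypothesis(list(sprintf("pair(if(flip(1/3),%s,F0(%s)),a)", EPS, EPS)),
                 ctx)
}

# three-factor composition: F0 = a^n, F1 appends one b per input character,
# F2 = F1(F0(eps)) generates a^n b^n
anbn_hypothesis <- function() {
  ctx <- lot_context(c("a", "b"), 3)
  lot_hypothesis(list(
    sprintf("pair(if(flip(1/3),%s,F0(%s)),a)", EPS, EPS),
    sprintf("if(empty(x),%s,append(pair(%s,first(x)),pair(F1(rest(x)),b)))",
            EPS, EPS),
    sprintf("F1(F0(%s))", EPS)), ctx)
}

# Marcus ABB: F0(x) := append(append(sample(S), x), x); F1(x) := Fm0(sample(S))
abb_hypothesis <- function(alphabet = c("a", "b", "c", "d")) {
  ctx <- lot_context(alphabet, 2)
  lot_hypothesis(list(
    sprintf("append(append(sample(%s),x),x)", SIG),
    sprintf("Fm0(sample(%s))", SIG)), ctx)
}

# twelve small stochastic programs (entry evaluated at x = eps)
stochastic_program_suite <- function() {
  ctx2 <- lot_context(c("a", "b"), 1)
  ctx2f <- lot_context(c("a", "b"), 2)
  p <- function(txt, ctx) lot_hypothesis(as.list(txt), ctx)
  list(
    an = an_hypothesis(),
    geom_half = p(sprintf("pair(if(flip(1/2),%s,F0(%s)),b)", EPS, EPS), ctx2),
    flip_quarter = p(sprintf("if(flip(1/4),pair(%s,a),pair(%s,b))", EPS, EPS),
                     ctx2),
    two_samples = p(sprintf("append(sample(%s),sample(%s))", SIG, SIG), ctx2),
    memo_pair = p(c(sprintf("sample(%s)", SIG),
                    sprintf("append(Fm0(%s),Fm0(%s))", EPS, EPS)), ctx2f),
    fresh_pair = p(c(sprintf("sample(%s)", SIG),
                     sprintf("append(F0(%s),F0(%s))", EPS, EPS)), ctx2f),
    abb = abb_hypothesis(c("a", "b")),
    half_error = p(sprintf("if(flip(1/2),pair(%s,first(%s)),pair(%s,a))",
                           EPS, EPS, EPS), ctx2),
    set_ops = p(sprintf("sample(union({pair(%s,a)},setminus(%s,a)))",
                        EPS, SIG), ctx2),
    insert_rand = p(sprintf("insert(append(sample(%s),sample(%s)),sample(%s))",
                            SIG, SIG, SIG), ctx2),
    bool_mix = p(sprintf(
      "if(or(flip(1/4),and(flip(1/2),flip(2/3))),pair(%s,a),sample(%s))",
      EPS, SIG), ctx2),
    sum_geom = p(c(sprintf("pair(if(flip(1/4),F0(%s),%s),a)", EPS, EPS),
                   sprintf("append(F0(%s),F0(%s))", EPS, EPS)), ctx2f)
  )
}

# total-variation distance between enumerated outcomes and MC frequencies,
# treating error mass as its own category
tv_enum_vs_mc <- function(od, mc) {
  keys <- union(names(od$outcomes), names(mc$freq))
  p <- od$outcomes[keys]; p[is.na(p)] <- 0
  q <- mc$freq[keys]; q[is.na(q)] <- 0
  0.5 * (sum(abs(p - q)) + abs(od$error_mass + od$unexplored_mass -
                                 mc$error_rate))
}

# literal re-derivation of posterior-weighted precision/recall from sets:
# hyps = list of list(topk=, support=, weight=); reference semantics mirror
# the definitions, written independently of the package implementation
brute_force_pr <- function(hyps, data_strings, data_topk) {
  precision <- 0; recall <- 0
  for (h in hyps) {
    inter_p <- 0
    for (s in h$topk) if (s %in% data_strings) inter_p <- inter_p + 1
    inter_r <- 0
    for (s in data_topk) if (s %in% h$support) inter_r <- inter_r + 1
    precision <- precision + h$weight * inter_p / length(h$topk)
    recall <- recall + h$weight * inter_r / length(data_topk)
  }
  c(precision = precision, recall = recall)
}

# forward simulation of the noise process itself (delete from the end each
# with prob delta until a failure or the string is gone, then append
# uniform characters each with prob gamma): an independent process-level
# oracle for the closed-form transform likelihood
noise_channel_sample <- function(o, delta, gamma, sigma) {
  s <- o
  while (nchar(s) > 0) {
    if (runif(1) < delta) s <- substr(s, 1, nchar(s) - 1) else break
  }
  while (runif(1) < gamma) {
    s <- paste0(s, sigma[floor(runif(1) * length(sigma)) + 1])
  }
  s
}

noise_channel_mc <- function(d, o, delta, gamma, sigma, n = 2e5) {
  hits <- 0
  for (i in seq_len(n)) {
    if (noise_channel_sample(o, delta, gamma, sigma) == d) hits <- hits + 1
  }
  hits / n
}
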