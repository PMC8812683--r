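test_that("posterior-weighted precision and recall follow the weighted-average rule", {
  ctx <- lot_context(c("a", "b"), 1)
  g <- expression_grammar(ctx)
  nm <- noise_model()
  mk_entry <- function(txt) {
    h <- lot_hypothesis(list(txt), ctx)
    list(codes = h$codes, lp = log_prior(h, g),
         ll = data_log_likelihood(run_program(h), as_dataset("a"), nm, 2))
  }
  # a single hypothesis whose top strings equal the data's string set
  a_only <- posterior_set(list(mk_entry(sprintf("pair(%s,a)", EPS))), ctx)
  pr <- posterior_precision_recall(a_only, as_dataset(c("a", "a")),
                                   eval_config())
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  expect_equal(pr$f, 1)
})

test_that("a half-weight perfect and half-weight partial hypothesis mix to P=1, R=0.6", {
  # direct weighted-average identity on constructed sets
  data_strings <- c("u", "v", "w", "y", "z")
  # one perfect hypothesis (P = R = 1) and one with P = 1, R = 0.2
  hyps <- list(list(topk = data_strings, support = data_strings, weight = 0.5),
               list(topk = c("u"), support = c("u"), weight = 0.5))
  pr <- brute_force_pr(hyps, data_strings, data_topk = data_strings)
  expect_equal(unname(pr["precision"]), 1)
  expect_equal(unname(pr["recall"]), 0.6)
  hyps2 <- list(list(topk = c("u"), support = "u", weight = 0.5),
                list(topk = c("u", "q"), support = c("u", "q"), weight = 0.5))
  pr2 <- brute_force_pr(hyps2, data_strings, data_strings)
  expect_equal(unname(pr2["precision"]), 0.75)  # q falls outside the data
})

test_that("an overgeneraliser shows high recall and depressed precision", {
  ctx <- lot_context(c("a", "b"), 1)
  g <- expression_grammar(ctx)
  nm <- noise_model()
  t <- get_language("an")
  D <- as_dataset(c("a", "aa", "aa", "aaa", "a"))
  sig_plus <- lot_hypothesis(list(sprintf(
    "pair(if(flip(1/3),%s,F0(%s)),first(sample(%s)))", EPS, EPS, SIG)), ctx)
  ps <- posterior_set(list(list(
    codes = sig_plus$codes, lp = log_prior(sig_plus, g),
    ll = data_log_likelihood(run_program(sig_plus), D, nm, 2))), ctx)
  cfg <- eval_config(k_top = 5L)
  pr_data <- posterior_precision_recall(ps, D, cfg, reference = "data")
  expect_lt(pr_data$precision, 1)  # top strings contain b-strings
  pr_tgt <- posterior_precision_recall(ps, D, cfg, target = t)
  expect_lt(pr_tgt$precision, 1)
  expect_equal(pr_tgt$recall, 1)  # every a^k is in its support
})

test_that("the implementation equals a brute-force re-derivation on random fixtures", {
  set.seed(141)
  ctx <- lot_context(c("a", "b"), 1)
  g <- expression_grammar(ctx)
  nm <- noise_model()
  pool <- c(sprintf("pair(%s,a)", EPS),
            sprintf("pair(%s,b)", EPS),
            sprintf("pair(pair(%s,a),b)", EPS),
            sprintf("append(sample(%s),x)", SIG),
            sprintf("pair(if(flip(1/3),%s,F0(%s)),a)", EPS, EPS),
            sprintf("pair(if(flip(1/2),%s,F0(%s)),b)", EPS, EPS),
            sprintf("append(sample(%s),sample(%s))", SIG, SIG))
  cfg <- eval_config(k_top = 4L)
  for (rep in 1:40) {
    txts <- sample(pool, sample(2:4, 1))
    D <- as_dataset(sample(c("a", "b", "ab", "ba", "aab", "bb"),
                           sample(3:8, 1), replace = TRUE))
    entries <- lapply(txts, function(txt) {
      h <- lot_hypothesis(list(txt), ctx)
      list(codes = h$codes, lp = log_prior(h, g),
           ll = data_log_likelihood(run_program(h), D, nm, 2))
    })
    ps <- posterior_set(entries, ctx)
    got <- posterior_precision_recall(ps, D, cfg, reference = "data")
    hyps <- lapply(seq_len(nrow(ps$entries)), function(i) {
      od <- run_program(lotlang:::hypothesis_from_codes(ps$codes[[i]], ctx))
      list(topk = head(names(od$outcomes), cfg$k_top),
           support = names(od$outcomes), weight = ps$entries$weight[i])
    })
    want <- brute_force_pr(hyps, unique(D$strings),
                           lotlang:::data_top_k(D, cfg$k_top))
    expect_equal(got$precision, unname(want["precision"]), tolerance = 1e-12)
    expect_equal(got$recall, unname(want["recall"]), tolerance = 1e-12)
  }
})

test_that("the memorisation baseline scores the data multiset against the target", {
  t <- get_language("anbn")
  cfg <- eval_config()
  mem <- memorized_f(as_dataset(c("ab", "ab", "ab")), t, cfg)
  expect_equal(mem$precision, 1)
  expect_equal(mem$recall, 1 / 25)
  expect_equal(mem$f, 2 * (1 / 25) / (1 + 1 / 25), tolerance = 1e-12)
  # a dataset containing the full target top-k memorises perfectly
  tk <- top_k_strings(t, 25)
  mem2 <- memorized_f(as_dataset(tk$strings), t, cfg)
  expect_equal(mem2$f, 1)
})

test_that("memorised F grows with data in expectation", {
  t <- get_language("anbncn")
  cfg <- eval_config()
  set.seed(151)
  f_at <- function(n) mean(vapply(1:3, function(s)
    memorized_f(sample_dataset(t, n), t, cfg)$f, 0))
  fs <- c(f_at(5), f_at(100), f_at(5000))
  expect_true(all(diff(fs) > 0))
})

test_that("a perfect generating program is an F = 1 fixed point", {
  ctx <- lot_context(c("a", "b"), 1)
  g <- expression_grammar(ctx)
  t <- get_language("an")
  D <- sample_dataset(t, 20, seed = 163)
  h <- an_hypothesis()
  ps <- posterior_set(list(list(codes = h$codes, lp = -1, ll = -1)),
                      h$context)
  pr <- posterior_precision_recall(ps, D, eval_config(), target = t)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  expect_equal(pr$f, 1)
})

test_that("generalisation matrices drop seen probes and expose -Inf for unreachable ones", {
  ctx <- lot_context("a", 1)
  h <- an_hypothesis()
  const <- lot_hypothesis(list(sprintf("pair(%s,a)", EPS)), ctx)
  ps <- posterior_set(list(
    list(codes = h$codes, lp = -2, ll = -1),
    list(codes = const$codes, lp = -1, ll = -4)), ctx)
  D <- as_dataset(c("a", "aa"))
  probes <- c("a", strrep("a", 6), strrep("a", 40))
  expect_warning(m <- generalization_matrix(ps, D, probes),
                 "present in the data")
  expect_equal(colnames(m), c(strrep("a", 6), strrep("a", 40)))
  # geometric law for the unseen a^6 under the a^n hypothesis
  i_an <- which(is.finite(m[, 1]))[1]
  expect_equal(unname(m[i_an, 1]), 5 * log(2 / 3) + log(1 / 3),
               tolerance = 1e-9)
  # a^40 is below the enumeration floor; the constant generator reaches nothing
  expect_true(all(m[, 2] == -Inf))
  const_row <- which(apply(m, 1, function(r) all(r == -Inf)))
  expect_gte(length(const_row), 1L)
  # rows sorted by posterior weight
  w <- attr(m, "weights")
  expect_true(all(diff(w) <= 0))
})

test_that("learning-curve rows satisfy the bounds and harmonic identity", {
  t <- get_language("an")
  cfg <- eval_config()
  curve <- learning_curve(t, cfg, inference_config(steps = 300L),
                          n_factors_set = 1L, seed = 3, max_tokens = 5)
  expect_equal(curve$n_tokens, c(1, 2, 5))
  for (i in seq_len(nrow(curve))) {
    expect_true(all(unlist(curve[i, c("precision", "recall", "f",
                                      "memorized_f")]) >= 0))
    expect_true(all(unlist(curve[i, c("precision", "recall", "f",
                                      "memorized_f")]) <= 1))
    p <- curve$precision[i]; r <- curve$recall[i]
    expect_equal(curve$f[i], if (p + r == 0) 0 else 2 * p * r / (p + r),
                 tolerance = 1e-12)
  }
})
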