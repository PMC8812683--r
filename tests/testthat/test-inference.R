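test_that("root regeneration is an independent prior draw with the matching Hastings ratio", {
  set.seed(91)
  ctx <- lot_context("a", 1)
  g <- expression_grammar(ctx)
  h <- lot_hypothesis(list(EPS), ctx)  # single-node hypothesis: root always picked
  for (i in 1:200) {
    pr <- propose(h, g)
    if (!pr$ok) next
    # q(h'|h) = P(h') and q(h|h') = P(h)/n' : the ratio telescopes to
    # log P(h) - log P(h') - log n'
    n2 <- length(lotlang:::expr_to_code(pr$hypothesis$factors[[1]]))
    expect_equal(pr$log_hastings,
                 log_prior(h, g) - log_prior(pr$hypothesis, g) - log(n2),
                 tolerance = 1e-9)
  }
})

test_that("accepted proposals are reversible (reverse density positive)", {
  set.seed(101)
  g <- expression_grammar(lot_context(c("a", "b"), 1))
  h <- lot_hypothesis(list(sprintf("pair(if(flip(1/3),%s,F0(%s)),a)",
                                   EPS, EPS)), g$context)
  state <- list(codes = h$codes)
  n_checked <- 0L
  for (i in 1:3000) {
    pr <- lotlang:::propose_codes(state$codes, g)
    if (!pr$ok) next
    expect_true(is.finite(pr$log_hastings))  # reverse move has positive density
    n_checked <- n_checked + 1L
    if (i %% 7 == 0) state$codes <- pr$codes  # drift around the space
  }
  expect_gt(n_checked, 2000L)
})

test_that("proposals reject hypotheses with unreachable factors", {
  set.seed(111)
  ctx <- lot_context(c("a", "b"), 2)
  g <- expression_grammar(ctx)
  h <- lot_hypothesis(list(sprintf("sample(%s)", SIG),
                           sprintf("append(F0(%s),F0(%s))", EPS, EPS)), ctx)
  saw_reject <- FALSE
  for (i in 1:500) {
    pr <- propose(h, g)
    if (!pr$ok) {
      saw_reject <- TRUE
      next
    }
    codes <- pr$hypothesis$codes
    expect_true(lotlang:::all_factors_reachable(codes, 2L))
  }
  expect_true(saw_reject)  # dropping the F0 call must be rejected sometimes
})

test_that("the proposal chain reaches the whole restricted expression space", {
  # chain-shaped space: STRING -> eps | pair(STRING, a)
  set.seed(121)
  ctx <- lot_context("a", 1)
  g <- expression_grammar(ctx, include = c("pair", EPS, "a"))
  code <- lotlang:::sample_code(g)
  seen <- new.env(parent = emptyenv())
  for (i in 1:2000) {
    pr <- lotlang:::propose_codes(list(code), g)
    if (pr$ok) code <- pr$codes[[1]]
    seen[[paste(code, collapse = ",")]] <- TRUE
  }
  # the six smallest programs (eps, a, aa, ..., a^5 builders) all visited
  expect_gte(length(ls(seen)), 6L)
})

test_that("the MH rule always accepts dominating symmetric proposals", {
  ctx <- lot_context("a", 1)
  g <- expression_grammar(ctx)
  cfg <- inference_config()
  D <- as_dataset(c("a", "a", "aa"))
  h_good <- lot_hypothesis(list(sprintf("pair(%s,a)", EPS)), ctx)
  st <- lotlang:::new_chain_state(h_good$codes, g, D$strings, D$counts, cfg, 1)
  # acceptance log-ratio with equal scores and symmetric q is 0 => accept
  expect_true(is.finite(st$log_likelihood))
  # and the stored scores match recomputation
  expect_equal(st$log_prior, log_prior(h_good, g))
  expect_equal(st$log_likelihood,
               data_log_likelihood(run_program(h_good, bounds = cfg$bounds),
                                   D, cfg$noise, 1))
})

test_that("long MH runs recover the exact posterior on a restricted space", {
  # restricted space: the chain eps, pair(eps,a), pair(pair(eps,a),a), ...
  # (the a^k constant programs); posterior computable in closed form
  set.seed(131)
  ctx <- lot_context("a", 1)
  g <- expression_grammar(ctx, include = c("pair", EPS, "a"))
  cfg <- inference_config()
  D <- as_dataset(c("a", "aa"))
  nm <- cfg$noise

  p_pair <- with(g$productions$STRING, prob[ops == 1L])
  p_eps <- with(g$productions$STRING, prob[ops == 19L])
  kmax <- 60L
  log_post <- vapply(0:kmax, function(k) {
    lp <- k * log(p_pair) + log(p_eps)  # CHAR has a single production
    o <- strrep("a", k)
    ll <- sum(vapply(rep(D$strings, D$counts), function(d)
      string_transform_loglik(d, o, nm, 1), 0))
    lp + ll
  }, 0)
  post <- exp(log_post - max(log_post))
  post <- post / sum(post)

  st <- lotlang:::new_chain_state(
    lot_hypothesis(list(EPS), ctx)$codes, g, D$strings, D$counts, cfg, 1)
  n_steps <- 30000L
  ks <- integer(n_steps)
  for (i in seq_len(n_steps)) {
    st <- lotlang:::mh_step_fast(st, D$strings, D$counts, g, cfg, NULL)
    ks[i] <- (length(st$codes[[1]]) - 1L) %/% 2L
  }
  ks <- ks[-(1:2000)]  # burn-in
  emp <- tabulate(ks + 1L, nbins = kmax + 1L) / length(ks)
  tv <- 0.5 * sum(abs(emp - post))
  expect_lt(tv, 0.03)
})

test_that("tempered swaps at equal temperature always succeed and seeds reproduce runs", {
  t <- get_language("an")
  D <- sample_dataset(t, 5, seed = 3)
  g <- expression_grammar(lot_context("a", 1))
  cfg <- inference_config(steps = 400L, n_chains = 2L, temp_range = c(1, 1),
                          swap_every = 50L)
  ps1 <- run_parallel_tempering(D, g, cfg, seed = 17)
  ps2 <- run_parallel_tempering(D, g, cfg, seed = 17)
  expect_identical(ps1$entries$factors, ps2$entries$factors)
  expect_identical(ps1$entries$weight, ps2$entries$weight)
  expect_equal(sum(ps1$entries$weight), 1, tolerance = 1e-9)
  # the swap acceptance rule degenerates to 1 at equal temperatures
  la <- (1 / 1 - 1 / 1) * (-3.2 - (-50))
  expect_equal(la, 0)
})

# the search trims the string-length cap to the data; mirror that here
run_bounds_of <- function(cfg, D) {
  b <- cfg$bounds
  b$max_length <- min(b$max_length, max(nchar(D$strings)) + 32L)
  b
}

test_that("stored posterior-set scores equal recomputation", {
  t <- get_language("an")
  D <- sample_dataset(t, 5, seed = 23)
  g <- expression_grammar(lot_context("a", 1))
  cfg <- inference_config(steps = 600L)
  ps <- run_parallel_tempering(D, g, cfg, seed = 29)
  idx <- sample(nrow(ps$entries), min(50L, nrow(ps$entries)))
  for (i in idx) {
    h <- lotlang:::hypothesis_from_codes(ps$codes[[i]], ps$context)
    expect_equal(ps$entries$log_prior[i], log_prior(h, g), tolerance = 1e-9)
    sc <- lotlang:::score_ll(ps$codes[[i]], g, D$strings, D$counts,
                             run_bounds_of(cfg, D), cfg$noise)
    expect_equal(ps$entries$log_likelihood[i], sc, tolerance = 1e-9)
  }
})

test_that("factor-count searches merge with joint renormalisation", {
  t <- get_language("an")
  D <- sample_dataset(t, 5, seed = 37)
  cfg <- inference_config(steps = 400L, top_n = 50L)
  res <- search_over_factor_counts(D, "a", n_factors_set = 1:2, cfg = cfg,
                                   seed = 41)
  expect_named(res$by_n, c("1", "2"))
  m <- res$merged
  expect_equal(sum(m$entries$weight), 1, tolerance = 1e-9)
  expect_lte(nrow(m$entries), 50L)
  # merging preserves the relative ordering of unnormalised scores
  sc <- m$entries$log_prior + m$entries$log_likelihood
  expect_true(all(diff(sc) <= 1e-9))
  # weights proportional to exp(score)
  w <- exp(sc - max(sc))
  expect_equal(m$entries$weight, w / sum(w), tolerance = 1e-9)
})

test_that("posterior sets serialise to JSON lines", {
  t <- get_language("an")
  D <- sample_dataset(t, 3, seed = 43)
  ps <- run_parallel_tempering(D, expression_grammar(lot_context("a", 1)),
                               inference_config(steps = 300L), seed = 47)
  path <- tempfile(fileext = ".jsonl")
  write_posterior_set(ps, path)
  lines <- readLines(path, encoding = "UTF-8")
  expect_equal(length(lines), nrow(ps$entries))
  rec <- jsonlite::fromJSON(lines[1])
  expect_named(rec, c("rank", "n_factors", "factors", "log_prior",
                      "log_likelihood", "weight"), ignore.order = TRUE)
})
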