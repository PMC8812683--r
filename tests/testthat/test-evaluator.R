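test_that("single primitives reproduce the worked string examples", {
  expect_equal(apply_primitive("insert", list("abcd", "efg"))$value,
               "abefgcd")
  expect_equal(apply_primitive("append", list("", "xyz"))$value, "xyz")
  expect_equal(apply_primitive("pair", list("ab", "c"))$value, "abc")
  expect_equal(apply_primitive("first", list("abc"))$value, "a")
  expect_equal(apply_primitive("rest", list("abc"))$value, "bc")
  br <- apply_primitive("sample", list(c("a", "b", "c")))
  expect_equal(br$kind, "branches")
  expect_equal(vapply(br$branches, `[[`, 0, "prob"), rep(1 / 3, 3))
  fl <- apply_primitive("flip", list(1 / 3))
  expect_equal(fl$branches[[1]]$value, TRUE)
  expect_equal(fl$branches[[1]]$prob, 1 / 3)
  expect_error(apply_primitive("first", list("")),
               class = "lot_empty_string_error")
  expect_error(apply_primitive("sample", list(character(0))),
               class = "lot_empty_set_error")
})

test_that("the geometric a^n program yields its exact law", {
  od <- run_program(an_hypothesis())
  for (n in seq_along(od$outcomes)) {
    expect_equal(od$outcomes[[strrep("a", n)]], (2 / 3)^(n - 1) / 3,
                 tolerance = 1e-12)
  }
  expect_equal(sum(od$outcomes) + od$unexplored_mass + od$error_mass, 1,
               tolerance = 1e-9)
  # enumeration reaches exactly the strings above the probability floor
  expect_gt(length(od$outcomes), 30)
})

test_that("deterministic programs concentrate all mass on one string", {
  ctx <- lot_context("a", 1)
  h <- lot_hypothesis(list("pair(x,a)"), ctx)
  od <- run_program(h)
  expect_equal(od$outcomes, c(a = 1))
  expect_equal(od$unexplored_mass, 0)
  expect_equal(od$error_mass, 0)
})

test_that("the three-factor composition generates a^n b^n and F1 appends b per character", {
  h <- anbn_hypothesis()
  od1 <- run_program(h, input = "xyz", factor = 2)
  expect_equal(names(od1$outcomes), "xyzbbb")
  od <- run_program(h)
  ns <- seq_along(od$outcomes)
  expect_true(all(names(od$outcomes) %in%
                    paste0(strrep("a", 1:40), strrep("b", 1:40))))
  top <- sort(od$outcomes, decreasing = TRUE)
  expect_equal(top[["ab"]], 1 / 3, tolerance = 1e-12)
  expect_equal(top[["aabb"]], 2 / 9, tolerance = 1e-12)
})

test_that("runtime errors and caps become error mass", {
  ctx <- lot_context("a", 1)
  od <- run_program(lot_hypothesis(list(sprintf("pair(%s,first(%s))",
                                                EPS, EPS)), ctx))
  expect_equal(od$error_mass, 1)
  expect_equal(length(od$outcomes), 0L)
  # unbounded deterministic recursion hits the recursion cap
  od2 <- run_program(lot_hypothesis(list("F0(x)"), ctx))
  expect_equal(od2$error_mass, 1)
})

test_that("memoised factor calls replay recorded choices; fresh calls do not", {
  ctx <- lot_context(c("a", "b"), 2)
  memo <- lot_hypothesis(list(sprintf("sample(%s)", SIG),
                              sprintf("append(Fm0(%s),Fm0(%s))", EPS, EPS)),
                         ctx)
  od <- run_program(memo)
  expect_equal(sort(names(od$outcomes)), c("aa", "bb"))
  expect_equal(unname(od$outcomes[c("aa", "bb")]), c(0.5, 0.5))
  fresh <- lot_hypothesis(list(sprintf("sample(%s)", SIG),
                               sprintf("append(F0(%s),F0(%s))", EPS, EPS)),
                          ctx)
  od2 <- run_program(fresh)
  expect_equal(sort(names(od2$outcomes)), c("aa", "ab", "ba", "bb"))
  expect_equal(max(abs(od2$outcomes - 0.25)), 0, tolerance = 1e-12)
})

test_that("the Marcus ABB hypothesis only produces sigma1 sigma2 sigma2", {
  h <- abb_hypothesis()
  od <- run_program(h)
  expect_true(all(nchar(names(od$outcomes)) == 3L))
  expect_true(all(substr(names(od$outcomes), 2, 2) ==
                    substr(names(od$outcomes), 3, 3)))
  expect_equal(sum(od$outcomes), 1, tolerance = 1e-9)
  mc <- monte_carlo_run(h, n_samples = 3000L, seed = 9)
  expect_true(all(substr(names(mc$freq), 2, 2) == substr(names(mc$freq), 3, 3)))
})

test_that("completed path probabilities are emitted in nonincreasing order", {
  set.seed(51)
  g <- expression_grammar(lot_context(c("a", "b"), 1))
  for (i in 1:200) {
    code <- tryCatch(lotlang:::sample_code(g),
                     lot_depth_error = function(err) NULL)
    if (is.null(code)) next
    h <- lotlang:::hypothesis_from_codes(list(code), g$context)
    od <- run_program(h)
    if (length(od$path_probs) > 1L)
      expect_true(all(diff(od$path_probs) <= 1e-12))
    total <- sum(od$outcomes) + od$unexplored_mass + od$error_mass
    expect_lte(total, 1 + 1e-9)
    if (od$n_paths < eval_bounds()$max_paths &&
        od$unexplored_mass < 1e-12)  # frontier exhausted
      expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("enumerated outcomes agree with forward-sampling frequencies", {
  suite <- stochastic_program_suite()
  set.seed(61)
  for (nm in c("flip_quarter", "two_samples", "memo_pair", "half_error")) {
    h <- suite[[nm]]
    od <- run_program(h)
    mc <- monte_carlo_run(h, n_samples = 20000L)
    expect_lt(tv_enum_vs_mc(od, mc), 0.02)
  }
})

test_that("output distributions serialise to sorted JSON lines", {
  od <- run_program(an_hypothesis())
  path <- tempfile(fileext = ".jsonl")
  write_output_dist(od, path)
  lines <- readLines(path, encoding = "UTF-8")
  expect_equal(length(lines), length(od$outcomes) + 1L)
  rec1 <- jsonlite::fromJSON(lines[1])
  expect_equal(rec1$string, "a")
  expect_equal(rec1$probability, 1 / 3, tolerance = 1e-9)
  probs <- vapply(lines[-length(lines)],
                  function(l) jsonlite::fromJSON(l)$probability, 0)
  expect_true(all(diff(probs) <= 0))
})
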