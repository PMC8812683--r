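test_that("the registry provides the full core set of target languages", {
  reg <- language_registry()
  core <- c("an", "a123", "abn", "sigma_plus", "anbn", "anbncn", "anbncndn",
            "anbm", "anb2n", "dyck", "mirror", "copy", "anbmcndm",
            "anbmanbmccc", "chinese_numeral", "count", "golden_mean",
            "aplus_b_aplus", "marcus_aba", "marcus_abb", "gomez2", "gomez6",
            "gomez12", "newport_aslin", "saffran", "reber", "berwick_pilato",
            "morgan_newport", "reeder", "english")
  expect_true(all(core %in% names(reg)))
  expect_gte(length(reg), 28L)
  expect_error(get_language("nope"), class = "lot_key_error")
})

test_that("membership answers the canonical cases", {
  expect_true(language_membership("anbn", "aabb"))
  expect_false(language_membership("anbn", "aab"))
  expect_false(language_membership("anbn", ""))
  expect_true(all(language_membership("dyck", c("ab", "aabb", "abab"))))
  expect_false(any(language_membership("dyck", c("ba", "aab", "a"))))
  expect_true(language_membership("mirror", "abba"))
  expect_false(language_membership("mirror", "abab"))
  expect_true(language_membership("copy", "abab"))
  expect_true(language_membership("count", "ababb"))
  expect_false(language_membership("count", "abbab"))
  expect_true(language_membership("chinese_numeral", "abbbab"))
  expect_false(language_membership("chinese_numeral", "ababb"))
  expect_true(language_membership("saffran", "tapirogolabu"))
  expect_false(language_membership("saffran", "tapirogo"))
  expect_true(all(language_membership("berwick_pilato",
                                      c("v", "mv", "mhbv", "hbv"))))
  expect_false(any(language_membership("berwick_pilato", c("m", "vm", "mm"))))
  expect_true(language_membership("english", "nv"))        # S -> NP VP
  expect_true(language_membership("english", "dnvtnv"))    # embedding
  expect_true(language_membership("english", "danpdanvtnv"))
  expect_false(language_membership("english", "vn"))
})

test_that("samplers agree with membership and are seed reproducible", {
  reg <- language_registry()
  for (nm in names(reg)) {
    t <- reg[[nm]]
    D <- sample_dataset(t, 300, seed = 53)
    expect_true(all(language_membership(t, rep(D$strings, 1))), info = nm)
    expect_true(all(unlist(strsplit(D$strings, "")) %in% t$alphabet),
                info = nm)
    D2 <- sample_dataset(t, 300, seed = 53)
    expect_identical(rep(D$strings, D$counts), rep(D2$strings, D2$counts),
                     info = nm)
  }
})

test_that("top-k enumeration matches closed forms for parametric families", {
  tk <- top_k_strings("an", 3)
  expect_equal(tk$strings, c("a", "aa", "aaa"))
  expect_equal(tk$probs, c(1 / 3, 2 / 9, 4 / 27), tolerance = 1e-12)
  tk2 <- top_k_strings("anbn", 4)
  expect_equal(tk2$strings, c("ab", "aabb", "aaabbb", "aaaabbbb"))
  expect_equal(tk2$probs, (2 / 3)^(0:3) / 3, tolerance = 1e-12)
  tk3 <- top_k_strings("a123", 3)
  expect_equal(tk3$strings, c("a", "aa", "aaa"))
  expect_equal(tk3$probs, c(9, 6, 4) / 19, tolerance = 1e-12)
  # k = 1 on an unambiguous family is its shortest string
  expect_equal(top_k_strings("anbncn", 1)$strings, "abc")
  # finite languages return their whole support when k exceeds it
  expect_equal(sort(top_k_strings("marcus_abb", 100)$strings),
               sort(as.character(outer(c("a", "b", "c", "d"),
                                       c("a", "b", "c", "d"),
                                       function(A, B) paste0(A, B, B)))))
})

test_that("top-k probabilities are nonincreasing and bounded by one in total", {
  for (nm in c("an", "sigma_plus", "dyck", "reber", "saffran", "english")) {
    tk <- top_k_strings(nm, 15)
    expect_true(all(diff(tk$probs) <= 1e-12), info = nm)
    expect_lte(sum(tk$probs), 1 + 1e-9)
    t <- get_language(nm)
    expect_true(all(language_membership(t, tk$strings)), info = nm)
  }
})

test_that("English top strings all parse under the grammar", {
  tk <- top_k_strings("english", 100, min_log_prob = -14)
  expect_gte(length(tk$strings), 50L)
  t <- get_language("english")
  expect_true(all(language_membership(t, tk$strings)))
})

test_that("empirical string frequencies rank-correlate with top-k probabilities", {
  # languages whose top-10 probabilities are strictly decreasing (rank
  # correlation is ill-defined under exact ties, as in the uniform finite
  # stimuli, which are covered by the closed-form checks above)
  for (nm in c("an", "abn", "anbn", "anbncn", "anb2n", "count")) {
    t <- get_language(nm)
    D <- sample_dataset(t, 10000, seed = 59)
    tk <- top_k_strings(t, 10)
    emp <- vapply(tk$strings, function(s) {
      i <- match(s, D$strings)
      if (is.na(i)) 0 else D$counts[i] / D$n_tokens
    }, 0)
    tau <- stats::cor(emp, tk$probs, method = "kendall")
    expect_gt(tau, 0.9)
  }
})

test_that("Reeder training never emits held-out strings but membership accepts them", {
  t <- get_language("reeder")
  held <- t$extra$held_out
  D <- sample_dataset(t, 3000, seed = 61)
  expect_false(any(held %in% D$strings))
  expect_true(all(language_membership(t, held)))
})

test_that("the Saffran stream contains lexicon words as contiguous substrings", {
  t <- get_language("saffran")
  D <- sample_dataset(t, 500, seed = 67)
  toks <- rep(D$strings, D$counts)
  hits <- mean(grepl("tapiro", toks, fixed = TRUE))
  # one word in four, about 1.5 words per utterance
  expect_gt(hits, 0.15)
  n_one <- sum(nchar(toks) == 6L)
  expect_gt(n_one / length(toks), 0.15)  # geometric length, stop prob 1/3
})

test_that("dataset sizes and degenerate cases behave", {
  D <- sample_dataset("an", 1, seed = 71)
  expect_equal(D$n_tokens, 1)
  expect_error(sample_dataset("an", 0), class = "lot_config_error")
  expect_error(top_k_strings("an", 0), class = "lot_config_error")
  # mean repetition index is 1/p = 3 under the geometric length law
  D2 <- sample_dataset("anbn", 4000, seed = 73)
  mean_n <- sum(nchar(rep(D2$strings, D2$counts))) / 2 / D2$n_tokens
  expect_equal(mean_n, 3, tolerance = 0.15)
})
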