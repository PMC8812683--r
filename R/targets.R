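# Target languages: each is a sampler + top-k enumerator + membership test.
# Samplers are written against the chooser interface so that the same
# generator yields i.i.d. samples (random chooser) and exact best-first
# top-k enumeration (replay chooser). String lengths / repetition indices
# are geometric with stop probability 1/3 unless noted.

new_language <- function(name, alphabet, gen, membership, ...) {
  structure(list(name = name, alphabet = sort(alphabet), gen = gen,
                 membership = membership, extra = list(...)),
            class = "lot_language")
}

#' @export
print.lot_language <- function(x, ...) {
  cat(sprintf("<lot_language> %s over {%s}\n", x$name,
              paste(x$alphabet, collapse = ",")))
  invisible(x)
}

# geometric repetition index: P(n) = (1-p)^(n-1) p, n >= 1
geom_index <- function(ch, p = 1 / 3) {
  n <- 1L
  while (ch$flip(1 - p)) n <- n + 1L
  n
}

chars_of <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# generic CYK membership for binarised CFGs:
# term_rules: named list lhs -> character vector of terminals
# bin_rules: list of c(lhs, r1, r2)
cyk_member <- function(s, term_rules, bin_rules, start) {
  cs <- chars_of(s)
  n <- length(cs)
  if (n == 0L) return(FALSE)
  cell <- vector("list", n * n)
  at <- function(i, l) (l - 1L) * n + i  # start i, length l
  for (i in seq_len(n)) {
    syms <- character(0)
    for (lhs in names(term_rules))
      if (cs[i] %in% term_rules[[lhs]]) syms <- c(syms, lhs)
    cell[[at(i, 1L)]] <- syms
  }
  if (n > 1L) {
    for (l in 2:n) {
      for (i in seq_len(n - l + 1L)) {
        syms <- character(0)
        for (sp in seq_len(l - 1L)) {
          left <- cell[[at(i, sp)]]
          right <- cell[[at(i + sp, l - sp)]]
          if (!length(left) || !length(right)) next
          for (r in bin_rules) {
            if (r[2] %in% left && r[3] %in% right) syms <- c(syms, r[1])
          }
        }
        cell[[at(i, l)]] <- unique(syms)
      }
    }
  }
  start %in% cell[[at(1L, n)]]
}

# word-decomposition membership (Saffran-style lexicon concatenations)
lexicon_member <- function(s, words) {
  n <- nchar(s)
  if (n == 0L) return(FALSE)
  ok <- c(TRUE, rep(FALSE, n))
  for (i in seq_len(n)) {
    if (!ok[i]) next
    for (w in words) {
      lw <- nchar(w)
      if (i + lw - 1L <= n && substr(s, i, i + lw - 1L) == w)
        ok[i + lw] <- TRUE
    }
  }
  ok[n + 1L]
}

fsm_language <- function(name, alphabet, transitions, start, accept) {
  # transitions: list by state of list(symbol=, to=) with uniform out-edges
  gen <- function(ch) {
    st <- start
    out <- character(0)
    while (!(st %in% accept)) {
      tr <- transitions[[st]]
      k <- ch$pick(seq_along(tr))
      out <- c(out, tr[[k]]$symbol)
      st <- tr[[k]]$to
    }
    paste(out, collapse = "")
  }
  membership <- function(s) {
    cs <- if (nzchar(s)) chars_of(s) else character(0)
    states <- start
    for (c0 in cs) {
      nxt <- integer(0)
      for (st in states) {
        if (st %in% accept) next
        for (tr in transitions[[st]])
          if (tr$symbol == c0) nxt <- c(nxt, tr$to)
      }
      states <- unique(nxt)
      if (!length(states)) return(FALSE)
    }
    any(states %in% accept)
  }
  new_language(name, alphabet, gen, membership)
}

uniform_pick_string <- function(ch, chars, n) {
  paste(vapply(seq_len(n), function(i) ch$pick(chars), ""), collapse = "")
}

#' The registry of target formal languages
#'
#' Simple formal languages across the Chomsky hierarchy (with the
#' convention that Sigma = \{a,b\} unless more symbols are required),
#' artificial-language-learning stimuli (Saffran segmentation, Marcus
#' ABA/ABB, Gomez aXb, Newport-Aslin nonadjacent dependencies, Reber and
#' Berwick-Pilato finite-state machines, Morgan-Newport phrase structure,
#' Reeder QAXB with held-out strings), and a simplified English
#' part-of-speech grammar. The Berwick-Pilato and Morgan-Newport machines
#' are synthetic reconstructions (uniform transition probabilities); the
#' Reber 'X' symbol is recoded to 'z' ('x' is the reserved argument
#' symbol).
#'
#' @return Named list of `lot_language` objects.
#' @export
language_registry <- function() {
  g <- geom_index
  langs <- list()
  add <- function(l) langs[[l$name]] <<- l

  add(new_language("an", "a",
    function(ch) strrep("a", g(ch)),
    function(s) grepl("^a+$", s)))
  add(new_language("a123", "a",
    function(ch) strrep("a", ch$pick(1:3, c(9, 6, 4) / 19)),
    function(s) s %in% c("a", "aa", "aaa")))
  add(new_language("abn", c("a", "b"),
    function(ch) strrep("ab", g(ch)),
    function(s) grepl("^(ab)+$", s)))
  add(new_language("sigma_plus", c("a", "b"),
    function(ch) uniform_pick_string(ch, c("a", "b"), g(ch)),
    function(s) grepl("^[ab]+$", s)))
  add(new_language("anbn", c("a", "b"),
    function(ch) { n <- g(ch); paste0(strrep("a", n), strrep("b", n)) },
    function(s) { n <- nchar(s) / 2
      n >= 1 && n == floor(n) && s == paste0(strrep("a", n), strrep("b", n)) }))
  add(new_language("anbncn", c("a", "b", "c"),
    function(ch) { n <- g(ch)
      paste0(strrep("a", n), strrep("b", n), strrep("c", n)) },
    function(s) { n <- nchar(s) / 3
      n >= 1 && n == floor(n) &&
        s == paste0(strrep("a", n), strrep("b", n), strrep("c", n)) }))
  add(new_language("anbncndn", c("a", "b", "c", "d"),
    function(ch) { n <- g(ch)
      paste0(strrep("a", n), strrep("b", n), strrep("c", n), strrep("d", n)) },
    function(s) { n <- nchar(s) / 4
      n >= 1 && n == floor(n) &&
        s == paste0(strrep("a", n), strrep("b", n), strrep("c", n),
                    strrep("d", n)) }))
  add(new_language("anbm", c("a", "b"),
    function(ch) paste0(strrep("a", g(ch)), strrep("b", g(ch))),
    function(s) grepl("^a+b+$", s)))
  add(new_language("anb2n", c("a", "b"),
    function(ch) { n <- g(ch); paste0(strrep("a", n), strrep("b", 2L * n)) },
    function(s) { n <- nchar(s) / 3
      n >= 1 && n == floor(n) &&
        s == paste0(strrep("a", n), strrep("b", 2L * n)) }))
  add(new_language("dyck", c("a", "b"),
    function(ch) {
      bal <- function() {
        if (ch$flip(2 / 3)) "" else paste0("a", bal(), "b", bal())
      }
      paste0("a", bal(), "b", bal())
    },
    function(s) {
      if (!nzchar(s) || !grepl("^[ab]+$", s)) return(FALSE)
      depth <- 0L
      for (c0 in chars_of(s)) {
        depth <- depth + (if (c0 == "a") 1L else -1L)
        if (depth < 0L) return(FALSE)
      }
      depth == 0L
    }))
  add(new_language("mirror", c("a", "b"),
    function(ch) {
      h <- uniform_pick_string(ch, c("a", "b"), g(ch))
      paste0(h, paste(rev(chars_of(h)), collapse = ""))
    },
    function(s) {
      n <- nchar(s)
      n >= 2 && n %% 2L == 0L && grepl("^[ab]+$", s) &&
        s == paste(rev(chars_of(s)), collapse = "")
    }))
  add(new_language("copy", c("a", "b"),
    function(ch) {
      h <- uniform_pick_string(ch, c("a", "b"), g(ch))
      paste0(h, h)
    },
    function(s) {
      n <- nchar(s)
      n >= 2 && n %% 2L == 0L && grepl("^[ab]+$", s) &&
        substr(s, 1L, n / 2L) == substr(s, n / 2L + 1L, n)
    }))
  add(new_language("anbmcndm", c("a", "b", "c", "d"),
    function(ch) { n <- g(ch); m <- g(ch)
      paste0(strrep("a", n), strrep("b", m), strrep("c", n), strrep("d", m)) },
    function(s) {
      m0 <- regmatches(s, regexec("^(a+)(b+)(c+)(d+)$", s))[[1]]
      length(m0) == 5L && nchar(m0[2]) == nchar(m0[4]) &&
        nchar(m0[3]) == nchar(m0[5])
    }))
  add(new_language("anbmanbmccc", c("a", "b", "c"),
    function(ch) { n <- g(ch); m <- g(ch)
      blk <- paste0(strrep("a", n), strrep("b", m))
      paste0(blk, blk, "ccc") },
    function(s) {
      m0 <- regmatches(s, regexec("^(a+)(b+)(a+)(b+)ccc$", s))[[1]]
      length(m0) == 5L && m0[2] == m0[4] && m0[3] == m0[5]
    }))
  add(new_language("chinese_numeral", c("a", "b"),
    function(ch) {
      n <- g(ch)
      out <- paste0("a", strrep("b", n))
      while (n > 1L && ch$flip(1 / 2)) {
        n <- ch$pick(seq_len(n - 1L))
        out <- paste0(out, "a", strrep("b", n))
      }
      out
    },
    function(s) {
      if (!grepl("^(ab+)+$", s)) return(FALSE)
      runs <- nchar(strsplit(s, "a", fixed = TRUE)[[1]][-1])
      all(diff(runs) < 0) || length(runs) == 1L
    }))
  add(new_language("count", c("a", "b"),
    function(ch) {
      k <- g(ch)
      paste(vapply(seq_len(k), function(i) paste0("a", strrep("b", i)), ""),
            collapse = "")
    },
    function(s) {
      if (!grepl("^(ab+)+$", s)) return(FALSE)
      runs <- nchar(strsplit(s, "a", fixed = TRUE)[[1]][-1])
      identical(runs, seq_along(runs))
    }))
  add(new_language("golden_mean", c("a", "b"),
    function(ch) {
      n <- g(ch)
      prev <- ""
      out <- character(n)
      for (i in seq_len(n)) {
        out[i] <- if (prev == "b") "a" else ch$pick(c("a", "b"))
        prev <- out[i]
      }
      paste(out, collapse = "")
    },
    function(s) grepl("^[ab]+$", s) && !grepl("bb", s, fixed = TRUE)))
  add(new_language("aplus_b_aplus", c("a", "b"),  # a+ b a+
    function(ch) paste0(strrep("a", g(ch)), "b", strrep("a", g(ch))),
    function(s) grepl("^a+ba+$", s)))
  syll <- c("a", "b", "c", "d")
  add(new_language("marcus_aba", syll,
    function(ch) { A <- ch$pick(syll); B <- ch$pick(syll)
      paste0(A, B, A) },
    function(s) nchar(s) == 3L && grepl("^[abcd]+$", s) &&
      substr(s, 1, 1) == substr(s, 3, 3)))
  add(new_language("marcus_abb", syll,
    function(ch) { A <- ch$pick(syll); B <- ch$pick(syll)
      paste0(A, B, B) },
    function(s) nchar(s) == 3L && grepl("^[abcd]+$", s) &&
      substr(s, 2, 2) == substr(s, 3, 3)))
  for (m in c(2L, 6L, 12L)) {
    xs <- letters[2 + seq_len(m)]  # c, d, e, ...
    add(local({
      xs_l <- xs; m_l <- m
      new_language(paste0("gomez", m_l), c("a", "b", xs_l),
        function(ch) paste0("a", ch$pick(xs_l), "b"),
        function(s) nchar(s) == 3L && substr(s, 1, 1) == "a" &&
          substr(s, 3, 3) == "b" && substr(s, 2, 2) %in% xs_l)
    }))
  }
  na_frames <- list(c("b", "t"), c("g", "d"), c("p", "r"), c("k", "u"),
                    c("l", "i"))
  na_x <- c("1", "2", "3", "4")
  add(new_language("newport_aslin",
    c(unique(unlist(na_frames)), na_x),
    function(ch) { f <- ch$pick(na_frames); paste0(f[1], ch$pick(na_x), f[2]) },
    function(s) {
      nchar(s) == 3L && substr(s, 2, 2) %in% na_x &&
        any(vapply(na_frames, function(f)
          substr(s, 1, 1) == f[1] && substr(s, 3, 3) == f[2], TRUE))
    }))
  saffran_words <- c("tapiro", "golabu", "bidaku", "padoti")
  add(new_language("saffran", unique(unlist(strsplit(saffran_words, ""))),
    function(ch) {
      m <- g(ch)
      paste(vapply(seq_len(m), function(i) ch$pick(saffran_words), ""),
            collapse = "")
    },
    function(s) lexicon_member(s, saffran_words),
    words = saffran_words))
  add(fsm_language("reber", c("p", "s", "t", "v", "z"),
    transitions = list(
      `1` = list(list(symbol = "t", to = 2L), list(symbol = "p", to = 3L)),
      `2` = list(list(symbol = "s", to = 2L), list(symbol = "z", to = 4L)),
      `3` = list(list(symbol = "t", to = 3L), list(symbol = "v", to = 5L)),
      `4` = list(list(symbol = "z", to = 3L), list(symbol = "s", to = 6L)),
      `5` = list(list(symbol = "p", to = 4L), list(symbol = "v", to = 6L))),
    start = 1L, accept = 6L))
  add(fsm_language("berwick_pilato", c("m", "h", "b", "v"),
    transitions = list(
      `1` = list(list(symbol = "m", to = 2L), list(symbol = "h", to = 3L),
                 list(symbol = "b", to = 4L), list(symbol = "v", to = 5L)),
      `2` = list(list(symbol = "h", to = 3L), list(symbol = "b", to = 4L),
                 list(symbol = "v", to = 5L)),
      `3` = list(list(symbol = "b", to = 4L), list(symbol = "v", to = 5L)),
      `4` = list(list(symbol = "v", to = 5L))),
    start = 1L, accept = 5L))
  mn_set <- as.character(outer(
    outer(c("a", "ad"), c("cf", "cdf", "e"), paste0),
    c("", "c", "cd"), paste0))
  add(new_language("morgan_newport", c("a", "c", "d", "e", "f"),
    function(ch) {
      ap <- paste0("a", if (ch$flip(1 / 2)) "d" else "")
      bp <- if (ch$flip(1 / 2)) {
        paste0("c", if (ch$flip(1 / 2)) "d" else "", "f")
      } else "e"
      cp <- if (ch$flip(1 / 2)) {
        paste0("c", if (ch$flip(1 / 2)) "d" else "")
      } else ""
      paste0(ap, bp, cp)
    },
    function(s) s %in% mn_set,
    strings = mn_set))
  re_a <- c("a", "b", "c"); re_x <- c("m", "n", "o"); re_b <- c("d", "e", "f")
  re_all <- as.character(outer(outer(re_a, re_x, paste0), re_b, paste0))
  re_held <- c("amd", "bne", "cof", "aoe", "bmf", "cnd")
  re_train <- setdiff(re_all, re_held)
  add(new_language("reeder", c(re_a, re_x, re_b),
    function(ch) ch$pick(re_train),
    function(s) s %in% re_all,
    held_out = re_held, training = re_train))
  add(english_language())
  langs
}

# Simplified English part-of-speech grammar:
#   S -> NP VP ; NP -> n | d n | d AP n | NP PP ; AP -> a | a AP
#   VP -> v | v NP | v t S | VP PP ; PP -> p NP
# Production probabilities decay geometrically over the listed expansions
# (nonuniform sentence probabilities; the skew is a package choice).
english_language <- function() {
  gen <- function(ch) {
    np <- function(depth) {
      k <- ch$pick(1:4, c(8, 4, 2, 1) / 15)
      switch(k,
             "n",
             paste0("d", "n"),
             paste0("d", ap(), "n"),
             paste0(np(depth + 1L), pp(depth + 1L)))
    }
    ap <- function() if (ch$flip(2 / 3)) "a" else paste0("a", ap())
    vp <- function(depth) {
      k <- ch$pick(1:4, c(8, 4, 2, 1) / 15)
      switch(k,
             "v",
             paste0("v", np(depth + 1L)),
             paste0("v", "t", s_(depth + 1L)),
             paste0(vp(depth + 1L), pp(depth + 1L)))
    }
    pp <- function(depth) paste0("p", np(depth + 1L))
    s_ <- function(depth) paste0(np(depth + 1L), vp(depth + 1L))
    s_(0L)
  }
  term_rules <- list(N = "n", D = "d", A = "a", V = "v", T = "t", P = "p",
                     NP = "n", AP = "a", VP = "v")
  bin_rules <- list(
    c("S", "NP", "VP"),
    c("NP", "D", "N"), c("NP", "D", "APN"), c("APN", "AP", "N"),
    c("NP", "NP", "PP"),
    c("AP", "A", "AP"),
    c("VP", "V", "NP"), c("VP", "V", "TS"), c("TS", "T", "S"),
    c("VP", "VP", "PP"),
    c("PP", "P", "NP"))
  new_language("english", c("n", "d", "a", "v", "t", "p"), gen,
               function(s) nzchar(s) && grepl("^[ndavtp]+$", s) &&
                 cyk_member(s, term_rules, bin_rules, "S"))
}

#' Fetch a target language by name
#'
#' @param name registry key, e.g. `"an"`, `"anbn"`, `"english"`.
#' @return A `lot_language`.
#' @export
get_language <- function(name) {
  reg <- language_registry()
  if (!name %in% names(reg))
    lot_error("lot_key_error", "unknown language '%s'; see language_registry()",
              name)
  reg[[name]]
}

#' Sample a dataset of positive examples from a target language
#'
#' @param t a `lot_language` (or registry name).
#' @param n_tokens number of i.i.d. tokens.
#' @param seed optional integer seed.
#' @return An `lot_dataset`.
#' @export
sample_dataset <- function(t, n_tokens, seed = NULL) {
  if (is.character(t)) t <- get_language(t)
  if (n_tokens < 1) lot_error("lot_config_error", "n_tokens must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ch <- random_chooser()
  toks <- vapply(seq_len(n_tokens), function(i) t$gen(ch), "")
  as_dataset(toks, source_language = t$name)
}

#' Most probable strings of a target language
#'
#' Computed by best-first enumeration of the generator's choice paths (the
#' same strategy as the program evaluator), aggregating duplicate
#' derivations; exact for unambiguous generators. Ties are broken by
#' length, then lexicographically.
#'
#' @param t a `lot_language` (or registry name).
#' @param k number of strings.
#' @param min_log_prob enumeration floor (deepened automatically if fewer
#'   than `k` strings are found).
#' @return list with `strings` (at most `k`, fewer for small finite
#'   languages) and `probs` (nonincreasing).
#' @export
top_k_strings <- function(t, k, min_log_prob = -18) {
  if (is.character(t)) t <- get_language(t)
  if (k < 1) lot_error("lot_config_error", "k must be >= 1")
  floor_ <- min_log_prob
  for (round in 1:3) {
    res <- enumerate_generator(t$gen, min_log_prob = floor_, stop_k = k)
    if (length(res$strings) >= k || res$unexplored < 1e-12) break
    floor_ <- floor_ * 2
  }
  n <- min(k, length(res$strings))
  list(strings = res$strings[seq_len(n)], probs = res$probs[seq_len(n)])
}

#' Membership test for target languages
#'
#' @param t a `lot_language` (or registry name).
#' @param strings character vector.
#' @return Logical vector.
#' @export
language_membership <- function(t, strings) {
  if (is.character(t) && length(t) == 1L && !inherits(t, "lot_language"))
    t <- get_language(t)
  vapply(strings, function(s) isTRUE(t$membership(s)), TRUE, USE.NAMES = FALSE)
}
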