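# Running a hypothesis: best-first enumeration of stochastic execution paths
# in order of path probability (compiled core), plus a pure-R forward
# sampler used as an independent oracle in the test-suite.

#' Resource bounds for program evaluation
#'
#' Paths are abandoned (accounted as unexplored mass) once their log
#' probability falls below `min_log_prob`; recursion and step caps convert a
#' path to error mass; enumeration stops after `max_outputs` distinct
#' strings. `max_paths` bounds the total number of enumerated paths so that
#' programs whose many paths collapse onto few outputs still terminate.
#'
#' @param min_log_prob log-probability floor (default -15).
#' @param max_recursion factor-call depth cap (default 64).
#' @param max_steps primitive-application cap per path (default 1024).
#' @param max_outputs distinct-output cap (default 256).
#' @param max_paths enumerated-path cap (default 3000).
#' @param max_work total primitive-application budget across all enumerated
#'   paths of one run (default 50000); the enumeration stops there and the
#'   remaining frontier is accounted as unexplored.
#' @param max_length string length cap; a path building a longer string
#'   becomes error mass (default 1024).
#' @return An object of class `eval_bounds`.
#' @export
eval_bounds <- function(min_log_prob = -15, max_recursion = 64L,
                        max_steps = 1024L, max_outputs = 256L,
                        max_paths = 3000L, max_work = 50000,
                        max_length = 1024L) {
  if (min_log_prob >= 0) lot_error("lot_config_error", "min_log_prob must be < 0")
  if (max_recursion < 1 || max_steps < 1 || max_outputs < 1 || max_paths < 1 ||
      max_work < 1 || max_length < 1)
    lot_error("lot_config_error", "all caps must be strictly positive")
  structure(list(min_log_prob = min_log_prob,
                 max_recursion = as.integer(max_recursion),
                 max_steps = as.integer(max_steps),
                 max_outputs = as.integer(max_outputs),
                 max_paths = as.integer(max_paths),
                 max_work = as.numeric(max_work),
                 max_length = as.integer(max_length)),
            class = "eval_bounds")
}

#' Enlarged bounds preset for complex grammars
#'
#' For rich targets such as the simplified English grammar a larger output
#' distribution must be enumerated; this preset lowers the probability floor
#' and raises the output cap.
#' @export
eval_bounds_large <- function() {
  eval_bounds(min_log_prob = -25, max_outputs = 2048L, max_paths = 50000L,
              max_work = 2e6)
}

#' Run a hypothesis and return its output distribution
#'
#' Enumerates execution paths greedily in order of probability: at every
#' stochastic primitive the path forks, and the frontier is explored
#' best-first (ties broken first-in-first-out). Runtime errors (e.g.
#' `first` of the empty string) and cap violations become error mass;
#' floor-abandoned paths become unexplored mass. Memoised factor calls
#' (`Fmi`) replay the value recorded for a previous call with the same
#' argument within the same top-level run.
#'
#' @param h a [lot_hypothesis()].
#' @param input the argument string bound to `x` (default the empty string).
#' @param bounds an [eval_bounds()].
#' @param factor 1-based factor index to evaluate (default the entry
#'   factor, i.e. the last one).
#' @return An object of class `output_dist`: `outcomes` (named probability
#'   vector over strings, sorted by decreasing probability),
#'   `unexplored_mass`, `error_mass`, and `path_probs` (completed-path
#'   probabilities in enumeration order).
#' @examples
#' ctx <- lot_context("a", 1)
#' h <- lot_hypothesis(list("pair(if(flip(1/3),ϵ,F0(ϵ)),a)"), ctx)
#' od <- run_program(h)
#' od$outcomes[1:3]  # 1/3, 2/9, 4/27
#' @export
run_program <- function(h, input = "", bounds = eval_bounds(),
                        factor = NULL) {
  if (is.null(factor)) factor <- h$entry_index
  r <- cpp_enumerate(h$codes, as.integer(factor), input,
                     h$context$alphabet, bounds$min_log_prob,
                     bounds$max_recursion, bounds$max_steps,
                     bounds$max_outputs, bounds$max_paths, bounds$max_work,
                     bounds$max_length)
  outcomes <- setNames(r$probs, r$outputs)
  structure(list(outcomes = outcomes, unexplored_mass = r$unexplored,
                 error_mass = r$error, path_probs = r$path_probs,
                 n_paths = r$n_paths),
            class = "output_dist")
}

#' @export
print.output_dist <- function(x, ...) {
  cat(sprintf(
    "<output_dist> %d strings (mass %.4f), unexplored %.4g, error %.4g\n",
    length(x$outcomes), sum(x$outcomes), x$unexplored_mass, x$error_mass))
  show <- head(x$outcomes, 8L)
  for (i in seq_along(show)) {
    s <- names(show)[i]
    cat(sprintf("  %-12s %.6f\n", ifelse(s == "", .lot_eps, s), show[i]))
  }
  if (length(x$outcomes) > 8L) cat("  ...\n")
  invisible(x)
}

#' Serialise an output distribution to JSON lines
#'
#' One object per line, `{"string": s, "probability": p}`, sorted by
#' decreasing probability, followed by one record for the unexplored and
#' error masses.
#' @param od an `output_dist`.
#' @param path file path.
#' @export
write_output_dist <- function(od, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(od$outcomes)) {
    writeLines(jsonlite::toJSON(
      list(string = names(od$outcomes)[i],
           probability = od$outcomes[[i]]), auto_unbox = TRUE, digits = NA),
      con)
  }
  writeLines(jsonlite::toJSON(
    list(unexplored_mass = od$unexplored_mass,
         error_mass = od$error_mass), auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

# --------------------------------------------------------------------------
# Single-primitive application (reference semantics, pure R)

#' Apply a single primitive to evaluated arguments
#'
#' Deterministic primitives return `list(kind = "value", value = ...)`;
#' the stochastic primitives return `list(kind = "branches", branches =
#' list(list(value =, prob =), ...))` (`flip(p)`: true with probability p;
#' `sample(S)`: one branch per set element). `first`/`rest` of the empty
#' string and `sample` of the empty set raise path-local errors. The
#' control-flow forms `if`, `and`, `or` are evaluated lazily by the
#' evaluator itself; applied to values here, `and`/`or` are their Boolean
#' functions.
#'
#' @param name primitive name (e.g. `"insert"`).
#' @param args list of evaluated argument values (strings, logicals,
#'   numerics, or character vectors for sets).
#' @param alphabet alphabet used by the `Σ` terminal.
#' @return See description.
#' @examples
#' apply_primitive("insert", list("abcd", "efg"))$value  # "abefgcd"
#' @export
apply_primitive <- function(name, args = list(), alphabet = c("a", "b")) {
  val <- function(v) list(kind = "value", value = v)
  switch(name,
    "pair" = val(paste0(args[[1]], args[[2]])),
    "first" = {
      if (!nzchar(args[[1]])) lot_error("lot_empty_string_error",
                                        "first of the empty string")
      val(substr(args[[1]], 1L, 1L))
    },
    "rest" = {
      if (!nzchar(args[[1]])) lot_error("lot_empty_string_error",
                                        "rest of the empty string")
      val(substr(args[[1]], 2L, nchar(args[[1]])))
    },
    "insert" = {
      a <- args[[1]]; b <- args[[2]]
      mid <- nchar(a) %/% 2L
      val(paste0(substr(a, 1L, mid), b, substr(a, mid + 1L, nchar(a))))
    },
    "append" = val(paste0(args[[1]], args[[2]])),
    "equals" = val(identical(args[[1]], args[[2]])),
    "empty" = val(!nzchar(args[[1]])),
    "and" = val(isTRUE(args[[1]]) && isTRUE(args[[2]])),
    "or" = val(isTRUE(args[[1]]) || isTRUE(args[[2]])),
    "not" = val(!isTRUE(args[[1]])),
    "union" = val(sort(unique(c(args[[1]], args[[2]])))),
    "setminus" = val(args[[1]][args[[1]] != args[[2]]]),
    "{s}" = val(args[[1]]),
    "flip" = list(kind = "branches", branches = list(
      list(value = TRUE, prob = args[[1]]),
      list(value = FALSE, prob = 1 - args[[1]]))),
    "sample" = {
      s <- args[[1]]
      if (!length(s)) lot_error("lot_empty_set_error", "sample of the empty set")
      list(kind = "branches",
           branches = lapply(s, function(e) list(value = e, prob = 1 / length(s))))
    },
    lot_error("lot_config_error", "unknown primitive '%s'", name)
  )
}

# --------------------------------------------------------------------------
# Forward-sampling oracle (independent of the compiled enumerator)

#' Forward-sample a hypothesis
#'
#' Runs the program `n_samples` times, resolving every stochastic site by
#' its stated probability and honouring memoisation, with the same resource
#' caps as [run_program()] (capped runs count as errors). Serves as an
#' independent Monte-Carlo oracle for the path enumerator.
#'
#' @param h a [lot_hypothesis()].
#' @param input argument string (default empty).
#' @param n_samples number of forward runs.
#' @param bounds an [eval_bounds()].
#' @param seed optional integer seed.
#' @return A list with `freq` (named relative frequencies over output
#'   strings) and `error_rate`.
#' @export
monte_carlo_run <- function(h, input = "", n_samples = 1000L,
                            bounds = eval_bounds(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- h$context
  counts <- new.env(parent = emptyenv())
  errors <- 0L
  for (rep in seq_len(n_samples)) {
    st <- new.env(parent = emptyenv())
    st$steps <- 0L; st$depth <- 0L
    st$memo <- new.env(parent = emptyenv())
    out <- tryCatch(
      mc_eval_factor(h, h$entry_index, input, st, ctx, bounds),
      lot_error = function(e) NULL)
    if (is.null(out)) {
      errors <- errors + 1L
    } else {
      key <- paste0("s:", out)
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  freq <- setNames(vapply(keys, function(k) counts[[k]], 0L) / n_samples,
                   substring(keys, 3L))
  list(freq = freq[order(-freq, nchar(names(freq)), names(freq))],
       error_rate = errors / n_samples)
}

mc_eval_factor <- function(h, idx, arg, st, ctx, bounds) {
  st$depth <- st$depth + 1L
  if (st$depth > bounds$max_recursion)
    lot_error("lot_eval_error", "recursion cap")
  v <- mc_eval(h$factors[[idx]], arg, h, st, ctx, bounds)
  st$depth <- st$depth - 1L
  v
}

mc_eval <- function(node, x, h, st, ctx, bounds) {
  st$steps <- st$steps + 1L
  if (st$steps > bounds$max_steps) lot_error("lot_eval_error", "step cap")
  op <- node$op
  ch <- node$children
  ev <- function(j) mc_eval(ch[[j]], x, h, st, ctx, bounds)
  if (op == .OP_EPS) return("")
  if (op == .OP_X) return(x)
  if (op == .OP_SIGMA) return(ctx$alphabet)
  if (op >= .OP_PROB0 && op < .OP_PROB0 + 5L)
    return(.prob_consts[op - .OP_PROB0 + 1L])
  if (op >= .OP_CHAR0 && op < .OP_CHAR0 + 32L)
    return(ctx$alphabet[op - .OP_CHAR0 + 1L])
  if (op %in% c(.OP_IFS, .OP_IFT, .OP_IFP))
    return(if (ev(1)) ev(2) else ev(3))
  if (op == .OP_AND) return(if (!ev(1)) FALSE else ev(2))
  if (op == .OP_OR) return(if (ev(1)) TRUE else ev(2))
  if (op == .OP_FLIP) return(runif(1) < ev(1))
  if (op == .OP_SAMPLE) {
    s <- ev(1)
    if (!length(s)) lot_error("lot_empty_set_error", "sample of empty set")
    return(s[[floor(runif(1) * length(s)) + 1L]])
  }
  if (op >= .OP_F0 && op < .OP_F0 + 4L)
    return(mc_eval_factor(h, op - .OP_F0 + 1L, ev(1), st, ctx, bounds))
  if (op >= .OP_FM0 && op < .OP_FM0 + 4L) {
    idx <- op - .OP_FM0 + 1L
    arg <- ev(1)
    key <- paste0(idx, ":", arg)
    hit <- st$memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- mc_eval_factor(h, idx, arg, st, ctx, bounds)
    st$memo[[key]] <- v
    v
  } else {
    v <- apply_primitive(ctx$name[op],
                         lapply(seq_along(ch), ev),
                         ctx$alphabet)$value
    if (is.character(v) && length(v) == 1L && nchar(v) > bounds$max_length)
      lot_error("lot_eval_error", "string length cap")
    v
  }
}
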