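# P(H): a probabilistic context-free grammar over expressions. Nonterminals
# are the five value types; the productions of a nonterminal are the
# primitives/terminals returning that type. Tree probability is the product
# of production probabilities, which penalises large programs.

#' Construct an expression grammar (the PCFG prior)
#'
#' Production weights default to 1 for every composite primitive and
#' `terminal_weight` for terminal productions (the empty string, `x`, the
#' alphabet set, probability constants, and the alphabet characters, which
#' share one terminal weight equally). Boosting terminals keeps the
#' branching process subcritical, so prior samples have finite expected
#' size while complexity is still penalised multiplicatively.
#'
#' @param ctx a [lot_context()], or an alphabet vector.
#' @param n_factors used when `ctx` is an alphabet.
#' @param terminal_weight weight multiplier for terminal productions
#'   (default 3).
#' @param include optional character vector of production names to keep
#'   (e.g. `c("pair", "ϵ", "a")`); all others are removed. Factor calls are
#'   named `F0`, `Fm0`, ...; the three `if` instances are all named `"if"`.
#' @param weights optional named numeric vector overriding individual
#'   production weights by name.
#' @return An object of class `lot_grammar`: per-nonterminal production
#'   tables (opcode, probability) plus a per-opcode log-probability lookup.
#' @export
expression_grammar <- function(ctx, n_factors = 1L, terminal_weight = 3,
                               include = NULL, weights = NULL) {
  if (!inherits(ctx, "lot_context")) ctx <- lot_context(ctx, n_factors)
  ids <- which(ctx$active)
  w <- ifelse(ctx$arity[ids] == 0L, terminal_weight, 1)
  names(w) <- ctx$name[ids]
  # alphabet characters share a single terminal weight; probability
  # constants likewise (so |Sigma| does not inflate the CHAR terminal mass)
  is_char <- ids >= .OP_CHAR0 & ids < .OP_CHAR0 + 32L
  w[is_char] <- terminal_weight / sum(is_char)
  is_prob <- ids >= .OP_PROB0 & ids < .OP_PROB0 + 5L
  w[is_prob] <- terminal_weight / sum(is_prob)
  if (!is.null(weights)) {
    for (nm in names(weights)) w[names(w) == nm] <- weights[[nm]]
  }
  keep <- rep(TRUE, length(ids))
  if (!is.null(include)) keep <- ctx$name[ids] %in% include
  ids <- ids[keep]; w <- w[keep]
  if (any(w <= 0)) lot_error("lot_config_error", "weights must be positive")

  op_logp <- rep(NA_real_, .OP_MAX)
  types <- .lot_types
  prods <- vector("list", length(types))
  names(prods) <- types
  for (tp in types) {
    sel <- ctx$ret[ids] == tp
    if (!any(sel)) {
      prods[[tp]] <- list(ops = integer(0), prob = numeric(0))
      next
    }
    p <- w[sel] / sum(w[sel])
    prods[[tp]] <- list(ops = as.integer(ids[sel]), prob = as.numeric(p))
    op_logp[ids[sel]] <- log(p)
  }
  structure(
    list(context = ctx, productions = prods, op_logp = op_logp,
         terminal_weight = terminal_weight,
         gspec = lapply(.lot_types, function(tp) prods[[tp]])),
    class = "lot_grammar"
  )
}

#' @export
print.lot_grammar <- function(x, ...) {
  cat("<lot_grammar>\n")
  for (tp in names(x$productions)) {
    pr <- x$productions[[tp]]
    if (!length(pr$ops)) next
    cat(sprintf("  %s -> %s\n", tp,
                paste(sprintf("%s (%.3f)", x$context$name[pr$ops], pr$prob),
                      collapse = " | ")))
  }
  invisible(x)
}

gspec_for_cpp <- function(g) g$gspec

#' Log prior probability of a hypothesis
#'
#' The sum over factors of the sum over tree nodes of log production
#' probabilities under the PCFG. Factors are scored independently.
#'
#' @param h a [lot_hypothesis()] (or a single `lot_expr`).
#' @param g an [expression_grammar()].
#' @return Log prior (a nonpositive number for normalised grammars).
#' @export
log_prior <- function(h, g) {
  codes <- if (inherits(h, "lot_hypothesis")) h$codes
           else list(expr_to_code(h))
  lp <- 0
  for (code in codes) {
    v <- g$op_logp[code]
    if (anyNA(v))
      lot_error("lot_config_error",
                "hypothesis uses a terminal absent from the grammar (%s)",
                paste(unique(g$context$name[code[is.na(v)]]), collapse = ", "))
    lp <- lp + sum(v)
  }
  lp
}

# log PCFG probability of a flat subtree code
code_log_prob <- function(code, g) {
  v <- g$op_logp[code]
  if (anyNA(v)) return(-Inf)
  sum(v)
}

#' Sample an expression from the PCFG
#'
#' @param g an [expression_grammar()].
#' @param type root nonterminal (default `"STRING"`).
#' @param max_depth hard depth cap; exceeding it raises a `lot_depth_error`.
#' @param seed optional integer seed.
#' @return A well-typed `lot_expr` drawn with probability `exp(log_prior)`.
#' @export
sample_expression <- function(g, type = "STRING", max_depth = 32L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- sample_code(g, type, max_depth)
  code_to_expr(code, g$context)
}

sample_code <- function(g, type = "STRING", max_depth = 32L) {
  tid <- match(type, .lot_types)
  out <- tryCatch(
    cpp_sample_code(gspec_for_cpp(g), tid, as.integer(max_depth)),
    error = function(e) {
      if (grepl("lot_depth_error", conditionMessage(e)))
        lot_error("lot_depth_error", "depth cap %d exceeded while sampling",
                  max_depth)
      stop(e)
    })
  out
}

# exact total prior mass of trees of depth <= d (dynamic programme over the
# grammar); independent of the sampler, used for the <= 1 mass invariant
grammar_mass_by_depth <- function(g, depth, type = "STRING") {
  ctx <- g$context
  z <- matrix(0, nrow = depth + 1L, ncol = length(.lot_types),
              dimnames = list(NULL, .lot_types))
  for (d in seq_len(depth)) {
    for (tp in .lot_types) {
      pr <- g$productions[[tp]]
      tot <- 0
      for (k in seq_along(pr$ops)) {
        op <- pr$ops[k]
        contrib <- pr$prob[k]
        for (at in ctx$args[[op]])
          contrib <- contrib * z[d, at]
        tot <- tot + contrib
      }
      z[d + 1L, tp] <- tot
    }
  }
  z[depth + 1L, type]
}
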