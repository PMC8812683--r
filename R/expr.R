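# Expression trees (nested form) and their flat pre-order integer encoding.
# The flat encoding is what the evaluator, prior and sampler operate on; the
# nested form backs parsing, printing and type checking.

new_expr <- function(op, children = list()) {
  structure(list(op = as.integer(op), children = children),
            class = "lot_expr")
}

#' @export
print.lot_expr <- function(x, ...) {
  ctx <- attr(x, "context")
  if (is.null(ctx)) {
    cat("<lot_expr> (print with print_expression(e, ctx))\n")
  } else {
    cat(print_expression(x, ctx), "\n")
  }
  invisible(x)
}

# flat pre-order code from nested expression
expr_to_code <- function(e) {
  out <- integer(0)
  rec <- function(node) {
    out[[length(out) + 1L]] <<- node$op
    for (ch in node$children) rec(ch)
  }
  rec(e)
  as.integer(out)
}

# nested expression from flat code
code_to_expr <- function(code, ctx) {
  pos <- 0L
  rec <- function() {
    pos <<- pos + 1L
    op <- code[pos]
    k <- ctx$arity[op]
    children <- vector("list", k)
    for (j in seq_len(k)) children[[j]] <- rec()
    new_expr(op, children)
  }
  e <- rec()
  if (pos != length(code))
    lot_error("lot_parse_error", "trailing opcodes in flat code")
  e
}

# one-past end of the subtree rooted at 1-based position i
code_subtree_end <- function(code, i) {
  cpp_subtree_end(code, i)[1] - 1L
}

#' Construct a hypothesis from factor expressions
#'
#' A hypothesis is an ordered tuple of factors `F0 ... F(n-1)`, each a
#' STRING-to-STRING program; the last factor is the entry point, evaluated
#' with `x` bound to the empty string. Every factor must be reachable from
#' the entry factor through factor calls.
#'
#' @param factors list of `lot_expr` (or character strings, parsed with
#'   [parse_expression()]).
#' @param ctx a [lot_context()]; its `n_factors` must equal `length(factors)`.
#' @param check validate typing and reachability (default `TRUE`).
#' @return An object of class `lot_hypothesis` with fields `factors`
#'   (expressions), `codes` (flat encodings), `n_factors` and `entry_index`
#'   (1-based; always the last factor).
#' @export
lot_hypothesis <- function(factors, ctx, check = TRUE) {
  if (!inherits(ctx, "lot_context"))
    lot_error("lot_config_error", "ctx must be a lot_context")
  if (is.character(factors)) factors <- as.list(factors)
  factors <- lapply(factors, function(f) {
    if (is.character(f)) parse_expression(f, ctx) else f
  })
  if (length(factors) != ctx$n_factors)
    lot_error("lot_config_error",
              "hypothesis has %d factors but context declares %d",
              length(factors), ctx$n_factors)
  if (check) {
    for (f in factors) {
      tp <- type_check(f, ctx)
      if (!tp %in% c("STRING", "CHAR"))
        lot_error("lot_type_error",
                  "factor body must have type STRING (got %s)", tp)
    }
  }
  h <- structure(
    list(factors = factors, codes = lapply(factors, expr_to_code),
         n_factors = ctx$n_factors, entry_index = ctx$n_factors,
         context = ctx),
    class = "lot_hypothesis"
  )
  if (check && !all_factors_reachable(h$codes, h$entry_index))
    lot_error("lot_config_error",
              "every factor must be reachable from the entry factor")
  h
}

hypothesis_from_codes <- function(codes, ctx) {
  structure(
    list(factors = lapply(codes, code_to_expr, ctx = ctx), codes = codes,
         n_factors = ctx$n_factors, entry_index = ctx$n_factors,
         context = ctx),
    class = "lot_hypothesis"
  )
}

# factor indices (1-based) called by a flat code
factors_called <- function(code) {
  f <- code[code >= .OP_F0 & code < .OP_F0 + 4L] - .OP_F0 + 1L
  fm <- code[code >= .OP_FM0 & code < .OP_FM0 + 4L] - .OP_FM0 + 1L
  unique(c(f, fm))
}

all_factors_reachable <- function(codes, entry) {
  n <- length(codes)
  if (n == 1L) return(TRUE)
  calls <- lapply(codes, factors_called)
  seen <- rep(FALSE, n)
  seen[entry] <- TRUE
  frontier <- entry
  while (length(frontier)) {
    nxt <- unique(unlist(calls[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.lot_hypothesis <- function(x, ...) {
  for (i in seq_along(x$factors)) {
    cat(sprintf("F%d(x) := %s\n", i - 1L,
                print_expression(x$factors[[i]], x$context)))
  }
  invisible(x)
}

#' @export
format.lot_hypothesis <- function(x, ...) {
  paste(vapply(x$factors, print_expression, "", ctx = x$context),
        collapse = " ; ")
}
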