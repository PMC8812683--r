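# Canonical program syntax: function application with parentheses and commas,
# bare (or quoted) single-character constants, the reserved symbols for the
# empty string and the alphabet set, probability constants written as
# fractions, `{e}` for singleton sets, and `Fi`/`Fmi` factor calls.

lot_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  toks <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    c0 <- chars[i]
    if (grepl("^\\s$", c0)) {
      i <- i + 1L
    } else if (c0 %in% c("(", ")", "{", "}", ",")) {
      toks <- c(toks, c0)
      i <- i + 1L
    } else if (c0 == "'") {
      if (i + 2L > n || chars[i + 2L] != "'")
        lot_error("lot_parse_error", "unterminated quoted character")
      toks <- c(toks, paste0("'", chars[i + 1L], "'"))
      i <- i + 3L
    } else if (c0 %in% c(.lot_eps, .lot_sigma, "\u03b5")) {
      toks <- c(toks, if (c0 == "\u03b5") .lot_eps else c0)
      i <- i + 1L
    } else if (grepl("[A-Za-z0-9]", c0)) {
      j <- i
      while (j < n && grepl("[A-Za-z0-9/]", chars[j + 1L])) j <- j + 1L
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      lot_error("lot_parse_error", "unexpected character '%s'", c0)
    }
  }
  toks
}

# static type with CHAR->STRING promotion NOT applied (the raw type)
expr_type <- function(e, ctx) ctx$ret[e$op]

#' Parse a program expression from canonical text
#'
#' @param text program text, e.g. `"pair(if(flip(1/3),ϵ,F0(ϵ)),a)"`.
#' @param ctx a [lot_context()] (fixes the alphabet and factor count), or an
#'   alphabet character vector (then `n_factors` is used).
#' @param n_factors factor count, used only when `ctx` is an alphabet.
#' @return A well-typed `lot_expr`.
#' @examples
#' ctx <- lot_context("a", 1)
#' e <- parse_expression("pair(if(flip(1/3),ϵ,F0(ϵ)),a)", ctx)
#' print_expression(e, ctx)
#' @export
parse_expression <- function(text, ctx, n_factors = 1L) {
  if (!inherits(ctx, "lot_context")) ctx <- lot_context(ctx, n_factors)
  toks <- lot_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- peek()
    if (is.na(t)) lot_error("lot_parse_error", "unexpected end of input")
    pos <<- pos + 1L
    t
  }
  expect <- function(t) {
    got <- advance()
    if (got != t)
      lot_error("lot_parse_error", "expected '%s' but found '%s'", t, got)
  }

  parse_one <- function() {
    t <- advance()
    if (t == "{") {
      inner <- parse_one()
      expect("}")
      return(new_expr(.OP_SETSINGLE, list(inner)))
    }
    if (grepl("^'.'$", t)) t <- substr(t, 2L, 2L)
    if (!is.na(peek()) && peek() == "(" &&
        grepl("^[A-Za-z][A-Za-z0-9]*$", t)) {
      return(parse_call(t))
    }
    parse_terminal(t)
  }

  parse_call <- function(name) {
    expect("(")
    args <- list()
    if (!is.na(peek()) && peek() != ")") {
      args[[1L]] <- parse_one()
      while (!is.na(peek()) && peek() == ",") {
        advance()
        args[[length(args) + 1L]] <- parse_one()
      }
    }
    expect(")")
    if (name == "flip" && length(args) == 0L) {
      # flip() is sugar for flip(1/2)
      args <- list(new_expr(.OP_PROB0 + 2L))
    }
    if (name == "if") {
      if (length(args) != 3L)
        lot_error("lot_parse_error", "if takes 3 arguments")
      bt <- expr_type(args[[2L]], ctx)
      op <- switch(bt, STRSET = .OP_IFT, PROB = .OP_IFP, .OP_IFS)
      return(new_expr(op, args))
    }
    if (grepl("^Fm?[0-9]+$", name)) {
      memo <- grepl("^Fm", name)
      idx <- as.integer(sub("^Fm?", "", name))
      if (idx >= ctx$n_factors)
        lot_error("lot_parse_error",
                  "factor index %d out of range (n_factors = %d)",
                  idx, ctx$n_factors)
      if (length(args) != 1L)
        lot_error("lot_parse_error", "factor calls take 1 argument")
      op <- (if (memo) .OP_FM0 else .OP_F0) + idx
      return(new_expr(op, args))
    }
    ids <- ctx_op_by_name(ctx, name)
    ids <- ids[ctx$arity[ids] > 0L]
    if (!length(ids))
      lot_error("lot_parse_error", "unknown function '%s'", name)
    op <- ids[1L]
    if (length(args) != ctx$arity[op])
      lot_error("lot_parse_error", "%s takes %d argument(s), got %d",
                name, ctx$arity[op], length(args))
    new_expr(op, args)
  }

  parse_terminal <- function(t) {
    if (t == .lot_eps) return(new_expr(.OP_EPS))
    if (t == .lot_sigma) return(new_expr(.OP_SIGMA))
    if (t == "x") return(new_expr(.OP_X))
    k <- match(t, .prob_names)
    if (!is.na(k)) return(new_expr(.OP_PROB0 + k - 1L))
    k <- match(t, ctx$alphabet)
    if (!is.na(k)) return(new_expr(.OP_CHAR0 + k - 1L))
    if (nchar(t) == 1L && grepl("^[a-z0-9]$", t))
      lot_error("lot_alphabet_error", "character '%s' is not in the alphabet", t)
    lot_error("lot_parse_error", "unknown symbol '%s'", t)
  }

  e <- parse_one()
  if (!is.na(peek()))
    lot_error("lot_parse_error", "trailing input after expression: '%s'", peek())
  type_check(e, ctx)  # raises lot_type_error on ill-typed composition
  attr(e, "context") <- ctx
  e
}

#' Render an expression in canonical syntax
#'
#' `parse_expression(print_expression(e, ctx), ctx)` is structurally the
#' identity for well-typed trees.
#'
#' @param e a `lot_expr`.
#' @param ctx the matching [lot_context()].
#' @return A single character string.
#' @export
print_expression <- function(e, ctx) {
  rec <- function(node) {
    op <- node$op
    if (op == .OP_SETSINGLE) return(paste0("{", rec(node$children[[1L]]), "}"))
    nm <- ctx$name[op]
    if (ctx$arity[op] == 0L) return(nm)
    paste0(nm, "(", paste(vapply(node$children, rec, ""), collapse = ","), ")")
  }
  rec(e)
}

#' Type-check an expression
#'
#' Checks every application against the primitive signatures. A CHAR may be
#' promoted to a one-character STRING wherever a STRING is required; `if`
#' requires both branches to share a type (strings, sets or probabilities).
#'
#' @param e a `lot_expr`.
#' @param ctx the matching [lot_context()].
#' @return The expression's return type, one of `"STRING"`, `"CHAR"`,
#'   `"BOOL"`, `"STRSET"`, `"PROB"`. Raises a `lot_type_error` (with the
#'   offending subtree printed) otherwise.
#' @export
type_check <- function(e, ctx) {
  if (is.character(e)) e <- parse_expression(e, ctx)
  rec <- function(node) {
    op <- node$op
    if (is.na(op) || op < 1L || op > .OP_MAX || !ctx$active[op])
      lot_error("lot_type_error", "inactive opcode %s", op)
    need <- ctx$args[[op]]
    if (length(node$children) != length(need))
      lot_error("lot_type_error", "%s expects %d argument(s)",
                ctx$name[op], length(need))
    for (j in seq_along(need)) {
      got <- rec(node$children[[j]])
      ok <- got == need[j] || (need[j] == "STRING" && got == "CHAR")
      if (!ok)
        lot_error("lot_type_error", "in %s: argument %d has type %s, need %s",
                  print_expression(node, ctx), j, got, need[j])
    }
    ctx$ret[op]
  }
  rec(e)
}
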