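#' @useDynLib lotlang, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames
#' @importFrom utils head tail
NULL

# Reserved surface symbols; must match the C++ opcode layout in src/lot_eval.cpp
.lot_eps <- "\u03f5"    # empty-string symbol (lunate epsilon)
.lot_sigma <- "\u03a3"  # alphabet-set symbol (capital sigma)

.OP_PAIR <- 1L; .OP_FIRST <- 2L; .OP_REST <- 3L; .OP_INSERT <- 4L
.OP_APPEND <- 5L; .OP_FLIP <- 6L; .OP_EQUALS <- 7L; .OP_EMPTY <- 8L
.OP_IFS <- 9L; .OP_IFT <- 10L; .OP_IFP <- 11L; .OP_AND <- 12L
.OP_OR <- 13L; .OP_NOT <- 14L; .OP_UNION <- 15L; .OP_SETMINUS <- 16L
.OP_SETSINGLE <- 17L; .OP_SAMPLE <- 18L; .OP_EPS <- 19L; .OP_X <- 20L
.OP_SIGMA <- 21L; .OP_PROB0 <- 22L; .OP_CHAR0 <- 27L; .OP_F0 <- 59L
.OP_FM0 <- 63L; .OP_MAX <- 66L

.prob_consts <- c(1 / 4, 1 / 3, 1 / 2, 2 / 3, 3 / 4)
.prob_names <- c("1/4", "1/3", "1/2", "2/3", "3/4")

.lot_types <- c("STRING", "CHAR", "BOOL", "STRSET", "PROB")

lot_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lot_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Primitive inventory
#'
#' The fixed inventory of typed primitives from which hypotheses are
#' composed: list/string operations (`pair`, `first`, `rest`, `insert`,
#' `append`), logical functions (`flip`, `equals`, `empty`, `if`, `and`,
#' `or`, `not`), set functions (the alphabet set, singleton sets, `union`,
#' `setminus`, `sample`), and the terminals (the empty string, the function
#' argument `x`, alphabet characters, probability constants) plus factor
#' calls `Fi`/`Fmi`. `flip` and `sample` are the only stochastic primitives;
#' `if` is polymorphic over strings, sets and probabilities (represented
#' internally as one entry per return type).
#'
#' @return A data frame with one row per primitive/terminal opcode:
#'   `id`, `name`, `ret` (return type), `arity`, `stochastic`, and a
#'   list-column `args` of argument types.
#' @export
lot_primitives <- function() {
  base <- list(
    list(.OP_PAIR, "pair", "STRING", c("STRING", "CHAR"), FALSE),
    list(.OP_FIRST, "first", "CHAR", "STRING", FALSE),
    list(.OP_REST, "rest", "STRING", "STRING", FALSE),
    list(.OP_INSERT, "insert", "STRING", c("STRING", "STRING"), FALSE),
    list(.OP_APPEND, "append", "STRING", c("STRING", "STRING"), FALSE),
    list(.OP_FLIP, "flip", "BOOL", "PROB", TRUE),
    list(.OP_EQUALS, "equals", "BOOL", c("STRING", "STRING"), FALSE),
    list(.OP_EMPTY, "empty", "BOOL", "STRING", FALSE),
    list(.OP_IFS, "if", "STRING", c("BOOL", "STRING", "STRING"), FALSE),
    list(.OP_IFT, "if", "STRSET", c("BOOL", "STRSET", "STRSET"), FALSE),
    list(.OP_IFP, "if", "PROB", c("BOOL", "PROB", "PROB"), FALSE),
    list(.OP_AND, "and", "BOOL", c("BOOL", "BOOL"), FALSE),
    list(.OP_OR, "or", "BOOL", c("BOOL", "BOOL"), FALSE),
    list(.OP_NOT, "not", "BOOL", "BOOL", FALSE),
    list(.OP_UNION, "union", "STRSET", c("STRSET", "STRSET"), FALSE),
    list(.OP_SETMINUS, "setminus", "STRSET", c("STRSET", "STRING"), FALSE),
    list(.OP_SETSINGLE, "{s}", "STRSET", "STRING", FALSE),
    list(.OP_SAMPLE, "sample", "STRING", "STRSET", TRUE),
    list(.OP_EPS, .lot_eps, "STRING", character(), FALSE),
    list(.OP_X, "x", "STRING", character(), FALSE),
    list(.OP_SIGMA, .lot_sigma, "STRSET", character(), FALSE)
  )
  rows <- lapply(base, function(r) {
    data.frame(id = r[[1]], name = r[[2]], ret = r[[3]],
               arity = length(r[[4]]), stochastic = r[[5]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$args <- lapply(base, function(r) r[[4]])
  out
}

#' Create an evaluation context (alphabet + factor count)
#'
#' A context fixes the alphabet \eqn{\Sigma} and the number of factors, and
#' derives the full opcode table used for parsing, printing, type checking,
#' prior construction and evaluation.
#'
#' @param alphabet character vector of distinct single characters; may not
#'   contain the reserved symbols `x`, the empty-string symbol, or the
#'   alphabet-set symbol.
#' @param n_factors number of factors (1 to 4).
#' @return An object of class `lot_context`.
#' @export
lot_context <- function(alphabet, n_factors = 1L) {
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 1 || any(nchar(alphabet) != 1))
    lot_error("lot_config_error", "alphabet must be single characters")
  if (anyDuplicated(alphabet))
    lot_error("lot_config_error", "alphabet characters must be distinct")
  if (length(alphabet) > 32)
    lot_error("lot_config_error", "alphabet may contain at most 32 characters")
  if (any(alphabet %in% c("x", .lot_eps, .lot_sigma)))
    lot_error("lot_config_error",
              "alphabet may not contain reserved symbols (x, %s, %s)",
              .lot_eps, .lot_sigma)
  n_factors <- as.integer(n_factors)
  if (n_factors < 1L || n_factors > 4L)
    lot_error("lot_config_error", "n_factors must be in 1..4")
  alphabet <- sort(alphabet)  # canonical order; Sigma evaluates sorted

  n <- .OP_MAX
  name <- character(n); ret <- character(n); arity <- integer(n)
  stoch <- logical(n); active <- logical(n)
  args <- vector("list", n)
  prim <- lot_primitives()
  for (i in seq_len(nrow(prim))) {
    id <- prim$id[i]
    name[id] <- prim$name[i]; ret[id] <- prim$ret[i]
    arity[id] <- prim$arity[i]; stoch[id] <- prim$stochastic[i]
    args[[id]] <- prim$args[[i]]; active[id] <- TRUE
  }
  for (k in seq_along(.prob_consts)) {
    id <- .OP_PROB0 + k - 1L
    name[id] <- .prob_names[k]; ret[id] <- "PROB"; arity[id] <- 0L
    args[[id]] <- character(); active[id] <- TRUE
  }
  for (k in seq_along(alphabet)) {
    id <- .OP_CHAR0 + k - 1L
    name[id] <- alphabet[k]; ret[id] <- "CHAR"; arity[id] <- 0L
    args[[id]] <- character(); active[id] <- TRUE
  }
  for (k in seq_len(n_factors)) {
    id <- .OP_F0 + k - 1L
    name[id] <- paste0("F", k - 1L); ret[id] <- "STRING"; arity[id] <- 1L
    args[[id]] <- "STRING"; active[id] <- TRUE
    id <- .OP_FM0 + k - 1L
    name[id] <- paste0("Fm", k - 1L); ret[id] <- "STRING"; arity[id] <- 1L
    args[[id]] <- "STRING"; active[id] <- TRUE
  }
  structure(
    list(alphabet = alphabet, n_factors = n_factors,
         name = name, ret = ret, arity = arity, stochastic = stoch,
         args = args, active = active),
    class = "lot_context"
  )
}

#' @export
print.lot_context <- function(x, ...) {
  cat(sprintf("<lot_context> alphabet {%s}, %d factor(s)\n",
              paste(x$alphabet, collapse = ","), x$n_factors))
  invisible(x)
}

ctx_op_by_name <- function(ctx, nm) {
  which(ctx$active & ctx$name == nm)
}
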