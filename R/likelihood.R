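# P(D|H): prefix likelihood. An observed string arises from a generated
# string via a noise channel that first deletes characters from the end
# (each with probability delta) and then appends characters drawn uniformly
# from the alphabet (each with probability gamma). This gives partial
# credit to hypotheses that get most of a string right.

#' Noise model for the prefix likelihood
#'
#' @param delete_prob per-character probability of deleting the last
#'   character (delta, default 0.01).
#' @param append_prob per-character probability of appending one more
#'   character (gamma, default 0.01).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(delete_prob = 0.01, append_prob = 0.01) {
  if (delete_prob < 0 || delete_prob >= 1 || append_prob < 0 || append_prob >= 1)
    lot_error("lot_config_error", "noise probabilities must be in [0, 1)")
  structure(list(delete_prob = delete_prob, append_prob = append_prob),
            class = "noise_model")
}

#' Log probability of observing one string given a generated string
#'
#' Sums over the number of deletions k = 0..|o|: the surviving prefix of
#' the generated string `o` must be a prefix of the observed string `d`,
#' deletions cost `delta^k (1-delta)` (or `delta^|o|` once the whole string
#' is gone, so the channel normalises exactly), and the remaining
#' characters of `d` are appended at `gamma/|Sigma|` each, with a final
#' stop factor `(1-gamma)`. Always finite: the full-deletion term applies
#' to any pair when `delta, gamma > 0`.
#'
#' @param observed observed string d.
#' @param generated generated string o.
#' @param nm a [noise_model()].
#' @param n_alphabet alphabet size |Sigma|.
#' @return Log probability (scalar).
#' @export
string_transform_loglik <- function(observed, generated, nm,
                                    n_alphabet = 2L) {
  del <- nm$delete_prob; gam <- nm$append_prob
  lo <- nchar(generated); ld <- nchar(observed)
  terms <- numeric(0)
  for (k in 0:lo) {
    keep <- lo - k
    m <- ld - keep
    if (m < 0) next
    if (substr(generated, 1L, keep) != substr(observed, 1L, keep)) next
    lp <- 0
    if (k > 0) {
      if (del == 0) next
      lp <- lp + k * log(del)
    }
    if (k < lo) lp <- lp + log1p(-del)
    if (m > 0) {
      if (gam == 0) next
      lp <- lp + m * log(gam / n_alphabet)
    }
    lp <- lp + log1p(-gam)
    terms <- c(terms, lp)
  }
  if (!length(terms)) return(-Inf)
  logsumexp(terms)
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Datasets of observed strings
#'
#' A dataset is a multiset of strings over the alphabet, stored as distinct
#' strings with multiplicities.
#'
#' @param strings character vector of observed strings (with repeats), or a
#'   named numeric vector of counts.
#' @param source_language optional label.
#' @return An object of class `lot_dataset` with `strings`, `counts`,
#'   `n_tokens`.
#' @export
as_dataset <- function(strings, source_language = NULL) {
  if (inherits(strings, "lot_dataset")) return(strings)
  if (!is.null(names(strings)) && is.numeric(strings)) {
    counts <- as.numeric(strings)
    strs <- names(strings)
  } else {
    tab <- table(factor(strings, levels = unique(strings)))
    strs <- names(tab)
    counts <- as.numeric(tab)
  }
  structure(list(strings = strs, counts = counts,
                 n_tokens = sum(counts), source_language = source_language),
            class = "lot_dataset")
}

#' @export
print.lot_dataset <- function(x, ...) {
  cat(sprintf("<lot_dataset> %d tokens, %d distinct strings%s\n",
              x$n_tokens, length(x$strings),
              if (is.null(x$source_language)) ""
              else paste0(" (", x$source_language, ")")))
  invisible(x)
}

#' Read / write plain-text datasets
#'
#' One string per line; `#` starts a comment; blank lines are skipped; the
#' empty-string token is written as the literal symbol `ϵ`.
#'
#' @param path file path.
#' @return For `read_dataset`, an `lot_dataset`.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines[lines == .lot_eps] <- ""
  as_dataset(lines)
}

#' @rdname read_dataset
#' @param d an `lot_dataset` or character vector.
#' @export
write_dataset <- function(d, path) {
  d <- as_dataset(d)
  toks <- rep(d$strings, times = d$counts)
  toks[toks == ""] <- .lot_eps
  writeLines(toks, con = file(path, encoding = "UTF-8"))
  invisible(path)
}

#' Data log likelihood of an output distribution
#'
#' `sum_d count(d) * log sum_o P(o) exp(string_transform_loglik(d, o))`,
#' i.e. tokens are i.i.d. given the hypothesis. Only enumerated outcomes
#' contribute (unexplored and error mass are dropped), so the value is a
#' lower bound on the exact marginal likelihood.
#'
#' @param out an `output_dist` from [run_program()].
#' @param D an `lot_dataset` (or character vector of tokens).
#' @param nm a [noise_model()].
#' @param n_alphabet alphabet size.
#' @return Total log likelihood.
#' @export
data_log_likelihood <- function(out, D, nm = noise_model(),
                                n_alphabet = 2L) {
  D <- as_dataset(D)
  if (!length(out$outcomes))
    lot_error("lot_likelihood_error",
              "output distribution has no enumerated outcomes")
  cpp_data_loglik(names(out$outcomes), as.numeric(out$outcomes),
                  D$strings, D$counts,
                  nm$delete_prob, nm$append_prob, as.integer(n_alphabet))
}
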