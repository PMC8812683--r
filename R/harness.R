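# Evaluation: posterior-weighted precision/recall over top-k strings,
# the memorisation baseline, learning curves over the data schedule, and
# the generalisation matrix for unseen probe strings.

#' Evaluation configuration
#'
#' @param k_top top-string count (25 by default; 100 is used for the
#'   English grammar).
#' @param data_schedule token counts for learning curves (default the
#'   standard 15-point schedule from 1 to 100000).
#' @param n_hypotheses posterior-set size used (500).
#' @param bounds [eval_bounds()] used when enumerating hypothesis outputs.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(k_top = 25L,
                        data_schedule = c(1, 2, 5, 10, 20, 50, 100, 200, 500,
                                          1000, 2000, 5000, 10000, 50000,
                                          100000),
                        n_hypotheses = 500L, bounds = eval_bounds()) {
  if (k_top < 1) lot_error("lot_config_error", "k_top must be >= 1")
  if (any(diff(data_schedule) <= 0))
    lot_error("lot_config_error", "data_schedule must be strictly increasing")
  structure(list(k_top = as.integer(k_top), data_schedule = data_schedule,
                 n_hypotheses = as.integer(n_hypotheses), bounds = bounds),
            class = "eval_config")
}

f_score <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

# data strings ordered by frequency (ties: shorter first, then lexicographic)
data_top_k <- function(D, k) {
  D <- as_dataset(D)
  ord <- order(-D$counts, nchar(D$strings), D$strings)
  head(D$strings[ord], k)
}

# per-hypothesis output distributions for a posterior set (cached)
pset_outputs <- function(ps, bounds) {
  lapply(ps$codes, function(codes) {
    h <- hypothesis_from_codes(codes, ps$context)
    run_program(h, bounds = bounds)
  })
}

#' Posterior-weighted precision and recall
#'
#' Precision is the posterior-weighted fraction of each hypothesis's top-k
#' generated strings that are correct; recall is the weighted fraction of
#' the reference top-k strings that the hypothesis can generate (anywhere
#' in its enumerated support). With `reference = "data"` (the default when
#' no target is given) "correct" means occurring anywhere in the observed
#' data and the reference top-k are the k most frequent data strings; with
#' a target language, "correct" means membership in the target language
#' and the reference top-k are the target's k most probable strings (this
#' is the variant plotted in learning curves, and the one under which the
#' memorisation baseline is scored).
#'
#' @param ps a [posterior_set()].
#' @param D the training dataset.
#' @param cfg an [eval_config()].
#' @param target optional `lot_language` (or name).
#' @param reference `"target"` or `"data"`.
#' @return list with `precision`, `recall`, `f` and the per-hypothesis
#'   values.
#' @export
posterior_precision_recall <- function(ps, D, cfg = eval_config(),
                                       target = NULL,
                                       reference = if (is.null(target))
                                         "data" else "target") {
  reference <- match.arg(reference, c("data", "target"))
  if (reference == "target") {
    if (is.null(target))
      lot_error("lot_config_error", "target required for target reference")
    if (is.character(target)) target <- get_language(target)
  }
  D <- as_dataset(D)
  k <- cfg$k_top
  w <- ps$entries$weight
  keep <- w > 0
  if (!any(keep)) keep <- seq_len(min(1L, length(w))) == 1L
  outs <- pset_outputs(ps, cfg$bounds)
  ref_topk <- if (reference == "target") top_k_strings(target, k)$strings
              else data_top_k(D, k)
  data_set <- unique(D$strings)
  prec_i <- rec_i <- rep(NA_real_, length(w))
  for (i in seq_along(w)) {
    if (!keep[i]) next
    od <- outs[[i]]
    support <- names(od$outcomes)
    if (!length(support))
      lot_error("lot_eval_error", "hypothesis %d enumerates zero strings", i)
    sk <- head(support, k)  # outcomes are prob-sorted with length/lex ties
    prec_i[i] <- if (reference == "target")
      mean(language_membership(target, sk))
    else mean(sk %in% data_set)
    rec_i[i] <- mean(ref_topk %in% support)
  }
  wk <- w * keep
  wk <- wk / sum(wk)
  precision <- sum(wk[keep] * prec_i[keep])
  recall <- sum(wk[keep] * rec_i[keep])
  list(precision = precision, recall = recall,
       f = f_score(precision, recall),
       per_hypothesis = data.frame(weight = w, precision = prec_i,
                                   recall = rec_i))
}

#' F score of a pure memorisation baseline
#'
#' Treats the observed data multiset itself as the learned distribution:
#' its top-k strings are the k most frequent observed strings and its
#' support is the set of observed strings. Precision is the fraction of
#' memorised top-k strings that belong to the target language; recall is
#' the fraction of the target's top-k strings that were observed.
#'
#' @param D the dataset.
#' @param t the target `lot_language` (or name).
#' @param cfg an [eval_config()].
#' @return list with `precision`, `recall`, `f`.
#' @export
memorized_f <- function(D, t, cfg = eval_config()) {
  if (is.character(t)) t <- get_language(t)
  D <- as_dataset(D)
  k <- cfg$k_top
  mem_topk <- data_top_k(D, k)
  ref_topk <- top_k_strings(t, k)$strings
  precision <- mean(language_membership(t, mem_topk))
  recall <- mean(ref_topk %in% D$strings)
  list(precision = precision, recall = recall, f = f_score(precision, recall))
}

#' Learning curve for one target language
#'
#' For each schedule point: sample a dataset, search for hypotheses with
#' parallel tempering (per factor count), merge, and evaluate posterior-
#' weighted precision/recall against the target, alongside the
#' memorisation baseline.
#'
#' @param t target `lot_language` (or name).
#' @param cfg an [eval_config()]; only schedule points `<= max_tokens` are
#'   run.
#' @param inf_cfg an [inference_config()].
#' @param n_factors_set factor counts to search.
#' @param seed integer seed.
#' @param max_tokens truncate the schedule (default 50).
#' @param verbose print progress.
#' @return A data frame with columns n_tokens, precision, recall, f,
#'   memorized_f, seed.
#' @export
learning_curve <- function(t, cfg = eval_config(),
                           inf_cfg = inference_config(),
                           n_factors_set = 1L, seed = 1L, max_tokens = 50,
                           verbose = FALSE) {
  if (is.character(t)) t <- get_language(t)
  schedule <- cfg$data_schedule[cfg$data_schedule <= max_tokens]
  rows <- list()
  for (n in schedule) {
    D <- sample_dataset(t, n, seed = seed * 1000L + n %% 997L)
    res <- search_over_factor_counts(D, t$alphabet, n_factors_set,
                                     cfg = inf_cfg, seed = seed)
    pr <- posterior_precision_recall(res$merged, D, cfg, target = t)
    mem <- memorized_f(D, t, cfg)
    if (verbose)
      message(sprintf("n=%d: P=%.3f R=%.3f F=%.3f memF=%.3f", n,
                      pr$precision, pr$recall, pr$f, mem$f))
    rows[[length(rows) + 1L]] <-
      data.frame(n_tokens = n, precision = pr$precision, recall = pr$recall,
                 f = pr$f, memorized_f = mem$f, seed = seed)
  }
  do.call(rbind, rows)
}

#' Generalisation matrix over unseen probe strings
#'
#' Each row is a hypothesis (sorted by posterior weight, duplicated
#' generalisation patterns removed); each column a probe string not in the
#' training data; entries are the hypothesis's log probability of
#' generating the probe (`-Inf` when the probe is outside its enumerated
#' support). Probes occurring in the data are dropped with a warning.
#'
#' @param ps a [posterior_set()].
#' @param D the training dataset.
#' @param probe_strings candidate probes.
#' @param bounds an [eval_bounds()].
#' @return A numeric matrix with attribute `weights`.
#' @export
generalization_matrix <- function(ps, D, probe_strings,
                                  bounds = eval_bounds()) {
  D <- as_dataset(D)
  seen <- probe_strings %in% D$strings
  if (any(seen)) {
    warning(sprintf("dropping %d probe(s) present in the data", sum(seen)))
    probe_strings <- probe_strings[!seen]
  }
  outs <- pset_outputs(ps, bounds)
  m <- matrix(-Inf, nrow = length(outs), ncol = length(probe_strings),
              dimnames = list(NULL, probe_strings))
  for (i in seq_along(outs)) {
    oc <- outs[[i]]$outcomes
    hit <- match(probe_strings, names(oc))
    m[i, !is.na(hit)] <- log(unname(oc[hit[!is.na(hit)]]))
  }
  ord <- order(ps$entries$weight, decreasing = TRUE)
  m <- m[ord, , drop = FALSE]
  wts <- ps$entries$weight[ord]
  pat <- apply(m, 1L, function(r) paste(signif(r, 10), collapse = "|"))
  keep <- !duplicated(pat)
  m <- m[keep, , drop = FALSE]
  attr(m, "weights") <- wts[keep]
  m
}
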