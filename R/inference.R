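# Posterior inference: Metropolis-Hastings with subtree-regeneration
# proposals inside an adaptive parallel-tempering scheme. The likelihood
# (not the prior) is tempered; chains at higher temperatures explore more
# freely and exchange states with cooler chains.

#' Inference configuration
#'
#' Scheduling is by reproducible proposal counts rather than wall-clock
#' time, so identical seeds give identical runs on any machine.
#'
#' @param n_factors number of factors to search over (1..4).
#' @param steps Metropolis-Hastings proposals per chain.
#' @param n_chains number of tempered chains (default 5).
#' @param temp_range temperature ladder endpoints, spaced exponentially
#'   (default `c(1, 1.2)`).
#' @param swap_every propose adjacent-chain swaps every this many steps.
#' @param adapt_every adapt the temperature ladder every this many steps.
#' @param adapt_target target adjacent swap acceptance rate (0.234).
#' @param adapt_kappa adaptation gain (decays over adaptation rounds).
#' @param top_n posterior-set capacity (default 500).
#' @param bounds an [eval_bounds()]; the search default trims the path and
#'   work caps (`max_paths = 1500`, `max_work = 20000`) relative to the
#'   evaluation bounds, which only truncates the enumerated support of
#'   pathological proposals (truncated mass is unexplored and simply earns
#'   no likelihood).
#' @param noise a [noise_model()].
#' @param max_depth proposal subtree depth cap.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(n_factors = 1L, steps = 12000L, n_chains = 5L,
                             temp_range = c(1, 1.2), swap_every = 100L,
                             adapt_every = 2000L, adapt_target = 0.234,
                             adapt_kappa = 0.5, top_n = 500L,
                             bounds = eval_bounds(max_paths = 1500L,
                                                  max_work = 20000),
                             noise = noise_model(), max_depth = 32L) {
  if (length(temp_range) != 2L || temp_range[1] < 1 ||
      temp_range[2] < temp_range[1])
    lot_error("lot_config_error", "invalid temperature ladder")
  structure(list(n_factors = as.integer(n_factors), steps = as.integer(steps),
                 n_chains = as.integer(n_chains), temp_range = temp_range,
                 swap_every = as.integer(swap_every),
                 adapt_every = as.integer(adapt_every),
                 adapt_target = adapt_target, adapt_kappa = adapt_kappa,
                 top_n = as.integer(top_n), bounds = bounds, noise = noise,
                 max_depth = as.integer(max_depth)),
            class = "inference_config")
}

# -- internal fast scoring -------------------------------------------------

score_ll <- function(codes, g, dstrings, dcounts, bounds, nm) {
  cpp_score(codes, length(codes), g$context$alphabet,
            bounds$min_log_prob, bounds$max_recursion, bounds$max_steps,
            bounds$max_outputs, bounds$max_paths, bounds$max_work,
            bounds$max_length,
            dstrings, dcounts, nm$delete_prob, nm$append_prob)
}

codes_log_prior <- function(codes, g) {
  lp <- 0
  for (code in codes) lp <- lp + sum(g$op_logp[code])
  lp
}

codes_key <- function(codes) {
  paste(vapply(codes, paste, "", collapse = ","), collapse = ";")
}

# -- proposals -------------------------------------------------------------

#' Subtree-regeneration proposal
#'
#' Picks one node uniformly at random across all factor trees and
#' regenerates the subtree rooted there from the PCFG, conditioned on its
#' type. Proposals in which some factor is unreachable from the entry
#' factor are rejected outright (`ok = FALSE`).
#'
#' @param h a [lot_hypothesis()] (or internal code list).
#' @param g an [expression_grammar()].
#' @param max_depth regeneration depth cap.
#' @return list with `hypothesis` (or `codes`), `log_hastings`
#'   (log q(h|h') - log q(h'|h)) and `ok`.
#' @export
propose <- function(h, g, max_depth = 32L) {
  res <- propose_codes(h$codes, g, max_depth)
  if (!res$ok)
    return(list(hypothesis = h, log_hastings = -Inf, ok = FALSE))
  list(hypothesis = hypothesis_from_codes(res$codes, g$context),
       log_hastings = res$log_hastings, ok = TRUE)
}

propose_codes <- function(codes, g, max_depth = 32L) {
  sizes <- lengths(codes)
  n <- sum(sizes)
  k <- floor(runif(1) * n) + 1L
  fi <- 1L
  while (k > sizes[fi]) {
    k <- k - sizes[fi]
    fi <- fi + 1L
  }
  code <- codes[[fi]]
  tp <- .lot_types[cpp_node_types(code[k])[1L]]
  new_sub <- NULL
  for (try in 1:20) {
    new_sub <- tryCatch(sample_code(g, tp, max_depth),
                        lot_depth_error = function(e) NULL)
    if (!is.null(new_sub)) break
  }
  if (is.null(new_sub)) return(list(ok = FALSE))
  end <- code_subtree_end(code, k)
  old_sub <- code[k:end]
  new_code <- c(if (k > 1L) code[1:(k - 1L)] else integer(0),
                new_sub,
                if (end < length(code)) code[(end + 1L):length(code)]
                else integer(0))
  codes2 <- codes
  codes2[[fi]] <- as.integer(new_code)
  if (!all_factors_reachable(codes2, length(codes2)))
    return(list(ok = FALSE))
  n2 <- sum(lengths(codes2))
  log_h <- (log(1 / n2) + code_log_prob(old_sub, g)) -
           (log(1 / n) + code_log_prob(new_sub, g))
  list(codes = codes2, log_hastings = log_h, ok = TRUE)
}

# -- chain state and MH kernel --------------------------------------------

new_chain_state <- function(codes, g, dstrings, dcounts, cfg, temperature) {
  structure(list(codes = codes,
                 log_prior = codes_log_prior(codes, g),
                 log_likelihood = score_ll(codes, g, dstrings, dcounts,
                                           cfg$bounds, cfg$noise),
                 temperature = temperature),
            class = "chain_state")
}

init_chain <- function(g, dstrings, dcounts, cfg, temperature,
                       max_tries = 50L) {
  best <- NULL
  for (i in seq_len(max_tries)) {
    codes <- tryCatch(
      lapply(seq_len(cfg$n_factors), function(j) sample_code(g, "STRING",
                                                             cfg$max_depth)),
      lot_depth_error = function(e) NULL)
    if (is.null(codes)) next
    if (!all_factors_reachable(codes, length(codes))) next
    st <- new_chain_state(codes, g, dstrings, dcounts, cfg, temperature)
    if (is.finite(st$log_likelihood)) return(st)
    if (is.null(best)) best <- st
  }
  if (is.null(best))
    lot_error("lot_config_error", "could not initialise a valid chain")
  best
}

#' One Metropolis-Hastings step
#'
#' Accepts a proposal with probability
#' `min(1, exp(d_log_prior + d_log_lik / T + log_hastings))`. The data
#' log-likelihood is divided by the chain temperature; the prior is not
#' tempered. Every scored hypothesis is offered to the posterior set at
#' temperature-1 scoring.
#'
#' @param state a chain state (from [run_parallel_tempering()] internals or
#'   built by scoring a hypothesis).
#' @param D dataset (or character vector).
#' @param g an [expression_grammar()].
#' @param cfg an [inference_config()].
#' @param pset optional posterior-set accumulator environment.
#' @return The new chain state (with attribute `accepted`).
#' @export
mh_step <- function(state, D, g, cfg = inference_config(), pset = NULL) {
  D <- as_dataset(D)
  mh_step_fast(state, D$strings, D$counts, g, cfg, pset)
}

mh_step_fast <- function(state, dstrings, dcounts, g, cfg, pset) {
  pr <- propose_codes(state$codes, g, cfg$max_depth)
  if (!pr$ok) {
    attr(state, "accepted") <- FALSE
    return(state)
  }
  lp2 <- codes_log_prior(pr$codes, g)
  ll2 <- score_ll(pr$codes, g, dstrings, dcounts, cfg$bounds, cfg$noise)
  if (!is.null(pset) && is.finite(ll2)) pset_offer(pset, pr$codes, lp2, ll2)
  ll1 <- state$log_likelihood
  dll <- if (ll2 == -Inf && ll1 == -Inf) 0 else ll2 - ll1
  la <- (lp2 - state$log_prior) + dll / state$temperature + pr$log_hastings
  if (is.nan(la)) la <- -Inf
  if (la >= 0 || log(runif(1)) < la) {
    st <- structure(list(codes = pr$codes, log_prior = lp2,
                         log_likelihood = ll2,
                         temperature = state$temperature),
                    class = "chain_state")
    attr(st, "accepted") <- TRUE
    return(st)
  }
  attr(state, "accepted") <- FALSE
  state
}

# -- posterior set accumulator ---------------------------------------------

pset_new <- function(top_n) {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(parent = emptyenv())
  e$n <- 0L
  e$top_n <- as.integer(top_n)
  e
}

pset_offer <- function(e, codes, lp, ll) {
  key <- codes_key(codes)
  if (!is.null(e$map[[key]])) return(invisible(FALSE))
  e$map[[key]] <- list(codes = codes, lp = lp, ll = ll)
  e$n <- e$n + 1L
  if (e$n > 4L * e$top_n) pset_prune(e)
  invisible(TRUE)
}

pset_prune <- function(e) {
  keys <- ls(e$map)
  sc <- vapply(keys, function(k) {
    v <- e$map[[k]]
    v$lp + v$ll
  }, 0)
  drop <- keys[order(sc, decreasing = TRUE)][-seq_len(e$top_n)]
  rm(list = drop, envir = e$map)
  e$n <- e$n - length(drop)
}

pset_entries <- function(e) {
  keys <- ls(e$map)
  lapply(keys, function(k) e$map[[k]])
}

#' Posterior sets
#'
#' The top-N (default 500) hypotheses found, with posterior weights
#' renormalised to sum to one over the set. Entries are unique up to
#' structural identity of the printed form.
#'
#' @param entries list of `list(codes, lp, ll)` records.
#' @param ctx the [lot_context()].
#' @param top_n capacity.
#' @return An object of class `posterior_set`: a list with `entries` (a
#'   data frame: rank, n_factors, factors, log_prior, log_likelihood,
#'   weight) and `codes` (list of code lists, parallel to the rows).
#' @export
posterior_set <- function(entries, ctx, top_n = 500L) {
  entries <- entries[vapply(entries, function(v) is.finite(v$ll), TRUE)]
  if (!length(entries))
    lot_error("lot_eval_error", "no scoreable hypotheses found")
  sc <- vapply(entries, function(v) v$lp + v$ll, 0)
  ord <- order(sc, decreasing = TRUE)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  entries <- entries[ord]
  sc <- sc[ord]
  w <- exp(sc - logsumexp(sc))
  printed <- vapply(entries, function(v) {
    paste(vapply(v$codes, function(code) {
      print_expression(code_to_expr(code, ctx), ctx)
    }, ""), collapse = " ; ")
  }, "")
  df <- data.frame(
    rank = seq_along(entries),
    n_factors = vapply(entries, function(v) length(v$codes), 0L),
    factors = printed,
    log_prior = vapply(entries, function(v) v$lp, 0),
    log_likelihood = vapply(entries, function(v) v$ll, 0),
    weight = w,
    stringsAsFactors = FALSE
  )
  structure(list(entries = df, codes = lapply(entries, function(v) v$codes),
                 context = ctx),
            class = "posterior_set")
}

#' @export
print.posterior_set <- function(x, ...) {
  cat(sprintf("<posterior_set> %d hypotheses (n_factors = %d)\n",
              nrow(x$entries), x$entries$n_factors[1]))
  show <- head(x$entries, 5L)
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  [%.3f] %s\n", show$weight[i], show$factors[i]))
  }
  if (nrow(x$entries) > 5L) cat("  ...\n")
  invisible(x)
}

#' Serialise a posterior set as JSON lines
#'
#' One record per hypothesis: rank, n_factors, printed factors, log prior,
#' log likelihood, weight.
#' @param ps a `posterior_set`.
#' @param path file path.
#' @export
write_posterior_set <- function(ps, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(ps$entries))) {
    writeLines(jsonlite::toJSON(as.list(ps$entries[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

# -- parallel tempering ----------------------------------------------------

#' Search for hypotheses by adaptive parallel tempering
#'
#' Runs `n_chains` Metropolis-Hastings chains at temperatures spaced
#' exponentially over `temp_range`, proposing adjacent-chain swaps every
#' `swap_every` steps (standard tempered-swap rule) and adapting the
#' temperature ladder every `adapt_every` steps towards the target swap
#' acceptance rate. Fully reproducible given `seed`.
#'
#' @param D dataset (an `lot_dataset` or character vector of tokens).
#' @param g an [expression_grammar()]; its context's `n_factors` must match
#'   `cfg$n_factors`.
#' @param cfg an [inference_config()].
#' @param seed integer seed.
#' @param verbose print progress.
#' @return A [posterior_set()] of the top `cfg$top_n` hypotheses.
#' @export
run_parallel_tempering <- function(D, g, cfg = inference_config(),
                                   seed = 1L, verbose = FALSE) {
  if (g$context$n_factors != cfg$n_factors)
    lot_error("lot_config_error",
              "grammar context has %d factors, config expects %d",
              g$context$n_factors, cfg$n_factors)
  set.seed(seed)
  D <- as_dataset(D)
  # while searching, cap generated-string length a little above the longest
  # observed string: longer outputs contribute only ~delta^k to the
  # likelihood (suffix deletions), which is negligible at default noise
  cfg$bounds$max_length <- min(cfg$bounds$max_length,
                               max(nchar(D$strings)) + 32L)
  K <- cfg$n_chains
  temps <- if (K == 1L) cfg$temp_range[1] else
    exp(seq(log(cfg$temp_range[1] + 1e-12), log(cfg$temp_range[2]),
            length.out = K))
  chains <- lapply(temps, function(tt)
    init_chain(g, D$strings, D$counts, cfg, tt))
  pset <- pset_new(cfg$top_n)
  for (ch in chains) {
    if (is.finite(ch$log_likelihood))
      pset_offer(pset, ch$codes, ch$log_prior, ch$log_likelihood)
  }
  n_blocks <- max(1L, cfg$steps %/% cfg$swap_every)
  swap_acc <- rep(0, max(K - 1L, 1L))
  swap_try <- rep(0, max(K - 1L, 1L))
  adapt_round <- 0L
  for (b in seq_len(n_blocks)) {
    for (i in seq_len(K)) {
      st <- chains[[i]]
      for (s in seq_len(cfg$swap_every)) {
        st <- mh_step_fast(st, D$strings, D$counts, g, cfg, pset)
      }
      chains[[i]] <- st
    }
    if (K > 1L) {
      for (j in seq_len(K - 1L)) {
        ci <- chains[[j]]; cj <- chains[[j + 1L]]
        swap_try[j] <- swap_try[j] + 1
        if (is.finite(ci$log_likelihood) && is.finite(cj$log_likelihood)) {
          la <- (1 / ci$temperature - 1 / cj$temperature) *
                (cj$log_likelihood - ci$log_likelihood)
          if (la >= 0 || log(runif(1)) < la) {
            tmp <- ci
            ci <- cj; cj <- tmp
            ci$temperature <- chains[[j]]$temperature
            cj$temperature <- chains[[j + 1L]]$temperature
            chains[[j]] <- ci; chains[[j + 1L]] <- cj
            swap_acc[j] <- swap_acc[j] + 1
          }
        }
      }
    }
    if (K > 1L && (b * cfg$swap_every) %% cfg$adapt_every == 0L) {
      adapt_round <- adapt_round + 1L
      rate <- ifelse(swap_try > 0, swap_acc / swap_try, 0)
      gaps <- diff(log(temps + 1e-12))
      kap <- cfg$adapt_kappa / adapt_round
      gaps <- gaps * exp(kap * (rate - cfg$adapt_target))
      gaps <- pmin(pmax(gaps, 1e-6), log(4))
      temps <- c(temps[1], temps[1] * exp(cumsum(gaps)))
      for (i in seq_len(K)) chains[[i]]$temperature <- temps[i]
      if (verbose)
        message(sprintf("block %d: swap rates %s; temps %s", b,
                        paste(sprintf("%.2f", rate), collapse = " "),
                        paste(sprintf("%.3f", temps), collapse = " ")))
      swap_acc[] <- 0; swap_try[] <- 0
    }
  }
  posterior_set(pset_entries(pset), g$context, cfg$top_n)
}

#' Independent searches per factor count
#'
#' Runs one parallel-tempering search per factor count and merges the
#' resulting sets with joint renormalisation over the union's top N.
#'
#' @param D dataset.
#' @param alphabet alphabet character vector.
#' @param n_factors_set factor counts to search (default 1:4).
#' @param cfg an [inference_config()] (its `n_factors` is overridden).
#' @param seed integer seed.
#' @param ... passed to [expression_grammar()].
#' @return list with `by_n` (posterior set per factor count) and `merged`.
#' @export
search_over_factor_counts <- function(D, alphabet, n_factors_set = 1:4,
                                      cfg = inference_config(), seed = 1L,
                                      ...) {
  by_n <- list()
  for (nf in n_factors_set) {
    g <- expression_grammar(lot_context(alphabet, nf), ...)
    cfg_n <- cfg
    cfg_n$n_factors <- as.integer(nf)
    by_n[[as.character(nf)]] <-
      run_parallel_tempering(D, g, cfg_n, seed = seed + nf)
  }
  list(by_n = by_n, merged = merge_posterior_sets(by_n, cfg$top_n))
}

#' Merge posterior sets with joint renormalisation
#'
#' @param sets list of `posterior_set`s (possibly with different factor
#'   counts).
#' @param top_n capacity of the merged set.
#' @return A `posterior_set` whose weights sum to one over the union's top
#'   N by unnormalised posterior score.
#' @export
merge_posterior_sets <- function(sets, top_n = 500L) {
  recs <- list()
  ctx <- NULL
  for (ps in sets) {
    if (is.null(ctx)) ctx <- ps$context
    for (i in seq_len(nrow(ps$entries))) {
      recs[[length(recs) + 1L]] <- list(
        codes = ps$codes[[i]],
        lp = ps$entries$log_prior[i],
        ll = ps$entries$log_likelihood[i])
    }
  }
  # contexts may differ in n_factors; keep the one with the most factors so
  # every factor reference prints
  for (ps in sets)
    if (ps$context$n_factors > ctx$n_factors) ctx <- ps$context
  posterior_set(recs, ctx, top_n)
}
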