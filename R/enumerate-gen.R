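# Best-first enumeration over an arbitrary stochastic generator function.
# A generator is written against a "chooser": gen(ch) calls ch$flip(p) and
# ch$pick(values, probs) and returns a string. Running it with a random
# chooser samples; running it under choice-prefix replay enumerates the
# most probable outcomes (the same strategy the program evaluator uses for
# stochastic primitives).

random_chooser <- function() {
  list(
    flip = function(p) runif(1) < p,
    pick = function(values, probs = NULL) {
      n <- length(values)
      if (is.null(probs)) return(values[[floor(runif(1) * n) + 1L]])
      values[[sample.int(n, 1L, prob = probs)]]
    }
  )
}

# max-heap keyed by (lp desc, seq asc) with preallocated vectors
heap_new <- function(cap = 1024L) {
  e <- new.env(parent = emptyenv())
  e$lp <- numeric(cap); e$seq <- numeric(cap)
  e$choices <- vector("list", cap)
  e$n <- 0L
  e
}
heap_less <- function(e, i, j) {  # TRUE if i has lower priority than j
  e$lp[i] < e$lp[j] || (e$lp[i] == e$lp[j] && e$seq[i] > e$seq[j])
}
heap_swap <- function(e, i, j) {
  tmp <- e$lp[i]; e$lp[i] <- e$lp[j]; e$lp[j] <- tmp
  tmp <- e$seq[i]; e$seq[i] <- e$seq[j]; e$seq[j] <- tmp
  tmp <- e$choices[[i]]; e$choices[[i]] <- e$choices[[j]]; e$choices[[j]] <- tmp
}
heap_push <- function(e, lp, seq, choices) {
  if (e$n == length(e$lp)) {
    e$lp <- c(e$lp, numeric(e$n)); e$seq <- c(e$seq, numeric(e$n))
    e$choices <- c(e$choices, vector("list", e$n))
  }
  e$n <- e$n + 1L
  i <- e$n
  e$lp[i] <- lp; e$seq[i] <- seq; e$choices[[i]] <- choices
  while (i > 1L) {
    p <- i %/% 2L
    if (heap_less(e, p, i)) {
      heap_swap(e, p, i)
      i <- p
    } else break
  }
}
heap_pop <- function(e) {
  out <- list(lp = e$lp[1L], choices = e$choices[[1L]])
  heap_swap(e, 1L, e$n)
  e$choices[[e$n]] <- NULL_choice
  e$n <- e$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    big <- i
    if (l <= e$n && heap_less(e, big, l)) big <- l
    if (r <= e$n && heap_less(e, big, r)) big <- r
    if (big == i) break
    heap_swap(e, i, big)
    i <- big
  }
  out
}
NULL_choice <- integer(0)

# Enumerate outcomes of gen down to a log-probability floor. If stop_k is
# given, enumeration also stops once the k best outcomes can no longer be
# displaced by any pending path (exact for unambiguous generators).
enumerate_generator <- function(gen, min_log_prob = -18, max_paths = 50000L,
                                max_choices = 400L, stop_k = NULL) {
  outcomes <- new.env(parent = emptyenv())
  n_out <- 0L
  h <- heap_new()
  heap_push(h, 0, 0, integer(0))
  seq_ctr <- 0
  n_paths <- 0L
  unexplored <- 0
  while (h$n > 0L) {
    it <- heap_pop(h)
    if (it$lp < min_log_prob || n_paths >= max_paths) {
      unexplored <- unexplored + exp(it$lp)
      next
    }
    if (!is.null(stop_k) && n_out >= stop_k) {
      p <- vapply(ls(outcomes), function(k) outcomes[[k]], 0)
      if (sort(p, decreasing = TRUE)[stop_k] >= exp(it$lp)) {
        unexplored <- unexplored + exp(it$lp)
        next
      }
    }
    n_paths <- n_paths + 1L
    idx <- 0L
    fork <- NULL
    ch <- list(
      flip = function(p) {
        idx <<- idx + 1L
        if (idx <= length(it$choices)) return(it$choices[idx] == 1L)
        fork <<- list(probs = c(p, 1 - p))
        stop("lot_gen_fork")
      },
      pick = function(values, probs = NULL) {
        idx <<- idx + 1L
        n <- length(values)
        if (is.null(probs)) probs <- rep(1 / n, n)
        if (idx <= length(it$choices)) return(values[[it$choices[idx]]])
        fork <<- list(probs = probs)
        stop("lot_gen_fork")
      }
    )
    res <- tryCatch(gen(ch), error = function(e) {
      if (!grepl("lot_gen_fork", conditionMessage(e))) stop(e)
      NULL
    })
    if (is.null(res)) {
      if (idx > max_choices) {
        unexplored <- unexplored + exp(it$lp)
        next
      }
      for (b in seq_along(fork$probs)) {
        if (fork$probs[b] <= 0) next
        seq_ctr <- seq_ctr + 1
        heap_push(h, it$lp + log(fork$probs[b]), seq_ctr,
                  c(it$choices, b))
      }
    } else {
      key <- paste0("s:", res)
      prev <- outcomes[[key]]
      if (is.null(prev)) n_out <- n_out + 1L
      outcomes[[key]] <- (if (is.null(prev)) 0 else prev) + exp(it$lp)
    }
  }
  keys <- ls(outcomes)
  p <- unname(vapply(keys, function(k) outcomes[[k]], 0))
  s <- substring(keys, 3L)
  ord <- order(-p, nchar(s), s)
  list(strings = s[ord], probs = p[ord], unexplored = unexplored)
}
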