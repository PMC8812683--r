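---
title: "Learning formal languages by Bayesian program induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning formal languages by Bayesian program induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lotlang)
```

## The model

`lotlang` learns a *generative program* for a formal language from positive
string examples alone. A hypothesis $H$ is a tuple of factors
$F_0,\dots,F_{n-1}$ ($n \le 4$), each a typed expression over a small
inventory of domain-general primitives: list operations (`pair`, `first`,
`rest`, `insert`, `append`), Boolean logic (`flip`, `equals`, `empty`,
`if`, `and`, `or`, `not`), set operations (the alphabet set `Σ`, singleton
sets, `union`, `setminus`, `sample`), and factor calls `Fi` / memoised
`Fmi`. `flip` and `sample` make programs stochastic, so a hypothesis
denotes a probability distribution over output strings. The last factor is
the entry point and is evaluated with its argument `x` bound to the empty
string `ϵ`.

Learning is posterior inference,
$P(H \mid D) \propto P(H)\, P(D \mid H)$, where

* $P(H)$ is a probabilistic context-free grammar (PCFG) over expressions —
  nonterminals are the five value types, the productions of a nonterminal
  are the primitives returning that type, and the probability of a tree is
  the product of its production probabilities. This penalises program size
  multiplicatively, i.e. it is a simplicity prior.
* $P(D \mid H)$ is a *prefix likelihood*: each observed token is explained
  by a generated string passed through a noise channel that deletes
  characters from the end (each with probability $\delta$) and then
  appends characters drawn uniformly from the alphabet (each with
  probability $\gamma$). A hypothesis that gets most of a string right
  therefore earns partial credit, which gives hill-climbing search a
  gradient.

The canonical example, the geometric $a^n$ language, is the one-factor
program

```{r}
ctx <- lot_context("a", 1)
h <- lot_hypothesis(list("pair(if(flip(1/3),ϵ,F0(ϵ)),a)"), ctx)
h
run_program(h)
```

whose output law is exactly $P(a^n) = (2/3)^{n-1} \cdot 1/3$.

## Evaluating stochastic programs

`run_program()` computes the marginal distribution over output strings by
enumerating execution paths best-first in order of path probability: at
every stochastic site the path forks, forks are kept in a priority queue
(FIFO among ties), and each popped prefix of recorded choices is replayed
deterministically. Memoised calls `Fmi` return the value recorded for an
earlier call with the same argument within the same top-level run; the
memo table is keyed by (factor index, argument) and rebuilt identically on
replay.

The default resource bounds are: paths are abandoned (to *unexplored
mass*) below a log-probability floor of $-15$; recursion beyond depth 64,
more than 1,024 primitive applications on a path, or runtime errors
(`first`/`rest` of `ϵ`, `sample` of the empty set) convert the path to
*error mass*; and enumeration stops at 256 distinct outputs. Three
additional caps are this package's own termination guarantees, needed
because a random proposal can make combinatorially many forks that
collapse onto few outputs, or build strings of exponentially growing
length: at most `max_paths = 3000` enumerated paths, a total work budget
of `max_work = 50000` primitive applications per run, and a string length
cap `max_length = 1024` (length violations are error mass; path/work
truncations are unexplored mass). Outcome probabilities, unexplored and
error mass always sum to one (up to $10^{-9}$). `eval_bounds_large()` is a
preset with a $-25$ floor and a 2,048-output cap for rich grammars such as
the simplified English grammar, which need a larger enumerated
distribution.

The likelihood uses only enumerated outcomes — truncated mass simply
earns nothing — so scores are lower bounds that are tight for the
well-behaved programs the search favours. `monte_carlo_run()` is an
independent pure-R forward sampler with the same semantics; the test suite
checks total-variation agreement with the enumerator on a fixed suite of
twelve stochastic programs.

## The noise channel, exactly

For a generated string $o$ and observed string $d$,

$$P(d \mid o) = \sum_{k=0}^{|o|}
  \mathbf{1}\left[o_{1:|o|-k} \text{ is a prefix of } d\right]
  P_\mathrm{del}(k)\,
  (\gamma/|\Sigma|)^{|d| - |o| + k} (1 - \gamma),$$

with $P_\mathrm{del}(k) = \delta^k (1-\delta)$ for $k < |o|$ and
$P_\mathrm{del}(|o|) = \delta^{|o|}$: once the whole string has been
deleted there is nothing left to try to delete, so no continue/stop factor
is charged. This convention makes the channel normalise *exactly* —
$\sum_d P(d \mid o) = 1$ — which the tests verify by exhaustive
enumeration; charging $\delta^{|o|}(1-\delta)$ instead would leave a
$\delta^{|o|+1}$ deficit. Defaults are $\delta = \gamma = 0.01$: small
enough that the likelihood is sharp, large enough that partial credit
guides search. The noise parameters are fixed, not fitted; they are
exposed in `noise_model()`.

## Search

`run_parallel_tempering()` runs five Metropolis–Hastings chains at
temperatures spaced exponentially from 1 to 1.2. Proposals regenerate the
subtree at a node chosen uniformly at random across all factor trees from
the PCFG conditioned on the node's type; the Hastings correction uses the
node counts and subtree PCFG probabilities. Proposals leaving any factor
unreachable from the entry factor are rejected outright. Only the data
log-likelihood is tempered (divided by $T$); the prior is not. Adjacent
chains propose state swaps every `swap_every = 100` proposals, accepted
with the standard tempered-swap rule, and the ladder adapts every
`adapt_every = 2000` proposals by scaling the log-temperature gaps toward
a target adjacent-swap acceptance of 0.234 (a stochastic-approximation
update with decaying gain). Scheduling is by proposal counts rather than
wall-clock time so that runs are exactly reproducible from a seed.

Every hypothesis scored anywhere in the ladder is offered to a shared
top-500 posterior set, deduplicated by canonical printed form; at the end
the set's weights are renormalised to sum to one. `search_over_factor_counts()`
runs one search per factor count and merges the results with joint
renormalisation over the union's top 500.

Two numerical choices matter for throughput. While searching, the
string-length cap is trimmed to the longest observed datum plus 32
characters — longer outputs could only match data through massive
suffix deletion, contributing $O(\delta^{30})$ likelihood — and the
search bounds trim the path/work caps (`max_paths = 1500`,
`max_work = 20000`). Both only truncate the enumerated support of
pathological proposals; evaluation of results always uses the full
`eval_bounds()`.

## Target languages

`language_registry()` provides thirty targets: parametric families across
the Chomsky hierarchy ($a^n$, $(ab)^n$, $\Sigma^+$, $a^nb^n$,
$a^nb^nc^n$, $a^nb^nc^nd^n$, $a^nb^m$, $a^nb^{2n}$, Dyck, mirror
$xx^R$, copy $xx$, crossed $a^nb^mc^nd^m$, $a^nb^ma^nb^mccc$, the
Chinese-numeral-style decreasing-block language, the Count language,
GoldenMean, $a^+ba^+$, the finite $a^{1,2,3}$), artificial-language
stimuli (Saffran-style segmentation with the four-word lexicon
`tapiro/golabu/bidaku/padoti` recoded to characters, Marcus ABA/ABB,
Gómez $aXb$ with $|X| \in \{2, 6, 12\}$, Newport–Aslin nonadjacent
frames, Reber and Berwick–Pilato finite-state machines, a
Morgan–Newport-style optional-constituent phrase grammar, Reeder QAXB
with six held-out strings), and a simplified English part-of-speech
grammar
$S \to NP\ VP$, $NP \to n \mid d\,n \mid d\,AP\,n \mid NP\ PP$,
$AP \to a \mid a\,AP$, $VP \to v \mid v\,NP \mid v\,t\,S \mid VP\ PP$,
$PP \to p\,NP$.

Each target is written as a *chooser program*: the same generator yields
i.i.d. samples when driven by a random number stream and exact best-first
top-$k$ enumeration when driven by choice-prefix replay — the identical
strategy the program evaluator uses. Repetition indices and lengths are
geometric with stop probability 1/3 by default, matching the `flip(1/3)`
worked examples; finite languages get geometrically decaying weights over
an enumeration order (uniform distributions would make the top-$k$
metric degenerate). Probabilities not fixed by any printed description
are package choices: FSM transitions are uniform over out-edges, the
English grammar's expansions decay as $2^{-i}$ over the listed
productions of each nonterminal, and the Berwick–Pilato auxiliary machine
($m?h?b?v$ over recoded words) and the Morgan–Newport grammar are
synthetic reconstructions. Reber's `X` symbol is recoded to `z` because
`x` is the reserved argument symbol of the program syntax; alphabets may
not contain it.

## Evaluation

`posterior_precision_recall()` computes the posterior-weighted top-$k$
precision and recall ($k = 25$ by default, 100 recommended for English):
precision is the weighted fraction of each hypothesis's top-$k$ strings
that are correct, recall the weighted fraction of the reference top-$k$
strings anywhere in the hypothesis's enumerated support, and
$F = 2PR/(P+R)$.

There are two choices of reference. The literal data-referenced form
scores precision against the observed string set and recall against the
data's top-$k$; it is the default when no target is supplied, and the
tests verify it against a brute-force re-derivation. But learning curves
use the *target-referenced* form — precision by target membership,
recall against the target's top-$k$ — for a structural reason: at ten
tokens a correct $a^n$ learner enumerates strings far beyond what a
ten-token sample contains, so data-referenced precision of a *perfect*
learner is about 0.2 and the measure cannot distinguish learning from
memorisation until the sample itself covers the language. The
target-referenced form is also precisely how the memorisation baseline
(`memorized_f()`) is defined — the data multiset's top-$k$ scored
against the target — which makes the gray and red curves commensurable:
the memoriser's recall is the fraction of the target's top-25 strings
ever sampled, which is why it needs on the order of $10^5$ tokens on
$a^nb^nc^n$ while the learner needs about ten.

An instructive consequence of evaluating *support under the enumeration
floor*: on $a^n$ data, the posterior honestly splits mass between rate
variants `flip(1/3)`, `flip(1/2)`, ... of the same program shape. The
`flip(1/2)` variant's paths fall below the $-15$ floor after $a^{21}$, so
its recall against the target's top 25 is $21/25$. At ten tokens the data
only weakly separate the rates, so posterior-weighted $F$ sits near (and
occasionally below) 0.95 depending on the sampled lengths — the
across-seed variance seen in the learning tests is a property of the
ten-token condition, not of the search.

```{r, eval = FALSE}
t <- get_language("an")
D <- sample_dataset(t, 10, seed = 1)
ps <- run_parallel_tempering(D, expression_grammar(lot_context("a", 1)),
                             inference_config(), seed = 1)
posterior_precision_recall(ps, D, eval_config(), target = t)
```

`generalization_matrix()` reports, for probe strings absent from the
data, each top hypothesis's log probability of generating the probe —
the model's beliefs about constructions it has never seen.

## Problem sizes and limitations

The package's default budgets are desk-scale choices: 12,000 proposals
per chain across five chains (about a minute on one core for the
single-letter languages), a top-500 posterior set, and learning-curve
schedules truncated at 50 tokens. These reliably recover $a^n$-class
languages within ten tokens. Context-sensitive targets such as
$a^nb^nc^n$ need a much larger search: the shortest known one-factor
program is around thirteen nodes, and at a few hundred thousand proposals
the search typically reaches an $a^nb^n$-generating waypoint (earning
prefix-likelihood credit) without completing the $c$-suffix counting
trick; closing that gap is a matter of search time, not of model
specification. Bach-style counting languages, $x^{|x|}$ and
$a^{2^n}$ are expected to remain unlearned — they are awkward to express
in this primitive inventory at any budget.

The synthetic generators emulate *idealised study conditions* —
i.i.d. positive examples with geometric lengths from the stated
distributions — not natural corpora: there is no noise in the data
itself, no non-stationarity, and token frequencies follow the generator
exactly. Passing tests therefore show that the inference machinery
recovers generative programs under those conditions; they do not speak to
robustness under realistic child-directed input.

Other fixed numerical choices: probability constants are the finite set
$\{1/4, 1/3, 1/2, 2/3, 3/4\}$ (a proper PCFG needs finite terminals, and
$1/3$ must be expressible), `flip()` is sugar for `flip(1/2)`,
`insert(A,B)` places `B` at $\lfloor |A|/2 \rfloor$ inside `A` (following
the worked `abcd`/`efg` example rather than the table prose, whose
argument order contradicts it), the entry factor is the last one, CHAR
promotes to STRING where a string is expected, terminal productions carry
weight 3 (shared across the alphabet block and across the probability
block) to keep the PCFG branching process subcritical, and grammar ties
in the frontier pop first-in-first-out for bit-reproducibility.
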