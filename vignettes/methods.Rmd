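---
title: "Methods: uncertainty-prioritized labeling and the normalized sentiment index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-prioritized labeling and the normalized sentiment index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sentistream)
```

`sentistream` implements a continuously-learning sentiment surveillance
pipeline for short-text streams. This vignette is the package's account of
the underlying model and procedure: what is computed, under which
assumptions, which knobs matter, and what the synthetic test bed does and
does not establish about real data.

## 1. The pipeline model

A *post* is a timestamped short text. The pipeline operates in five
stages.

**Keyword filtering.** A post enters the system iff at least one keyword
equals, case-insensitively, a token of its tokenized text. We deliberately
interpret "exact match" at the token level (no stemming: "vaccines" does
not match keyword "vaccine") because token-exact matching is reproducible
and testable; stream APIs in the wild use looser, undocumented dialects,
and a `substring_match` switch is provided for that behavior.
Tokenization lowercases, maps URLs to `<url>` and @-mentions to `<user>`,
and splits on runs of non-alphanumeric characters.

**Labeling priority.** Labeling capacity is the scarce resource. Each
queue-eligible post is scored

$$s = \lambda\,U + (1 - \lambda)\,e^{-a/\tau},$$

where $U \in [0,1]$ is the label uncertainty of the current classifier,
$a$ is the post's age in seconds, $\lambda \in [0,1]$ (default 0.5)
weights uncertainty against recency and $\tau$ (default 86,400 s = 1 day)
is the recency decay constant. The exponential decay keeps $s \in [0,1]$
and makes "old and low-priority" a single comparison. The blend itself is
a design choice: the monitoring literature names the two ingredients —
uncertainty (exploitation for the learner) and timeliness (exploration of
the current distribution) — but no canonical formula; we expose
$\lambda, \tau$ rather than claim an optimum. $\lambda = 1$ is classical
uncertainty sampling, which is what the active-learning loop uses by
default; `blended` uses the configured $\lambda$.

The queue is bounded (default 100). When full, the incoming item competes
with the current minimum *recomputed at insertion time*, so recency decay
is honored; the loser is dropped. Ties break deterministically (newer
first, then post id) so runs are reproducible. A post retires from the
queue after `n_consensus` (default 3) *distinct* users complete its
question sequence; a user abandoning a sequence mid-way leaves no trace
and may be served the same post again, but a user who completed it never
sees it twice.

**Question sequences and consensus.** Annotation is a walk through a DAG
of questions; each answer selects the next question or `END`, and each
answered question is one immutable (user, post, question, answer) row.
Answers may carry a class tag. A user's *vote* is the tag of the last
tagged answer on their path; users routed to `END` before any tagged
answer (e.g. answering "irrelevant" on the relevance question) vote
`irrelevant`. The consensus label is the strict majority ($> n/2$) of the
votes; anything less is `unresolved` and excluded from training. Strict
majority is conservative by intent — plurality labels at agreement
$\le 1/2$ are exactly the labels most likely to be noise. How multiple
tagged questions should combine into one training label is genuinely open;
the terminal-tag rule is the simplest policy consistent with
relevance-then-sentiment sequences and is isolated in `user_vote()` so
alternatives can be swapped in.

**Classifier.** The platform contract is: fast retraining, calibrated-ish
probabilities, no manual features. We use ridge multinomial logistic
regression on unigram+bigram counts (fitted with `glmnet`, $\alpha = 0$,
per-observation penalty $\lambda_{\mathrm{ridge}} = 0.01$, tokens with
document frequency $< 2$ pruned). Prediction is a plain softmax over the
extracted coefficient matrix, so saved models are portable text.
Out-of-vocabulary tokens are ignored; an all-OOV text falls back to the
bias-only softmax, i.e. the model's class prior. Subword embeddings and
pretrained vectors are intentionally out of scope; the classifier sits
behind a small interface (`train_bow` / `predict_proba`) precisely so a
stronger model can replace it. Uncertainty is least-confidence
$1 - \max_k p_k$ by default; normalized entropy
$-\sum p_k \log p_k / \log K$ is available, both in $[0,1]$.

**Active learning loop.** Repeat: predict the unlabeled pool, enqueue by
strategy, serve the top of the queue to `n_consensus` simulated
annotators, aggregate consensus, and retrain after every `retrain_every`
(default 100) new consensus labels — consensus labels, not raw
annotations, because the consensus is the unit of training data.
Accuracy is measured on a 20% stratified held-out split fixed up front
and never queued; the loop asserts that no labeled post id intersects the
test split. The random strategy replaces the uncertainty score with a
uniform draw — everything else identical — giving a paired control arm.

## 2. Trend analytics

Counts are binned per class into right-open daily bins $[t, t + 1\,
\mathrm{day})$; display smoothing is a trailing 1-week moving average
(prefix bins average over what exists). The trend signal is built from
the *polar* posts only:

$$r_t = \frac{\sum P}{\sum P + \sum N}
\quad\text{over the trailing 30-day window},$$

the fraction of positive among positive+negative posts; neutral posts are
excluded by definition but reported in the counts. Windows with fewer
than `min_polar_count` (default 10) polar posts leave $r_t$ undefined
rather than noisy. The **sentiment index** is

$$z_t = (r_t - \mu) / \sigma,$$

with $\mu$ and $\sigma$ the mean and *population* standard deviation of
the defined $r_t$ — population, so the identity "mean 0, sd 1 over
defined bins" is exact rather than approximate, which the tests assert to
1e-9. Because $r$ is a ratio, multiplying the stream volume leaves its
expectation unchanged: the index is volume-invariant by construction, and
the acceptance suite verifies a five-fold rate change moves the index by
< 0.2 mean absolute difference. If $\sigma$ falls at or below a floor
(1e-12) — a constant ratio — the index degenerates to zeros with a
warning instead of exploding.

Two estimation choices were open and are worth stating. First, $\mu$ and
$\sigma$ are computed over the full analyzed series; for prospective
monitoring they should be frozen on a reference period, which the caller
can do by normalizing manually, but retrospective whole-series
normalization is the default because it is the natural reading of a
retrospective trend figure. Second, the lowess curve (tricube weights,
2 robustness iterations, span 0.1 of the defined points via
`stats::lowess`) is fitted to the *normalized index*, not to $r$; the two
differ only by an affine map, which lowess preserves, so the choice only
fixes the plotted scale. Windows are trailing rather than centered
throughout: causal, so the same code can run in real time.

## 3. The synthetic test bed

The generator emulates exactly the stream features the analytics assume:
day-scale volume variation (per-day Poisson counts with uniform within-day
times — simple and exactly analyzable), a class mixture that can shift
abruptly (`inject_changepoint`), and bag-of-tokens text whose learnability
is set by `class_token_share`, the fraction of a post's tokens drawn from
its class's private vocabulary. Every post carries one keyword token by
default so filter pass-through is controlled; `nonmatch_fraction`
exercises the reject branch. Simulated annotators answer through the same
question-sequence machinery as a human would, with errors from a
row-stochastic confusion matrix (uniform off-diagonal when only an
accuracy is given) — the simplest defensible error model, since no
empirical annotator-error model is available. Each annotator owns a
private RNG stream, so answers are reproducible given (seed, call
sequence) regardless of surrounding code.

Default study conditions used by the experiments and the acceptance
script: 3,000-post streams (30 days × 100/day for the learning fixture),
`class_token_share = 0.25` with 5–10 tokens per post — hard enough that
300 labels do not saturate the learner, so query strategies are
distinguishable — five annotators of accuracy 0.9, consensus of 3,
budget 300, retrain every 100, 60 initial random seed labels (drawing
continues past 60 in the rare case a class is still unrepresented, since
the fit requires every class). The drift scenario is 200 posts/day for
120 days with the polar-positive share stepping 0.5 → 0.7 at day 60 and
the neutral share fixed at 1/3.

What the generator does *not* emulate: real language (no grammar, no
polysemy, no class overlap beyond shared background tokens), annotator
bias that is correlated across users, bursty within-day volume, and label
classes whose meaning drifts. Passing tests therefore demonstrate that
the machinery is correct and that uncertainty sampling beats random
sampling *when the signal is a stable token distribution* — not that
equivalent gains will materialize on any particular real stream.

## 4. Numerical and degenerate-input choices

- Probability vectors must sum to 1 within 1e-9 at I/O boundaries;
  classifier outputs satisfy this by construction (softmax).
- Consensus of three annotators with independent accuracy $p$ recovers
  the truth with probability $p^3 + 3p^2(1-p)$ (0.972 at $p = 0.9$)
  regardless of how wrong votes distribute, because a single correct vote
  can never be a strict majority of three; the Monte-Carlo acceptance
  check sits within ±0.01 of this closed form at $n = 10{,}000$.
- Queue score ties: newer `enqueued_at` first, then lexicographic post
  id; eviction ties: oldest first. All deterministic.
- `glmnet` is run to a tight tolerance (`thresh = 1e-12`) down a short
  lambda path; this makes the fit reproducible and makes duplicating the
  training set a no-op (the objective is per-observation averaged), which
  is tested to 1e-6.
- Empty text, all-OOV text: prior softmax, never an error. Empty streams,
  missing classes in training data, fewer than 2 defined ratio points,
  fewer than 10 defined index points: immediate errors naming the
  problem.

## 5. Experiment sizes

The shipped experiments are sized for a single CPU: the paired strategy
comparison uses 10 seeds × 2 arms × (1 initial fit + 3 retrains) on
3,000-post streams; the drift and volume checks analyze 24k- and
120k-post streams through the trend chain; the consensus Monte Carlo uses
10,000 items; the demo runs the full pipeline twice to prove artifact
determinism. These sizes give comfortable statistical margins (e.g. the
strategy gap at the final checkpoint is ~5 accuracy points against a
seed-to-seed spread of ~2) while keeping the whole suite to a few
minutes.

## 6. Known limitations

- The classifier is a linear bag-of-words model; its uncertainty is
  poorly calibrated early in training, which mildly blunts uncertainty
  sampling at the first checkpoint (the dominance claim is made from the
  second checkpoint on, and strictly at the end).
- The queue contract is single-writer; concurrent annotators are
  serialized by construction. This matches a simulation harness, not a
  multi-process deployment.
- `irrelevant`-voted consensus outcomes are counted against the labeling
  budget but excluded from training, mirroring real annotation cost.
- The trend module requires both polar classes to appear; a stream with
  no negative posts at all has an undefined ratio and errors out rather
  than reporting a constant index.
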