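# sentistream

Active-learning sentiment surveillance for streams of short social-media
posts.

## The problem

Public-health researchers increasingly monitor attitudes — toward
vaccination in particular — through social-media streams. Two things make
this hard in practice. First, classifiers trained once degrade as the
language of the stream drifts, so labels must be collected continuously
and the model retrained; labeling effort is scarce, so the posts humans
label should be the ones the classifier is most uncertain about, balanced
against recency of the data. Second, raw per-class counts are dominated by
large swings in stream volume, so a trend signal must be normalized before
it says anything about sentiment.

`sentistream` is a desk-scale implementation of that whole workflow:

1. **Ingest** — keyword filtering (token-exact, case-insensitive),
   tokenization, prediction metadata attached to each post.
2. **Labeling queue** — a bounded priority queue scoring each post by
   `lambda * U + (1 - lambda) * exp(-age / tau)`, where `U` is the label
   uncertainty (least confidence `1 - max p`, or normalized entropy);
   full queues evict the lowest-scoring item, and every post is labeled by
   `n_consensus` distinct annotators before it retires.
3. **Annotation** — branching question sequences (a DAG of questions where
   each answer selects the next question); every answer is one annotation
   row; strict-majority consensus over annotators yields the training
   label, with ties marked `unresolved` and excluded from training.
4. **Learning** — a ridge multinomial logistic regression on
   unigram+bigram counts, retrained every `retrain_every` consensus
   labels inside the active learning loop.
5. **Trends** — per-class daily counts, 1-week moving averages, the
   rolling 1-month ratio `r = P / (P + N)` of positive among polar
   (positive + negative) posts, and the **sentiment index**
   `(r - mu) / sigma`, with `mu` and `sigma` the mean and population
   standard deviation of `r` — a volume-invariant trend signal — plus a
   lowess fit of the index.

A synthetic stream generator (inhomogeneous Poisson volume, time-varying
class mixture with injectable changepoints, bag-of-tokens text, simulated
annotators with confusion-matrix noise) makes every stage testable without
any external data.

## Worked example

```r
library(sentistream)

# a 60-day stream, ~50 posts/day, positive share among polar posts
# jumping 0.5 -> 0.7 at day 30
cfg <- demo_stream_config(seed = 42)
posts <- generate_stream(cfg)

annotators <- lapply(1:5, function(k)
  simulated_annotator(paste0("u", k), accuracy = 0.9, seed = 42000 + k))

al <- active_learning_loop(posts, annotators,
                           al_config(strategy = "uncertainty", budget = 300,
                                     rng_seed = 307))
al$history
#>   checkpoint labels_used train_size  accuracy model_version
#> 1          0           0         58 0.4777595             1
#> 2          1         100        156 0.6886326             2
#> 3          2         200        256 0.8846787             3
#> 4          3         300        353 0.9703460             4

series <- trend_report(posts, trend_config(source = "true"))
round(c(mu = series$mu, sigma = series$sigma), 4)
#>     mu  sigma
#> 0.5620 0.0531
```

The history shows held-out accuracy (20% stratified split, never queued)
climbing from near-chance to ~0.97 within 300 consensus labels; `mu` and
`sigma` are the mean and spread of the rolling positive-among-polar ratio,
and `series$index` is the normalized trend that jumps by well over one
sigma across the injected changepoint.

The same pipeline is scriptable from a shell via
`inst/cli/sentistream.R` (`simulate`, `pipeline`, `train`, `al-run`,
`trends`, `demo` subcommands), and `run_demo(dir, seed)` performs the
whole simulate → learn → trend run, writing plain-text artifacts that are
byte-identical across reruns with the same seed.

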