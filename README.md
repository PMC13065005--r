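# aspectrx

Rule-based aspect term extraction and polarity detection for patient drug
reviews, built for human-in-the-loop annotation workflows in
pharmacovigilance.

Post-market drug safety monitoring leans increasingly on what patients
write about their medication, but aspect-level annotation (which *thing*
is being opined on — "side effects", "mood swings" — and with what
polarity) is expensive to produce by hand. `aspectrx` implements a
deterministic annotation scheme that proposes aspect/polarity labels for
review sentences, exports them for sequence-labeling models, and computes
the inter-annotator agreement statistics used to validate samples of its
output against human judges.

## What it computes

Given a POS/dependency-tagged sentence, three extraction patterns emit
aspect candidates:

* a standalone noun with dependency `ROOT` or `nmod`;
* a `compound`-tagged noun joined with the following noun
  ("side affects");
* a noun licensed by a preceding `amod` adjective
  ("depressive *feelings*" → `feelings`).

Candidates are kept only if their embedding's best cosine similarity
against a condition-specific medical vocabulary reaches 0.7 (inclusive).
Sentence polarity `P ∈ [0,1]` is then composed from SentiWordNet-style
`(pos, neg, obj)` triples: opinion words with `obj ≥ Θ` are silent;
otherwise the word sets the running score (`pos`, or `1 − neg` on the
negative side) and any pending modifier flag is applied —

| modifier | rule |
|---|---|
| strong intensifier (boost) | `P ← 1 − (1 − P)²` |
| weak modifier (attenuate) | `P ← P²` |
| negation | `P ← 1 − P` |

Finally `P > θ_pos` → positive, `P < θ_neg` → negative, the closed band
in between → neutral, and a sentence with no scoring opinion word →
`no_opinion`. Defaults: `Θ = 0.5`, `θ_pos = 0.6`, `θ_neg = 0.4`.

The evaluation module provides token-overlap precision / recall / F1
(`P = Correct/Predicted`, `R = Correct/Actual`, `F1 = 2PR/(P+R)`),
Cohen's κ, Fleiss' κ, majority-vote consolidation, and the
non-aspect / uni-word / bi-word token classification used for sequence
evaluation. A synthetic-corpus generator plants pattern-conforming
aspects, class-balanced opinion words and out-of-vocabulary distractors
so the whole pipeline is testable offline.

## Worked example

```r
library(aspectrx)

pipe <- build_pipeline(run_config())   # bundled lexicons + fixture tagger
rec <- annotate_review(list(
  review_id = "ex1", drug_name = "actemra", condition = "rheumatoid arthritis",
  text = paste("I have been truly lucky as I have not experienced any side",
               "affects in the years I have been on Actemra.")), pipe)

s <- rec$sentences[[1]]
s$aspects[[1]]$surface   # "side affects"   (compound-pair pattern)
s$aspects[[1]]$similarity # 1               (verbatim vocabulary hit)
s$polarity               # 0.91
s$label                  # "positive"
```

The intensifier *truly* boosts *lucky* `(0.7, 0, 0.3)` to
`1 − (1 − 0.7)² = 0.91`, above `θ_pos = 0.6`, so the kept aspect
"side affects" is labeled positive; the trailing "not" modifies the
non-opinion verb "experienced" and is never consumed. The same pipeline
on *"so far im feeling quite positive and free of depressive feelings"*
extracts `feelings` and scores `0.7² = 0.49` → neutral, the weak
modifier *quite* having pulled a positive word into the neutral band.

A command-line wrapper ships in `inst/cli/`:

```sh
aspectrx annotate --input reviews.csv --condition depression --out out/
aspectrx agreement --labels annotators.tsv --out out/
aspectrx simulate --n 200 --seed 1 --out sim/
```

`annotate` writes JSONL annotation records plus a CoNLL BIO export
(`O` / `B-ASP` / `I-ASP`) for downstream sequence-labeling models; every
output carries the run-configuration fingerprint.

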