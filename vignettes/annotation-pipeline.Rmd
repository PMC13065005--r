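---
title: "Rule-based aspect annotation of drug reviews: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based aspect annotation of drug reviews: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspectrx)
```

## The problem

Patient-written drug reviews carry signal that clinical trials miss —
adverse reactions, tolerability, quality-of-life effects — but they arrive
as informal free text. Aspect-based sentiment analysis needs the *aspect
terms* (the things being opined on: "side effects", "mood swings",
"feelings") and a *polarity* for each. Hand annotation at corpus scale is
the bottleneck; `aspectrx` implements a deterministic, auditable rule
pipeline that produces candidate annotations for a human-in-the-loop
workflow, together with the agreement statistics (Cohen's and Fleiss'
kappa, majority voting) used to validate samples of its output against
human annotators.

The pipeline has four stages:

1. **Normalization and tagging.** Text is lowercased, digit runs are
   stripped, sentences are split on terminal punctuation, and each
   sentence is tagged with coarse POS (`NOUN/ADJ/ADV/VERB/OTHER`) and a
   dependency label per token through a pluggable tagger contract.
2. **Aspect term extraction.** A single pass over the tagged tokens
   applies three patterns: a `ROOT`/`nmod` noun on its own; a
   `compound`-tagged noun paired with the following noun ("side
   affects"); and a noun licensed by a preceding `amod` adjective
   ("depressive *feelings*").
3. **Vocabulary filtering.** Every candidate is embedded (multi-word
   terms as the mean of token vectors) and compared by cosine similarity
   to a condition-specific medical word list; the maximum over entries
   must reach the cutoff (default 0.7, inclusive).
4. **Polarity detection.** A second pass composes a score $P \in [0,1]$
   from lexicon triples $(pos, neg, obj)$ that sum to 1, with modifier
   flags: a strong intensifier boosts the next opinion word
   ($P \leftarrow 1-(1-P)^2$), a weak modifier attenuates it
   ($P \leftarrow P^2$), a negator flips it ($P \leftarrow 1-P$).
   Scores above $\theta_{pos}$ are positive, below $\theta_{neg}$
   negative, the closed band between them neutral; a sentence with no
   scoring opinion word gets the `no_opinion` sentinel rather than a
   numeric verdict.

## Rule dialects: `as_printed` vs the production defaults

Both rule engines exist in two dialects, and the difference is the most
consequential design decision in the package.

The **`as_printed`** dialect is a literal transcription of the rule
scheme's pseudocode, kept primarily so that the implementation can be
checked, line for line, against an independently written transcription on
randomized inputs (the oracle-equivalence tests). Literal semantics have
sharp edges:

* the compound continuation closes on the *next token of any part of
  speech*, so "side" + `quickly` would form a pair;
* the `comp` marker is never cleared, only the stored prefix is;
* adjective licensing has no distance limit — an `amod` adjective can
  license a noun arbitrarily far to its right;
* one token can be emitted twice (a `ROOT` noun that is also
  adjective-licensed);
* in polarity composition, a positive-side opinion word first clamps the
  base score to exactly 1, and the "cross" modifier rule
  $P \leftarrow 1-(1-P)$ is the identity.

The last two points interact badly: with the clamp and the identity rule,
a weak modifier can never move a positive opinion word out of the
positive band, so the canonical weak-modifier sentence ("so far im
feeling *quite positive* … of depressive feelings") could never come out
neutral. The **production defaults** therefore deviate in documented,
minimal ways:

* extraction `strict` mode requires the compound partner to be a noun,
  clears prefix and marker together, restricts adjective licensing to a
  3-token window (dependency parses place attributive adjectives adjacent
  to their noun; the window tolerates intervening modifiers without
  letting a flag leak across clause boundaries), and merges duplicate
  candidates over the same token indices;
* polarity `calibrated` mode takes the raw lexicon magnitude as the base
  score ($pos$, or $1-neg$ on the negative side), implements the cross
  case as attenuation $P^2$, and consumes the modifier flag after each
  scored opinion word so a modifier scopes to the next opinion word only.

Under the calibrated defaults the two canonical sentences behave as
intended: *quite* + *positive* $(0.7, 0, 0.3)$ gives $0.7^2 = 0.49$ —
neutral — and *truly* + *lucky* $(0.7, 0, 0.3)$ gives
$1-(1-0.7)^2 = 0.91$ — positive, with the trailing "not" left
unconsumed because "experienced" is a verb and verbs are outside the
opinion POS set.

Within a sentence the last scored opinion word wins (assignment, not
averaging), matching the single running `polarity` variable of the rule
scheme; a mean-aggregation option exists but is off by default.

## Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| $\Theta$ (`theta_obj`) | objectivity gate: opinion words with $obj \ge \Theta$ carry no sentiment | 0.5 |
| $\theta_{pos}$ | lower edge of the positive region (exclusive) | 0.6 |
| $\theta_{neg}$ | upper edge of the negative region (exclusive) | 0.4 |
| similarity cutoff | minimum max-cosine against the vocabulary, inclusive | 0.7 |
| opinion POS set | tags eligible to carry opinion | ADJ, ADV |
| stopword removal | drop stopwords during normalization | off |

All are dimensionless quantities on $[0,1]$ scales. The band edges are a
symmetric ±0.1 neutral margin around the scale midpoint: wide enough that
a single weak modifier demotes a strong positive (0.7 → 0.49), narrow
enough that unmodified strong scores (≥ 0.7 raw) stay classified. The
objectivity gate at 0.5 says a word must be *predominantly* subjective to
score. The classification bands are read as a partition — positive above
$\theta_{pos}$, negative below $\theta_{neg}$, the closed interval
between them neutral — which is the only non-overlapping reading when
$\theta_{neg} < \theta_{pos}$. Stopword removal defaults to off because
the polarity rules depend on function words ("not", "quite"); when
enabled, words in the modifier lexicons are exempt. Every run
configuration carries a fingerprint (a 32-bit FNV-1a hash of the settings
and lexicon contents) stamped into all outputs, so annotation files are
traceable to the exact thresholds that produced them.

Digit handling in normalization strips a *leading* digit run from each
whitespace token: dose numbers ("300") disappear, measure prefixes lose
their number ("2x" → "x"), and identifiers with interior digits ("b12")
survive. This is the narrowest rule consistent with treating standalone
numbers as noise while not mangling in-word alphanumerics.

## Vocabulary similarity

The relevance filter compares each candidate against *each* vocabulary
entry and takes the maximum cosine — not a pooled centroid — because the
vocabulary is a list of discrete clinical concepts, and relevance to any
one of them suffices. Multi-word terms use the arithmetic mean of their
token vectors, the standard composition for static word vectors. A term
none of whose tokens can be embedded maps to the zero vector, scores 0
against everything, and is dropped with a distinct `oov_zero_vector`
reason code. The cutoff is inclusive (`score >= threshold`). The bundled
vocabularies include the misspelling "side affects" alongside "side
effects": review prose uses both, and a surface-matching filter must
carry the variants it is expected to keep.

The packaged embedding backend is a seeded hash embedder: every token
gets a deterministic unit vector drawn from a hash-seeded RNG (the global
RNG state is saved and restored around each call). Unrelated tokens are
nearly orthogonal in expectation (cosine sd $\approx 1/\sqrt{d}$, default
$d = 64$), and declared synonym pairs are forced to cosine ≥ 0.9 by
interpolation ($v_{syn} = \mathrm{normalize}(0.95\,v_{base} +
0.05\,v_{own})$). It is a *fixture*: it makes similarity arithmetic exact
and testable, but encodes no semantics — two spellings of the same
concept are orthogonal unless declared synonyms or listed in the
vocabulary. A production deployment would drop in a biomedical vector
model behind the same embedder contract.

## Taggers

The gold-tag fixture tagger looks sentences up (on a
punctuation-insensitive lowercase key) in a table of hand-authored tagged
sentences — the worked review sentences ship in
`inst/extdata/gold_tags.tsv` — and falls back to a deterministic
heuristic (closed-class word lists, suffix rules, and a positional
dependency pass) for unknown input. The heuristic is *not* a parser; its
job is stable, repeatable tags so that pipeline behaviour is
reproducible, and its output is flagged `heuristic = TRUE`. The coarse
tag mapping folds `PROPN` to `NOUN`: biomedical taggers frequently mark
clinical terms as proper nouns, and the vocabulary filter — not the
tagset — is the relevance gate. A real dependency parser plugs in as any
function from sentence string to tagged sentence; the wrapper enforces
determinism-friendly invariants (0-based gap-free indices, coarse POS,
populated dependency labels) and converts backend failures into
per-sentence skips rather than dropped reviews.

## The synthetic corpus generator

Tests and the acceptance script never download anything: a generator
emits template reviews in which every planted aspect conforms to the
POS/dependency signature of exactly one extraction pattern, the drawn
sentiment class is realized through opinion words whose lexicon scores
land in the intended band, and out-of-vocabulary distractor nouns are
planted through the same patterns at a configurable rate (default 0.3).
The default class mix is roughly 21% positive, 48% negative and 31%
no-opinion — the negative-skewed distribution typical of
condition-specific drug reviews, where people write most often about
what went wrong. Neutral sentences are realized as a weak modifier over
a strong positive word (the 0.7 → 0.49 construction), so a spec
requesting a neutral share with an empty weak-modifier inventory is
rejected as contradictory. Modifier insertions on positive/negative
sentences are label-preserving by construction (boosts keep the side;
weak attenuation is only drawn for words whose squared score stays in
band; negation realizes a class by flipping an opposite-side word), so
the intended label is always achievable. Everything is a pure function
of the spec's seed.

What the generator does **not** emulate: real syntax (templates only),
tagger noise, spelling variation, implicit aspects ("lose weight" as
surface for the concept *weight loss*), sarcasm, or multi-aspect
sentences with conflicting polarities. Passing the planted-recovery
tests therefore demonstrates that the rule engines, filter and scorer
are faithful to their definitions — not that the scheme attains any
particular accuracy on real reviews, which is precisely why the package
also ships the agreement machinery for human validation.

## Numerical and degenerate-input choices

* Zero-denominator conventions: empty predicted set → precision 0, empty
  gold set → recall 0, $P+R=0$ → $F_1 = 0$; each occurrence warns.
* Cohen's kappa with $p_e = 1$ (both raters constant and identical) is
  defined as 1; likewise Fleiss'. Kappa oracles in the test suite are
  independent contingency-table/per-item recomputations.
* Majority voting requires a *strict* majority; ties return
  `"unresolved"` for human adjudication, never a silent default.
* Token-overlap PRF uses set semantics on lowercase surfaces,
  micro-averaged over items.
* BIO export: a covered token opens a span unless the preceding token is
  covered too; non-adjacent pair members each open their own span, so
  output is always valid BIO (adjacent distinct aspects merge — accepted
  and documented rather than emitting invalid `I` tags).
* Sentence-level polarity is assigned to every kept aspect in the
  sentence; proximity-scoped assignment is out of scope.

## Problem sizes

The oracle-equivalence suites run 1,000 randomized sentences per rule
engine (seeds 7 and 11 in the tests); the composition-invariant sweep
uses 10,000 random $(P, flag, side)$ triples; planted-recovery runs a
200-review corpus (about 540 planted aspects at distractor rate 0.3);
the determinism check uses the bundled 20-review fixture corpus. These
sizes make every property distinguishable from chance while keeping the
full suite fast enough to run on every change.

## Known limitations

Negation is linear-scan and flag-based, not dependency-scoped: "not"
flips the *next* opinion word regardless of syntactic attachment, and a
negator followed by no opinion word silently expires (calibrated mode) or
persists to the sentence end (`as_printed`). Compound surfaces are capped
at two tokens in both dialects, so three-noun chains yield the final
pair. The heuristic tagger's dependency labels are positional guesses.
The similarity filter inherits every blind spot of its embedder. None of
these are accidental: each mirrors the scheme the package implements,
with the deviations confined to the two documented dialect switches.
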