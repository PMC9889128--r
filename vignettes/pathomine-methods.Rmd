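---
title: "Methods: identifying and characterising experimentally studied pathogens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and characterising experimentally studied pathogens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathomine)
```

## The task and its decomposition

Given a MEDLINE/PubMed citation (PMID, title, optional abstract, MeSH index
terms), we want the set of pathogens that the article *experimentally
studies*, not merely mentions. The package decomposes this into **pathogen
identification** — find as many candidate mentions as possible in the title
and abstract — and **pathogen filtering** — remove the (citation, pathogen)
pairs whose mentions are background: comparisons, prior work, surveillance
or patient-history context.

Two simplifying assumptions underpin supervision and evaluation:

* if a pathogen's MeSH descriptor is among a citation's index terms, the
  pathogen is a focus entity of that article and treated as experimentally
  studied;
* evaluation is citation-level — a pathogen counts once per citation
  regardless of its mention count — because the labels derive from
  per-citation indexing.

Both are proxies: MeSH indexers annotate from full text, and focus does not
strictly imply wet-lab experimentation. They are, however, cheap, abundant
and reproducible, which is what a weakly supervised training signal needs.

## Lexicon construction

Organism terms come from an OBO taxonomy: for each pathogen of interest,
the scientific name and synonyms of its root taxon and of every transitive
descendant (subspecies, strains). Synonyms with EXACT or RELATED scope are
harvested; BROAD and NARROW synonyms are excluded to limit false-positive
surfaces. The normalization cascade then applies, in order:

1. the token "subtype" is deleted ("H1N1 subtype" → "H1N1") — prose rarely
   carries it;
2. terms starting (case-folded) with `influenza a virus (` or
   `influenza b virus (` are discarded: these strain-level entries number in
   the thousands and add nothing a shorter form does not already match;
3. for virus terms — defined as terms whose last whitespace token,
   lower-cased, is "virus" — a variant with the trailing "virus" removed is
   *added* while the full form is kept. Dropping the full form would trade
   recall for dictionary size; keeping both costs nothing because
   longest-match resolution prefers the full form when it is present;
4. single-letter virus names ("B virus") are discarded outright — they would
   fire inside unrelated names such as "influenza B virus";
5. any term of three characters or fewer is discarded ("TBE").

The cascade is idempotent, deduplication is case-insensitive with
first-seen casing kept, and abbreviations are not added (they are ambiguous,
and long forms usually co-occur in citations). A surface shared by several
pathogens stays in the dictionary once per pathogen; the ambiguity is
resolved deterministically at match time.

## Mention recognition

**Dictionary matching.** The original tooling in this line of work is a
configurable dictionary tagger whose exact configuration options are not
recoverable; our matching policy is therefore a documented decision, not a
reconstruction. Tokens are maximal runs of letters, digits and hyphens;
a dictionary surface matches where the case-folded text slice equals the
surface and both edges fall on token boundaries. The scan is left to right;
among candidates starting at the same token the longest wins (subspecies
over species); accepted spans never overlap; equal-length ties go to the
lexicographically lowest pathogen id, with all candidates recorded on the
mention. Offsets are 0-based and half-open per field, so
`substr(text, start + 1, end)` always reproduces the surface.

**Toxin regular expressions.** Toxin names combine and embed ("onabotulinumtoxinA",
"antiaflatoxinB1"), so the toxin path is deliberately *not*
boundary-constrained: one case-insensitive pattern per toxin of the shape
`(?i)[a-z]*<stem>[a-z0-9-]*`, with stems `aflatox`,
`botulinum ?(neuro)?tox`, `ciguatox`, `conotox`, `enterotox`, `saxitox`,
`tetrodotox`. Every pattern must embed `(?i)` and compile at bank load, not
at match time.

**Prion co-occurrence.** PrPSc prion variants are designated by host
species and have no species-specific vocabulary entries; a mention is
emitted per species-term occurrence (common name plus plural) whenever a
misfolded-protein term ("PrPSc", "prion") occurs anywhere in the same
citation.

**Cross-method overlaps** within a field keep the longer span; on length
ties a dictionary mention beats a regex mention beats a prion mention,
mirroring longest-match preference and keeping output deterministic. Only
the title and abstract are scanned; MeSH heading strings are metadata, not
text.

## Weak labels and masking

One training example per (citation, pathogen) pair with at least one
mention. The pair is labeled relevant iff the citation's MeSH descriptors
intersect the pathogen's descriptor set. Only that pathogen's mentions are
masked to `@PATHOGEN$` (right-to-left per field, title and abstract joined
by one newline); other pathogens' surfaces remain visible text. Per-pair
masking is the only granularity consistent with filtering pathogens
individually within a citation, which is why we chose it where the
alternative (masking all pathogens jointly) was also defensible. Pathogens
with no MeSH mapping generate no training examples — their weak label is
undecidable and emitting them would manufacture systematically wrong
negatives — but they are still recognized and filtered at inference.

## The relevance classifier

A linear model over binary n-gram presence indicators (lower-cased tokens,
packaged English stop-word list, unigrams or unigrams + bigrams; the mask
token survives tokenization intact). Training minimizes mean modified Huber
loss plus an L2 penalty by SGD. The loss, for margin $m = y(w\cdot x + b)$
with $y \in \{\pm 1\}$:

$$L(m) = \begin{cases}\max(0, 1-m)^2 & m \ge -1\\ -4m & m < -1\end{cases}$$

It is continuous (both branches give 4 at $m=-1$), continuously
differentiable and convex; the linear tail bounds the influence of badly
misclassified points, which matters under the label imbalance weak
supervision produces.

Defaults, all serialized with the model: 10 epochs, shuffling each epoch
under seed 42; $\lambda = 10^{-4}$; learning rate
$\eta_t = 1/(\lambda(t + t_0))$ with $t_0 = 1/(\lambda\,\eta_0)$ and
$\eta_0 = 0.1$, i.e. the first step uses 0.1 and the rate decays
hyperbolically; the L2 shrink is applied through the usual weight-scale
trick so a step costs only the active features, with renormalization when
the scale underflows. Feature values are binary, not counts or TF-IDF.
Training restores the session RNG state on exit, and retraining with the
same configuration is weight-identical.

Confidence maps the raw score through the standard clipped link for
modified-Huber scores, $(1 + \mathrm{clip}(s, -1, 1))/2$, so score 0 gives
confidence 0.5. The default filtering threshold is 0.5; no principled value
exists without a tuning corpus, and the threshold is an explicit model
field precisely so users can move it. Raising it never increases the number
of retained mentions.

On the standard synthetic fixture, unigram features plateau around F1 0.84
while bigrams reach ≈ 1: with per-pair masking, a citation carrying two
pathogens contains both pairs' cue words, and only adjacency to
`@PATHOGEN$` (a bigram property) identifies which cue belongs to the masked
pathogen. The bigram configuration is therefore the recommended default
for filtering.

## Evaluation conventions

From per-pathogen counts (TP, gold positives, predicted positives):
precision = TP/(FP+TP), recall = TP/Positives, F1 = 2PR/(P+R). Any metric
with a zero denominator is 0, and F1 is 0 when P+R = 0. Values are kept at
full precision internally; reporting rounds half-away-from-zero at 4
decimals, which reproduces every internally consistent printed value in the
published per-pathogen benchmark rows the test suite freezes. Two printed
precision cells in those rows (toxin regex/aflatoxins and toxin
dictionary/saxitoxins) disagree with their own printed count triples — in
both cases the printed recall and F1 *are* consistent with the counts, and
the F1 is consistent with the counts-derived precision, so the cells are
documented as typographical and excluded from exact checks. Micro averaging
sums counts before computing; macro averaging means per-pathogen metrics.
Micro F1 is not claimed to lie between the per-pathogen extremes — that is
false in general — and is only ever checked against the summation oracle.

## Dataset building

The acquisition methodology is expressed against a small record-service
contract: taxonomy name search (scientific names only, or all name fields),
child listing, literature search over `[MH]`-tagged query clauses, and
gene-record links. Name resolution searches scientific names first, widens
to all name fields on zero hits, and accepts only single-record answers —
ambiguous names are skipped, not guessed. Subspecies expansion is the BFS
closure of child links. The PrPSc template query substitutes the species
MeSH heading: `"PrPSc Proteins"[MH] AND sheep[MH]`; seven common host
species have headings, and species without one (elk, greater kudu, moose,
mule, nyala, onyx, ostrich) are flagged not found. Toxins use their MeSH
mapping or are flagged. MeSH-derived and gene-link PMID sets are kept
separate in the report, and only MeSH-derived PMIDs feed weak labeling —
gene-link and full-text-derived identifiers denote presence, not focus.

The package ships the deterministic mock backend (a directory of five TSV
tables) as its only backend: builds against it are bit-reproducible, which
is what the tests verify. The contract keeps a live E-utilities backend
pluggable; anyone adding one should cache responses to disk and rate-limit,
and should note that newer MEDLINE mixes manual and automatic MeSH
indexing, which weakens the labeling assumption for recent citations.

## The synthetic generator: what it does and does not show

The generator emulates the *shapes* that matter to each stage: an OBO
taxonomy with species roots, strain children and synonyms; citations with a
title, an abstract missing at a configured rate (default 0.2, matching the
roughly one-fifth of MEDLINE citations that carry no abstract); one to two
pathogens per citation; planted surfaces that are dictionary entries
verbatim at exactly recorded offsets; MeSH lists that carry a pathogen's
descriptor iff the pair is relevant (the weak-labeling rule holds by
construction); and disjoint experimental vs background cue vocabularies
(default relevant fraction 0.5) that make relevance learnable from masked
text. Overlapping cue vocabularies are rejected at configuration time since
they would make the planted signal ambiguous.

It does **not** model natural abstracts: no term variation on planted
mentions by default (an optional exercise of the stripped-"virus" variant
is the generator's term-variation hook), no coordination ("Influenza A and
B viruses"), no abbreviations, no MeSH qualifier structure, and
template-slot English rather than scientific prose. Passing tests on these
fixtures therefore demonstrate the *mechanics* — offsets, longest-match
resolution, label plumbing, training determinism, the direction of the
precision gain from filtering — not performance on real MEDLINE text,
where term variability and genuine ambiguity dominate the error budget.

Test and acceptance problem sizes are the package's own choice: oracle
equivalence runs on 100–150 small seeded corpora (4–6 species, 6–15
citations each), and the classifier checks use a 1,430-citation fixture
yielding 2,002 (citation, pathogen) pairs with a deterministic 70/30
split — large enough for stable behaviour, small enough to keep the whole
suite under a minute.

## Known limitations

* The matching policy (tokenization, case folding, tie-breaks) is a
  documented design choice; other configurations are defensible and would
  change borderline matches.
* Toxin patterns are reconstructed from the stem behaviour their examples
  imply, with MeSH synonym alternates; they are not an authoritative
  pattern inventory.
* The weak labels inherit every bias of MeSH indexing, including full-text
  knowledge the citation text does not contain: a fraction of positives are
  unrecoverable from title + abstract alone, bounding attainable recall.
* The filter is linear over sparse n-grams by design (fast, auditable,
  deterministic); the classifier interface is pluggable for heavier models,
  which are out of scope here.
* No significance testing between configurations is provided.
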