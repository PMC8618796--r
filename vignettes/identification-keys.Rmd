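---
title: "Character-state algebra and dichotomous keys for yeast phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Character-state algebra and dichotomous keys for yeast phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichokey)
```

## The problem

Describing a new yeast species still rests on a panel of growth and
assimilation tests: can the strain grow on each of a few dozen sole carbon
and nitrogen sources, at elevated temperature, without vitamins; does it
form ascospores or true hyphae. The results are summarized twice -- once as
a taxon-by-character state matrix covering the whole genus, and once as a
printed dichotomous key that walks an identifier from couplet 1 to a species
name. Both artifacts are hand-maintained and drift apart easily: a key lead
can contradict the matrix, a couplet back-reference can be misprinted, and
uncertain states (strain-variable reactions, missing data) make "does this
specimen match this species" a subtler question than string equality.

`dichokey` makes these artifacts computable. The packaged fixture set is the
phenotypic taxonomy of the ascomycetous genus *Wickerhamomyces*: a 38
species x 22 character matrix, a 37-couplet species key, and a 36-species
global distribution table, all stored as plain text.

## The state algebra

A matrix cell holds one token: `+` (strong growth), `-` (negative), `w`
(weak), `l` (latent, i.e. delayed positive), `s` (slow positive), `v`
(strain-variable), `n` (no data), or an alternation of atoms joined by `/`
or `,` (e.g. `+/w`: some strains strong, some weak). Print sources use
several Unicode dashes for the negative sign; the parser normalizes all of
them. Canonical serialization orders alternation atoms positive < weak <
latent < slow < variable < negative, so `w/+` round-trips as `+/w`.

Key leads only ever ask a binary question, so every state is reduced to the
set of binary outcomes it *supports*:

* **default polarity**: `+`, `w`, `l`, `s` support the positive outcome
  only; `-` supports the negative only; `v` and `n` support both; an
  alternation supports an outcome if any atom does. Weak and delayed growth
  count as assimilation because that is how species descriptions themselves
  read ("inulin (weak) ... assimilated").
* **strict polarity**: identical except that `w` also supports the negative
  outcome, for flagging borderline reactions. Under strict polarity the
  fixture's one judgment call surfaces: *W. lannaensis* has vitamin-free
  growth coded `w`, which the default rule reads as growth and the strict
  rule leaves undecided. We document rather than resolve this.

Every state supports at least one outcome, which is why key traversal can
never hit a dead end at a couplet whose character has been observed.

Two species are *distinguished* by a character when their states share no
supported outcome. Note the asymmetry this induces: `+` vs `-`
distinguishes, but `+` vs `w` does not (both support positive), and nothing
distinguishes against `v` or `n`. Distinguishability is what the key
builder, the synthetic generator's guarantee, and the ambiguity reports are
all defined against.

## The key model

A key is a rooted binary tree of numbered couplets; each couplet's two leads
(`a`, `b`) assert opposite outcomes of one character, with lead `a` always
carrying the positive outcome (the printed key's convention, which the
validator relies on as transcription QC). Hard invariants -- two opposite
leads, single parent per couplet, acyclicity, reachability -- are enforced
at construction. The printed "(k)" back-reference after a couplet number is
deliberately *not* trusted: it is stored as metadata and checked by
`validate_structure()`. On the packaged key this surfaces exactly one
discrepancy: couplet 26 prints "(24)" but is actually entered from couplet
25, a typo the lead structure overrules.

Traversal distinguishes two kinds of uncertainty because they demand
different user remedies:

* a character **missing from the specimen profile** stalls the walk
  (`status = "stalled"`, with the couplet) -- the user should run that test;
* an observed but **uncertain state** (variable, or an alternation spanning
  both outcomes) forks the walk -- `identify_specimen()` reports
  `status = "ambiguous"` with the frontier of species reachable from the
  fork, computed by `reachable_leaves()`, which follows every supported lead
  exhaustively and treats absent characters as no-data.

`reachable_leaves()` is the semantic core, so it is tested against an
independent oracle: enumerate every resolution of a row into definite
outcomes, walk each resolution deterministically, and take the union. The
suite checks agreement exhaustively on generated matrices up to 6 x 6 and on
the most uncertain rows of the genus matrix.

## Consistency of a key against a matrix

`check_consistency()` asks, per species: does *some* resolution of its
matrix row walk to its own leaf? Existential, not universal, because
variable states describe strain-level variation and printed keys separate
such taxa by other characters downstream. Failures cite the first couplet on
the root-to-leaf path where the row contradicts the required lead. Species
names are matched after normalizing whitespace and genus abbreviation
("W." vs the spelled-out genus); there is no fuzzy matching. Whether all 36
previously described species pass against the genus matrix was an open
empirical question; the report answers it positively (38/38 consistent, with
*W. chaumierensis*'s no-data-heavy row also reaching a second leaf).

## Building keys

`build_key()` constructs a key greedily. At each node, for each candidate
character, taxa supporting only the positive outcome go to side a, only the
negative to side b, and taxa supporting both are duplicated onto *both*
sides -- mirroring how printed keys implicitly handle variable taxa. A
character is admissible only if both sides are strictly smaller than the
current set (so recursion always progresses). The default score is the
expected log-reduction in taxon count,

$$\log n \;-\; \big(\tfrac{n_a}{n_a+n_b}\log n_a + \tfrac{n_b}{n_a+n_b}\log n_b\big)
\;-\; 0.5\,d,$$

where $d$ is the number of duplicated taxa; the penalty weight (0.5 per
duplicate, configurable separately for variable-type and no-data states)
discourages but does not forbid uncertain characters. A worst-case-balance
scoring mode ($-\max(n_a,n_b)/n$) is available. Ties break by vocabulary
column order and couplets are numbered in preorder, so the same matrix and
configuration always yield the identical key. Unsplittable taxon sets become
multi-species leaves by default, or raise an error when disallowed. Optimal
(minimum expected depth) construction is NP-hard and out of scope; greedy is
what the field's key-generation tools use. Reproducing the printed key's
exact topology is likewise not a goal -- `compare_keys()` exists to quantify
the difference (couplet counts, depths, character overlap, per-species
depths) rather than erase it.

## Occurrence summaries

The distribution table maps each species to verbatim place names; a
place-to-continent mapping (UN-style geoscheme, user-editable TSV) resolves
them. A species counts once per continent in which it has any locality.
Against the packaged table the mapping reproduces South America = 8,
Africa = 7, Oceania = 1, Antarctica = 1 -- the four per-continent figures
that follow arithmetically from the table. The published Asia (18),
Europe (12), and North America (3) figures are *not* derivable from the
table under any single mapping (USA-recorded species alone exceed 3), so the
tool reports what the table supports and pins nothing it cannot recompute;
the mapping was fixed from the geoscheme before any counting and is not
tuned toward published numbers. Bookkeeping helpers cover the remaining
countable claims: 8 species known from Thailand before the two additions,
10 after, 38 species globally. The per-decade histogram operates on
user-supplied years only (the table carries none).

## Synthetic data

Generators exist so every pipeline stage is testable without downloads, and
every generator is a pure function of its seed. `gen_matrix()` draws cells
i.i.d. from a state-category mix whose default is the *empirical* token mix
of the packaged matrix (computed at call time, not hard-coded), so synthetic
matrices share real data's balance of definite, weak, variable, and missing
states. Pairwise distinguishability, when requested, is enforced by
resampling offending rows with a 100-round cap, after a necessary-condition
check (at least $\lceil \log_2 n \rceil$ characters). `gen_specimen()`
resolves a row the way an isolate realizes its species' description:
variable states become `+` or `-` uniformly, alternations pick one atom,
no-data stays unobserved. `gen_occurrences()` draws localities from a pool
with a configurable multi-country rate and uniform years.

What the generators do not emulate: phylogenetic correlation among
characters, non-independence of tests on shared pathways, and observer
error. Passing round-trip tests therefore demonstrates the algebra and the
algorithms, not robustness to correlated real-world noise.

The suite's standing problem sizes -- 5-6 species x 6-7 characters for the
oracle and round-trip properties, 100 seeded replicates for the
build-specimen-identify loop -- were chosen as the smallest sizes at which
every code path (forks, duplicates, multi-leaves) is routinely exercised.

## Known limitations

* Characters are binary-outcome only; quantitative characters (cell sizes,
  growth rates) are not modeled, and there is no DELTA/NEXUS import.
* Identification is single-access; no multi-access (polyclave) filtering.
* Consistency checking reports but does not repair inconsistent keys.
* Name matching is exact up to genus abbreviation; no synonym handling.
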