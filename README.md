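# dichokey

Dichotomous identification keys from phenotypic character matrices, with the
yeast genus *Wickerhamomyces* as the packaged worked example.

Yeast taxonomy identifies species from panels of growth and assimilation
tests, summarized in two hand-maintained artifacts: a taxon-by-character
**state matrix** for the genus and a printed **dichotomous key** that walks
from couplet 1 to a species name. `dichokey` makes both computable and keeps
them honest against each other:

* a **character-state algebra** for test outcomes — `+` positive, `-`
  negative, `w` weak, `l` latent, `s` slow, `v` strain-variable, `n` no
  data, and alternations like `+/w` — reduced to the binary outcomes a state
  *supports* (under the default polarity rule weak/latent/slow count as
  positive; `v` and `n` support both);
* **key traversal** that distinguishes a missing observation (the walk
  *stalls*; go run the test) from a genuinely uncertain one (the walk
  *forks*; the frontier of reachable species is reported);
* **consistency checking** of a key against a matrix: does some resolution
  of each species' row reach its own leaf, and if not, which couplet blocks
  it;
* **greedy key construction** from a matrix by expected log-reduction in
  taxon count (information gain), with taxa whose states support both
  outcomes duplicated onto both sides at a configurable penalty;
* **occurrence-table summaries** (species per continent/country, totals with
  proposed additions, per-decade discovery histograms);
* seeded **synthetic generators** for matrices, specimens, and occurrence
  tables, so every stage is testable end to end.

The packaged fixtures transcribe the genus-wide phenotypic data for
*Wickerhamomyces*: the 38 species × 22 character matrix, the 37-couplet
species key, the 36-species global distribution table, and resolved specimen
profiles for the two most recently described species (*W. lannaensis*,
*W. nanensis*), all as plain text under `inst/extdata/`.

## Worked example

```r
library(dichokey)

key <- wickerhamomyces_key()
identify_specimen(key, wickerhamomyces_profile("nanensis"))
#> identification: identified
#>   species: W. nanensis
#>   path: 1b -> 7b -> 19b -> 21b -> 23a -> 24b -> 25b -> 26a
```

The specimen fails melibiose, raffinose, 2-ketogluconate, and D-arabinose
(couplets 1, 7, 19, 21, all lead b), assimilates galactose (23a), fails
L-arabinose and sucrose (24b, 25b), and assimilates D-mannitol — couplet
26a, *W. nanensis*.

```r
m <- wickerhamomyces_matrix()
check_consistency(key, m)
#> consistency_report: 38/38 species reach their own leaf

validate_structure(key)$annotation_discrepancies
#>   couplet printed actual
#> 1      26      24     25
```

Every species' matrix row can walk the printed key to its own leaf, and the
one structural blemish is a misprinted back-reference: couplet 26 says
"(24)" but is entered from couplet 25.

```r
continent_counts(wickerhamomyces_occurrences(),
                 wickerhamomyces_continent_mapping())
#>        Africa    Antarctica          Asia        Europe North America
#>             7             1            19             8             8
#>       Oceania South America
#>             1             8

distinguishing_characters(m, "W. lannaensis", "W. nanensis")
#> [1] "Ga"   "DXy"  "Rh"   "DGlu" "Cit"
```

Five characters cleanly separate the two new species; nitrate does not,
because `+` versus `w` share the positive outcome. A freshly built key can
be compared against the printed one:

```r
built <- build_key(m)
compare_keys(built$key, key)
#> key_comparison: 38 vs 37 couplets; character Jaccard 0.90
#>   depth (max/mean): 9/6.23 vs 13/6.97
```

A command-line wrapper ships at `inst/scripts/dichokey`
(`identify`, `validate-key`, `build-key`, `compare-keys`, `summarize`,
`synth`, `fixtures`); see `?run_command`.

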