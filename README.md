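# sideroscreen

Rule-based discovery and chemical-space clustering of siderophore
candidates.

Siderophores — the iron-chelating secondary metabolites that microbes
secrete to scavenge ferric iron — are structurally diverse, but almost all
of them hold the metal with a short list of oxygen-donor functional
groups: hydroxamates, catechols, phenolates, citrate carboxylates, and a
handful of rarer moieties.  `sideroscreen` turns that regularity into an
auditable screen for molecule libraries:

> a molecule is a **candidate iron binder** iff it contains at least one
> of **15 searchable iron-coordinating groups**, none of **8 modified-veto
> groups** (O-alkylated/O-acylated chelating oxygens, which cannot form
> coordination bonds), and is not an already-known structure
> (exact canonical-SMILES identity).

Alpha-hydroxycarboxylate and plain carboxylate are counted but never
trigger candidacy — they are ubiquitous in non-siderophore metabolism.

Around the rule the package provides the full workflow used for curating
and mining siderophore collections:

* **Identity** — OpenBabel canonical SMILES with salt stripping and charge
  neutralization; deduplication merges records per unique structure and
  collects alternative names.
* **Matching** — a substructure matcher with matched-atom sets over a
  curated, versioned pattern registry (each entry: SMARTS + pattern graph
  + exemplar); non-redundant counting; per-molecule C/N/O statistics.
* **Novelty** — Tanimoto similarity on circular fingerprints (ECFP4);
  candidates with maximum similarity ≤ 0.60 to the known set count as
  novel chemistry.
* **Chemical space** — kNN graph + minimum spanning tree of known
  structures inside a background natural-product library; clusters are the
  components left after background deletion, size-ranked; groups form at a
  0.60 structure-similarity coefficient; every record gets an append-stable
  `x.y.z` (cluster.group.record) identifier; group biosynthetic types
  (NRPS / NIS / …) are inferred by majority vote.
* **Fixtures** — a download-free test bed: 16 literature-standard
  siderophores with expected group counts, 20 decoys, 4 veto constructs,
  and a seeded library generator.

## Worked example

```r
library(sideroscreen)

pats <- load_default_patterns()
pats
#> <pattern_registry> version 1.0 - 25 patterns
#> common_excluded   modified_veto      searchable
#>               2               8              15

# 2,3-dihydroxybenzoic acid: an enterobactin-type catechol arm
match_groups("OC(=O)c1cccc(O)c1O", pats)
#> <match_profile> OC(=O)c1cccc(O)c1O
#>   catecholate                          1
#>   phenolate                            1
#>   carboxylate                          1

# a seeded 17-molecule library: 5 planted siderophores, 10 decoys,
# 2 O-methylated veto constructs
lib <- make_library(fixture_spec(5, 10, 2, seed = 7))
res <- screen_library(lib, patterns = pats)
res
#> <screen_result> 17 records: 5 candidates, 4 vetoed, 0 known-excluded,
#>                 11 without any searchable group
res$decisions[res$decisions$is_candidate, c("record_id", "triggering")]
#>        record_id                                              triggering
#>    bacillibactin                                   catecholate|phenolate
#>       aerobactin hydroxamate|carboxylate-in-citrate|alpha-hydroxyca....
#>     vibriobactin            catecholate|phenolate|hydroxyphenyloxazoline
#>        pyochelin                                 hydroxyphenylthiazoline
#>      rhizoferrin  carboxylate-in-citrate|alpha-hydroxycarboxylate-in-...
```

The five candidates are exactly the five planted siderophores; the decoys
(sugars, terpenes, alkaloids) carry no searchable group, and the two veto
constructs are rejected because their chelating oxygens are methylated.
Note `n_vetoed = 4`: vanillin and ferulic acid among the decoys also carry
a blocked (O-methylated) catechol — vetoed *and* trigger-free.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/sideroscreen.R screen --library lib.csv --known known.csv \
    --out decisions.csv --summary summary.json
Rscript inst/cli/sideroscreen.R cluster --known known.csv \
    --background coconut.csv --out ids.csv
```

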