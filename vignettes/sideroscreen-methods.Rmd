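---
title: "Methods: rule-based siderophore discovery and chemical-space clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based siderophore discovery and chemical-space clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sideroscreen)
```

## The problem

Siderophores are microbial secondary metabolites that bind ferric iron with
very high affinity.  Chemically they are wildly diverse, but the iron is
almost always held by a short list of bidentate oxygen-donor moieties:
hydroxamates, catechols, phenolates, citrate-derived carboxylates, and a
tail of rarer groups (hydroxyphenyl-oxazolines and -thiazolines,
diazeniumdiolates, nitrosophenols, hydroxyquinolines, ...).  That
regularity supports a simple, auditable discovery rule: a molecule that
carries at least one intact iron-coordinating group is a candidate iron
chelator, unless the group's chelating oxygens are chemically blocked.

`sideroscreen` implements that rule end to end: canonical-SMILES identity
and record merging, a curated substructure-pattern registry with veto
patterns, the candidate screen, Tanimoto-fingerprint novelty assessment
against a known set, and minimum-spanning-tree (MST) clustering of known
structures inside a background natural-product library, with x.y.z
chemical-space identifiers.

## Structure identity

Two records denote the same structure when their OpenBabel canonical
SMILES agree, after two normalisations:

* **salt stripping** -- multi-fragment inputs are reduced to the largest
  covalent fragment (counter-ions and solvates are bookkeeping, not
  chemistry); every stripped fragment is reported;
* **charge neutralization** -- simple protonation states are neutralized so
  carboxylate and carboxylic-acid spellings collapse.

Stereochemistry is *retained*: stereoisomeric siderophores are distinct
records.  `canonicalize(..., keep_stereo = FALSE)` collapses stereoisomers
for sensitivity analysis of deduplication counts; unique-structure counts
can shift by a few records between canonicalization dialects and stereo
conventions, which is why reproduction work should always state the
convention used (this package's convention: OpenBabel canonical SMILES,
stereo retained, salts stripped, charges neutralized).

## The pattern registry

The registry (`load_default_patterns()`) holds three categories:

* **15 searchable groups** -- any one of them triggers candidacy;
* **2 common-excluded groups** -- alpha-hydroxycarboxylate and plain
  carboxylate.  Both are genuinely iron-coordinating but so ubiquitous in
  primary metabolism (citric, malic, lactic acids; every free amino acid
  backbone) that using them as triggers would flood any natural-product
  screen.  They are still counted, because per-cluster prevalence of
  alpha-hydroxycarboxylate is a useful descriptive statistic;
* **8 modified-veto groups** -- O-alkylated or O-acylated variants of the
  chelating oxygens.  A blocked oxygen cannot form a coordination bond, so
  the presence of such a group vetoes the molecule (see below).

Two design points deserve comment:

* **Citrate context.**  Free citric acid is *not* a siderophore candidate.
  The citrate-context patterns therefore require an amide-linked arm on
  the citrate core, the signature of citrate-based siderophores such as
  aerobactin, staphyloferrin A, and rhizoferrin, where the cell has
  invested biosynthetic effort in decorating citrate.  This is the reading
  that keeps citric acid out while keeping every citrate siderophore in.
* **Overlap is allowed.**  A 2,3-dihydroxybenzoyl arm matches both
  catecholate and phenolate; the aerobactin core matches both
  citrate-context groups.  The screening rule is existence-based, not
  partition-based, so overlapping counts are reported as they are.

Each registry entry stores a SMARTS string *and* an equivalent hand-built
pattern graph.  The package's own matcher consumes the graphs and returns
matched atom sets (needed for non-redundant counting and for per-site veto
logic); the SMARTS strings feed the OpenBabel engine, which serves as an
independent cross-check in the test suite -- every fixture molecule must
receive identical counts from both engines.  Matches that cover the same
atom set through a pattern symmetry are counted once.  Aromaticity follows
OpenBabel's model (the matcher reads aromatic flags from the canonical
SMILES itself), so both engines share one aromaticity perception; the
cyclic-hydroxamate pattern deliberately leaves ring-bond aromaticity
unconstrained because N-hydroxy-pyridinone tautomers are perceived
differently across toolkits.

The registry is versioned, dumpable as TSV
(`system.file("extdata/patterns.tsv", package = "sideroscreen")`), and
extensible: an override TSV appends user patterns (matched via the SMARTS
engine, counts only).

## The screening rule

```
candidate  <=>  (>=1 searchable group)  AND  (no veto group)  AND  (not a known structure)
```

* **Veto semantics.**  The default is a *global* veto: one blocked group
  anywhere rejects the molecule.  This is the conservative reading of the
  discovery pipeline -- a molecule that the producing organism (or a
  chemist) has O-methylated somewhere is suspect as an iron chelator.
  A *per-site* mode (`veto_mode = "per_site"`) is available behind a flag:
  there a molecule survives if at least one searchable match shares no
  atom with any veto match (desferrioxamine B with one of three
  hydroxamates methylated survives per-site, is rejected globally).  The
  default stays global.
* **Known-structure exclusion** is by exact canonical-SMILES identity,
  never similarity: identity is the only reproducible reading of
  "excluding known structures", and similarity-based exclusion would
  silently absorb genuinely novel near-analogues.

## Novelty

A candidate is compared against every known structure with Tanimoto
similarity on circular substructure fingerprints (OpenBabel ECFP4,
radius 2, 4096 bits -- the engine's native length; the path-based FP2
scheme is available as an alternative).  Candidates whose maximum
similarity exceeds 0.60 are "known-like"; the rest are novel chemistry.
The 0.60 threshold is the conventional cut for "clearly related
structures" on circular fingerprints.

One behaviour worth knowing: circular fingerprints include ring-membership
in their atom environments, so a macrocyclic structure (desferrioxamine E)
and its open-chain counterpart (desferrioxamine B) share almost no bits
despite near-identical repeating units.  Fingerprint novelty is a
*fingerprint* statement, not a biosynthetic one.

## Chemical-space clustering and x.y.z identifiers

Known structures are embedded jointly with a background natural-product
library: each molecule links to its `k = 20` nearest neighbours under the
distance `1 - Tanimoto` (a proper metric on bit vectors, checked by the
test suite on random triples), disconnected components are bridged with
the smallest inter-component edges (count reported), and the MST of the
result is taken.  Deleting the background molecules from the tree cuts it
into the clusters of known structures; clusters are indexed by decreasing
size.  Within a cluster, groups are connected components of the
similarity graph at a structure-similarity coefficient of 0.60 (kept
deliberately equal to the novelty threshold; both are configurable).
Records are then named `x.y.z` = cluster.group.record.

Determinism: nodes are internally ordered by record id before graph
construction, so kNN tie-breaking, MST construction, and all indexes
depend only on the molecule *set*, never on input order; equal-size
clusters and groups are ordered by their smallest record id.  Published
IDs are append-stable: `assign_ids(partition, previous = ...)` keeps
existing IDs and gives newcomers the next free `z` in their group.
Biosynthetic types of unannotated members are inferred by majority vote of
the annotated members of their group (ties break alphabetically, and the
group is flagged *mixed* whenever two distinct annotated types occur).

## The fixture bed

Because the reference corpora (curated siderophore deposits, COCONUT-scale
background libraries) cannot be bundled, the package ships a download-free
test bed:

* `reference_set()` -- 16 literature-standard siderophores spanning the
  major chemistries (enterobactin, bacillibactin, vibriobactin;
  desferrioxamines B/E, ferrichrome; aerobactin, schizokinen,
  staphyloferrin A, rhizoferrin, petrobactin; yersiniabactin, pyochelin;
  cepabactin, quinolobactin, graminine), each annotated with its expected
  group counts from independent inspection of the published structure;
* `decoy_set()` -- 20 natural-product-like negatives (sugars, terpenes,
  alkaloids, phenolics).  Vanillin and ferulic acid deliberately carry an
  O-methylated catechol so that realistic vetoed negatives occur;
* `veto_constructs()` -- reference structures with their chelating oxygens
  O-methylated; each must be vetoed while staying Tanimoto-similar
  (> 0.60) to its parent;
* `make_library()` -- seeded, byte-reproducible mixtures for end-to-end
  runs.

What passing on this bed does **not** show: the bed is small (40
structures), its decoys are clean drug-like molecules rather than the
noisy tautomer-rich contents of a real library dump, and its background is
far too sparse for the cluster topology to resemble a 4x10^5-molecule
embedding.  Deposit-scale checks (649 unique structures from 872 records;
25 clusters with the largest four holding 89.37% of structures; 102
groups with exactly two of mixed biosynthesis; per-cluster hydroxamate
prevalences) are implemented in the acceptance suite and run whenever the
published tables are placed under `deposit_dir()`.

## Numerical and scale choices

* MST correctness is tested against exhaustive enumeration of all
  labelled spanning trees (Pruefer sequences) on 100 seeded random graphs
  of 4-7 nodes, plus an independent Kruskal implementation at 8 nodes --
  sizes chosen so the exhaustive oracle itself stays exact and cheap.
* Similarity matrices are computed densely; that is fine up to a few
  thousand molecules.  A full COCONUT-scale join is hours of compute and
  is deliberately out of the default test path.
* Implicit hydrogens are recomputed from standard valences, kekulized
  bond orders, and formal charges; formal charges are read from the SDF
  charge fields so that charge-separated spellings (nitro groups) do not
  masquerade as hydroxyls.
* Degenerate inputs: empty libraries pass through every stage as empty
  artifacts; single-molecule graphs are rejected with a clear error
  (a similarity graph needs two molecules); unparsable SMILES name the
  offending record.

## Known limitations

* The pattern registry is a transcription of the published group
  repertoire; SMARTS granularity choices (how much context a "phenolate"
  needs, how strict the citrate core is) are documented per entry and
  auditable in `inst/extdata/patterns.tsv`, but other reasonable
  transcriptions exist and will shift borderline counts.
* Exact unique-structure counts depend on the canonicalization dialect;
  cross-toolkit reproductions should expect +/- a few records.
* The package predicts *candidate iron binders*, not siderophores proper:
  transport, regulation, and biosynthesis are out of scope, and wet-lab
  validation (e.g. chrome azurol S assays) remains the arbiter.
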