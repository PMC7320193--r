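---
title: "Quantifying locus heterogeneity through protein complexes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying locus heterogeneity through protein complexes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhcomplex)
```

## The scientific question

Locus heterogeneity (LH) is the observation that mutations in *different*
genes can cause clinically similar — sometimes indistinguishable —
diseases. A mechanistic explanation available for many such cases is that
the proteins encoded by the LH genes are members of the same protein
complex (PC): disrupting any subunit interferes with the same molecular
machine, so the downstream phenotype converges. `lhcomplex` implements a
complete, testable pipeline for measuring that convergence: it assembles
families of disease-protein sets from an OMIM-style morbid map (grouped
either by shared disease identifier or by shared phenotypic series, PS),
assembles a catalog of protein complexes from a Gene Ontology
cellular-component ontology, and quantifies every set-versus-complex
overlap with the Jaccard coefficient

$$ JC(S, C) \;=\; \frac{|S \cap C|}{|S \cup C|} \;=\; \frac{|S \cap C|}{|S| + |C| - |S \cap C|} \in [0, 1], $$

where $S$ is the protein set of a disease or series and $C$ the member set
of a complex. An *instance* of association requires at least two shared
proteins — one shared protein says nothing about convergent disruption.

## Defining diseases: the filtering rules

`filter_disease_gene_pairs()` reduces the raw morbid map to validated
disease-protein pairs. The discard rules run in a fixed order, and a row
is counted under the first rule it violates, which makes the filter report
reproducible (a susceptibility row with a non-molecular mapping key is
counted once, as a susceptibility):

1. phenotype labels marked unconfirmed (`?`), non-disease (`[ ]`) or
   susceptibility (`{ }`);
2. mapping keys 1, 2 and 4 — only key 3 (molecular basis known) survives.
   "Known molecular basis" is operationalized as key 3 exactly, since the
   other three keys are the stated discards;
3. phenotypes without their own MIM identifier;
4. genes that are moved, removed, or not mapped to an Entrez identifier;
5. genes that do not code for a protein.

Protein identity throughout the package is the Entrez-style gene
identifier; symbols are display-only. When a morbid row carries several
symbols, all are parsed but the row is keyed by its single gene MIM, and a
disease belonging to several series contributes its proteins to each of
them (series membership is many-to-many).

## Defining complexes: selection and pruning

A complex is any non-obsolete cellular-component term whose name contains
the substring "complex" (case-insensitive; GO names are lower-case, but
robustness costs nothing). Member proteins are the *directly* annotated
gene products. We deliberately do **not** propagate annotations up the
`is_a`/`part_of` hierarchy: propagation would make every parent the union
of its children, and the parent-removal logic below would then always
remove the information-richest terms. The cost of this choice is that a
parent term's member set reflects only its own annotations; naturally
nested complexes (a receptor complex inside a channel complex) still
emerge when curators annotate both levels.

Pruning runs in a fixed order:

1. *parents of parents* — terms with a selected child that itself has a
   selected child (depth-2 within the selected set, not a transitive
   closure: this matches the three-way non-parent / parent /
   parent-of-parent classification) — are removed, **unless** one of
   their children carries no proteins, in which case removing the parent
   would lose its annotations with nothing below to inherit them;
2. three generic umbrella terms (protein complex, transcription factor
   complex, macromolecular complex) are removed by identifier;
3. complexes left with fewer than two proteins are removed.

Each removed term is logged once under the first rule that removed it, so
`kept + removed = selected` always holds, and re-running the pruning on
its own output changes nothing.

## Intersections and their summary

`find_intersections()` materializes the (group, protein, complex)
3-tuples and self-joins them, emitting one record per (group, complex)
pair with at least two shared proteins; an exhaustive double loop over all
pairs is the test oracle for this operation. When one group intersects
several complexes, summaries use the per-group maximum coefficient
(`jc_max`), with ties broken toward the smallest complex identifier so
reports are deterministic (tied records all remain in the record table).
Histogram bins are width 0.1 over $(0, 1]$, right-closed, with $JC = 1$
in the top bin; coefficients are stored at full precision and rounded to
3 decimals only in reports.

Because the union term grows with complex size, large complexes have
systematically smaller coefficients at the same intersection size — a
12-protein series sharing 5 proteins scores 0.238 against a 14-member
complex but 0.053 against an 88-member one. This is a property of the
statistic, not a bug, and one reason the per-group maximum is reported.

## Randomization controls

Four permutation controls calibrate the observed counts
(`run_null_control()`, `pairwise_control()`):

- **pseudo-PS** — redistribute the disease proteins among pseudo-groups of
  the real group sizes and count pseudo-groups sharing two or more
  proteins with some real complex;
- **pseudo-PC** — the mirror image, randomizing the complex side;
- **non-LH** — pseudo-groups drawn from the pool of disease proteins not
  associated with locus heterogeneity;
- **pairwise** — compare the number of disease-protein pairs that both
  co-occur in a complex and cause two different diseases of one series
  against uniform random protein pairs, reporting the enrichment ratio.

Pseudo-groups are independent uniform subsets of the pool (a protein may
land in several pseudo-groups). A partition is impossible by arithmetic —
real group sizes sum to more than the number of distinct disease proteins
— so the independent-subset scheme is the minimal one preserving the size
multiset. Each control has its own seeded random stream;
fixed seed means bit-identical results. Z-scores use the sample (n−1)
standard deviation, standard for simulated nulls and indistinguishable
from the population version at the full-study setting of 100,000
replicates. A degenerate null (zero variance) yields an explicit
undefined flag rather than an infinite score.

## Murine-ortholog augmentation

Small coefficients can simply reflect ignorance: complex members that are
real disease genes not yet observed mutated in humans. For each
series-complex pair, a complex member outside the series is promoted to a
*presumptive disease protein* when its mouse ortholog carries a Mammalian
Phenotype term whose best-match Human Phenotype term is annotated to at
least one disease of the series (`find_presumptive_proteins()`).
Resemblance is exact term identity after the MP-to-HP translation — no
ontology-ancestor expansion — because the best-match table is itself the
product of a cross-species matching pipeline. We accept a match against
*any* disease of the series, not only diseases already in the
intersection; phenotypic similarity is a series-level property.

The augmented coefficient adds the promoted proteins to the intersection
while keeping the original group size in the union term:

$$ JC' = \frac{i + m}{g + p - (i + m)}. $$

This is a deliberate reading of "added to the intersection": the
presumptive proteins were already counted once inside the complex, so
recomputing a standard union over an enlarged group would double-discount
them and turn the canonical 4-in-12 example with two promotions into 0.50
instead of the intended behaviour (0.33 rising to 0.60). The formula
makes $JC' \ge JC$ with equality exactly when $m = 0$, an invariant the
tests assert globally. Augmentation can also create *new* records where
the original intersection was a single protein but reaches two with
promotions — this is how the count of series intersecting a complex
rises, not only the coefficients. We do require at least one real shared
protein as an anchor: a series with no observed disease protein in a
complex has no intersection to augment.

## Redundancy filtering of non-univocal relations

A series intersecting several complexes, or a complex intersecting
several series, is often an annotation artifact. For complex pairs within
one series (`filter_one_to_many()`), the discard precedence is:

1. `parent_child` — one complex is an ancestor of the other. Detection
   uses the transitive closure of `is_a`/`part_of` over *all* selected
   complex-named terms, including terms pruned from the analysis catalog:
   the witness parent may itself have been pruned;
2. `common_parent` — the two complexes share a *direct* parent. The three
   generic umbrella terms never count as a shared parent (in a real
   ontology almost every complex descends from them, which would void the
   rule);
3. `majority_shared` — the complexes share more than half (strict) of the
   smaller one's protein content. The denominator choice is the smaller
   complex: full enclosure then always triggers the rule regardless of
   the larger complex's size, which is the canonical case (a receptor
   complex fully inside a channel complex), while remaining symmetric in
   the pair. Full-enclosure cases do not discriminate between "half the
   smaller" and "half the union"; we document the choice rather than
   claim it is the only one.

Series pairs on one complex (`filter_many_to_one()`) are discarded when
the two series share an annotating protein — allele heterogeneity, where
one gene's different mutations cause diseases in both series.

A group counts as *univocal* when it is left with exactly one effective
complex: complexes connected by discarded (redundant) pairs collapse into
one effective entity, so a series hitting a complex and its parent is
univocal, while a series hitting three genuinely unrelated repair
complexes is not.

## The synthetic universe and what it does (not) show

`generate_universe()` writes a complete input bundle — morbid map, gene
catalog, series membership, OBO ontology, annotations, ortholog
phenotypes, MP-to-HP best matches, disease phenotypes, gain-of-function
flags — together with a truth manifest of every planted fact. The
generator's defaults are the package's study conditions:

- size samplers are discrete log-normals, clipped: series sizes with
  median ~4.5 (clip 2–40), mimicking the long-tailed 6.6 ± 8.1 proteins
  per series of real data; complex sizes with median 8 (clip 2–116), a
  compromise between the per-complex mean (7.8 ± 11.2) and median (13)
  typical of real snapshots, which no single unimodal size law matches
  jointly;
- a background of 40 series, 60 complexes and 1,200 coding genes, plus
  150 single-gene diseases outside any series (the non-LH pool), sized so
  a desk machine runs the full pipeline in seconds while chance overlap
  is still common enough to exercise every code path;
- planted overlap geometries (4, 12, i=4, m=2), (12, 14, i=5),
  (12, 88, i=5), (3, 88, i=3) and (3, 3, i=3) — the canonical worked
  examples, including the pair of complexes sharing one series's five
  proteins and a full intersection;
- planted redundancy cases (parent-child pair, common-parent trio,
  fully-enclosed pair, disjoint kept trio, allele-heterogeneity and
  disjoint series pairs on single complexes), pruning decoys (removable
  and exempt parent-of-parent chains, generic terms, a singleton, an
  obsolete term) and one morbid-map decoy per discard rule;
- `background_in_pc_frac` interpolates between a no-association world
  (0, the null for calibration) and a world where every background series
  sits inside some complex (1, the strong-association power check).

Identifiers are synthetic but format-valid, so parsers cannot
special-case test data, and the bundle is a byte-identical function of
the configuration and seed.

What passing on synthetic worlds shows: the pipeline recovers planted
overlap coefficients, presumptive sets, removal and discard reasons, and
relation classifications exactly, and its null models are calibrated
(median |Z| below 3 on 20 association-free worlds at 1,000 replicates)
yet powered (Z above 10 under full containment). What it does not show:
real OMIM/GO/MGI snapshots have correlated annotation biases — shared
curation provenance, literature-driven gene popularity, incomplete
phenotype vocabularies — that no independence-based generator reproduces.
Headline percentages from any specific database snapshot (which
complexes, how many series, which Z-scores) are version-dependent and
are treated as directional expectations, not numeric targets.

## Numerical and design choices, in brief

- Union in the coefficient is the standard set union. An additive
  reading ("all the series proteins plus all the complex proteins",
  counting shared proteins twice) would not reproduce the canonical
  worked examples; the set union does.
- Filter and pruning orders are fixed as listed; all reason counts are
  partitions, never overlapping tallies.
- The pairwise null draws, per replicate, as many uniform distinct-protein
  pairs as there are observed same-complex pairs, with replacement across
  replicates.
- Desk-scale problem sizes (tests and the acceptance script) are stated
  choices: 1,000 replicates per control, worlds of 30–80 series. The
  estimator is identical at the full-study 100,000 replicates, which any
  user can request.
- Degenerate inputs: two empty sets have no defined coefficient (error);
  a constant null flags Z as undefined; a series whose diseases collapse
  to one protein stays in the catalog, flagged, but cannot enter the
  two-protein intersection analysis.

## Known limitations

- Direct annotations only: a parent complex annotated sparsely will have
  a small member set even when its children are rich.
- Gain-of-function flags are consumed as a curated input table, never
  inferred from mutation text.
- The ortholog match is exact-term only; a coarser MP annotation that
  best-matches a sibling HP term of the disease phenotype is missed.
- The relation graph export assigns a complex's redundancy status within
  each series from its pair classifications; a complex kept in one pair
  and discarded in another counts as kept.
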