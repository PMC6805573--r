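---
title: "Bit-score-weighted voting for contig and MAG taxonomy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-score-weighted voting for contig and MAG taxonomy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxvote)
```

## The model

A long contig or a metagenome-assembled genome (MAG) carries many
protein-coding genes, each of which can be searched against a reference
protein database. `taxvote` treats each ORF's search result as one noisy
witness of the query's taxonomic origin and aggregates the witnesses by
weighted voting on the NCBI taxonomy tree.

**Per-ORF LCA.** For one ORF, let $B_{top}$ be the highest bit-score among
hits whose accession resolves to a taxid. All resolvable hits with

$$B \ge B_{top}\,(1 - r/100)$$

are collected and the ORF is assigned the last common ancestor (LCA) of
their distinct taxids; $B_{top}$ is registered as the ORF's vote weight.
The range parameter $r$ controls how conservative the per-ORF call is: a
conserved or horizontally transferred gene typically has near-top hits in
several clades, so widening the range drives its LCA toward a high rank,
which is exactly the desired behaviour — such a gene should not pretend to
carry species-level signal.

**Voting.** Each classified ORF adds its registered bit-score to its LCA
node and every ancestor up to the root. $B_{sum}$ is the total over
classified ORFs; by construction the root accumulates exactly $B_{sum}$
(a conservation law the test suite checks on random data).

**Assignment.** Given the support fraction $f$, the minimum bit-score
support is $mbs = f \cdot B_{sum}$. The query is assigned the set of
deepest nodes whose accumulated support reaches $mbs$ — a node qualifies
only if none of its descendants does. Because supports are non-increasing
from root to leaf, the qualifying nodes for $f > 0.5$ always form a single
root-anchored chain and at most one lineage is reported; for smaller $f$
several sibling lineages can qualify and all are reported with per-node
support values (fractions of $B_{sum}$). Support values rank confidence
but are not probabilities.

The model's assumptions are worth stating: bit-scores are taken as given
from the aligner and treated as additive evidence; ORFs are treated as
independent witnesses (tandem duplications of a transferred region violate
this); and the reference taxonomy is treated as correct.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| $r$ | percent below the top bit-score within which hits join the ORF LCA | 10 (contigs), 5 (bins) | bins pool hundreds of ORFs, so each ORF call can afford to be more specific |
| $f$ | minimum fraction of $B_{sum}$ a reported taxon must hold | 0.5 (contigs), 0.3 (bins) | $f = 0.5$ guarantees a single, majority-backed lineage; bins are large enough that minority lineages are informative |
| e-value cutoff | maximum alignment e-value | 0.001 | conventional protein-search significance level; applied when the table is parsed |

For downstream scoring, classifications computed at $f < 0.5$ are first
reduced to the single deepest node with support above 0.5
(`reduce_to_majority()`), i.e. scored as if $f = 0.5$ had been used.

## Numerical and edge-case choices

* **Boundary inclusive.** The range filter keeps hits with
  $B \ge B_{top}(1 - r/100)$; a hit tied with the top hit is never
  excluded, even at $r = 0$.
* **Floating-point tolerance.** All support and threshold comparisons use a
  relative epsilon of $10^{-9}$. Bit-scores are decimals parsed from text;
  summing them in different orders must not flip a boundary decision.
* **Unmappable hits.** Hits whose accession has no taxid are dropped
  *before* $B_{top}$ is determined, so the registered score is always the
  best score that carries taxonomic information. An ORF with no resolvable
  hit is reported with a reason (`"no hits"` / `"no taxid for hits"`) and
  contributes nothing to $B_{sum}$.
* **Duplicate HSPs.** Only the best line per (ORF, subject) pair is kept,
  so one database protein cannot vote twice for an ORF.
* **Sibling ties.** Two siblings with exactly equal qualifying support are
  both reported; majority reduction then stops at their parent. This is
  deterministic and conservative.
* **Merged and deleted taxids.** `merged.dmp` redirects are followed
  transitively before any lookup; `delnodes.dmp` entries and unknown taxids
  resolve to missing, which is a value, not an error. Mapping lines with
  unresolvable taxids are dropped with a counted warning rather than
  guessed at.
* **Accession LCA correction.** An accession occurring with several taxids
  (one database entry representing proteins from several organisms) is
  mapped to the LCA of all of them, which makes the map independent of
  line order; first-occurrence-wins is available for compatibility.
* **Root-only support.** A query whose votes only qualify at the root is
  still reported with its trivial lineage; the evaluation layer decides
  that such calls are uninformative (they count as unclassified).

## Evaluation machinery

Two scoring frameworks are implemented.

**Contig-set scoring.** A classification is *correct* if its lineage is a
subset of the true lineage, regardless of rank — and *incorrect* if it is
more specific than the truth (a species call on a novel family is wrong,
not partially right). Predictions at unofficial ranks are projected to
their deepest official ancestor; calls above superkingdom count as
unclassified. The four whole-set measures are the fraction of classified
contigs, sensitivity (correct/total), precision (correct/classified) — so
sensitivity = fraction × precision identically — and the mean/median rank
of classification with species…superkingdom mapped to 0…6. (That integer
mapping spans seven ranks; the deepest, species, is 0.) A per-rank
breakdown scores each official rank independently so only the too-specific
part of a lineage is penalised.

**Base-pair scoring.** At one official rank at a time, every measure is a
function of classified base pairs: accuracy (correct bp / total bp),
misclassification (incorrect bp / total bp), average precision (mean
purity over predicted taxon bins) and average recall (mean completeness
over real taxon bins). A query predicted at a rank absent from the gold
standard lineage is not taken into account — no penalty for over-specific
calls. Real taxa that received no assignment are included as zero-recall
bins; the alternative (averaging only over recovered taxa) would reward
classifying less. Because average precision is dominated by tiny erroneous
bins, it is also recomputed after discarding the smallest predicted bins
summing to at most 1% of the data (`filter_small_bins()`, ties broken
lexicographically by taxid for determinism).

## The synthetic-data generator

Real benchmarks for this class of tool require multi-GB reference
databases. The generator replaces them with a controlled model that
preserves the *statistical structure* the algorithm exploits:

* a complete seven-rank taxonomy with configurable branching (default
  branching 2 at superkingdom–order and 3 at family–species: 432 species,
  655 nodes — the smallest tree in which species-, genus- and family-level
  exclusion each leave at least two relatives at the next rank, so LCAs are
  well defined at every exclusion level);
* per species, a fixed number of database accessions (default 3);
* per ORF, hits whose bit-scores decay linearly with the rank distance of
  the subject from the true species (default mean 300 bits, decay 60 bits
  per rank step, Gaussian noise sd 5). The decay is deliberately larger
  than the default $r$-window (10% of 300 = 30 bits) so divergence steps
  are separable — mirroring the empirical fact that same-species hits score
  far above cross-genus hits for typical proteins;
* with probability 0.1 per ORF, one full-score hit to a uniformly random
  species, emulating conserved/HGT genes — the failure mode voting exists
  to absorb;
* genome fragmentation into at most 65 non-overlapping contigs of at least
  300 nt, with lengths drawn from a lognormal distribution by default
  (real assemblies have heavier-tailed, assembler-dependent length
  distributions; the fragmenter accepts any sampler).

What passing tests on this model *do* show: the LCA/voting/assignment
machinery is algebraically correct (it matches brute-force enumeration),
conserves evidence, responds monotonically to its parameters, recovers
planted truth, and degrades to higher ranks rather than wrong names under
clade exclusion, while a best-hit competitor degrades to wrong names.
What they do *not* show: performance on real databases, where bit-score
decay is gene-family-specific, taxon sampling is wildly uneven, and
taxonomy errors exist. The defaults above are fixed study conditions, not
tuning knobs.

The linear decay model is itself a design decision: published benchmarks
of this algorithm family use real genomes, which give no generative model
to copy. Linear decay with configurable slope is the simplest model that
creates controllable signal-to-noise across rank distances.

## Clade-exclusion benchmark

`clade_exclusion_experiment()` draws 50 query contigs (10 ORFs each) of
known species and classifies each against the full protein map and against
maps with that query's species, genus or family removed
(`clade_exclusion_reduce()`). Exclusion is applied per query — equivalent
to the batch construction of removing all queries' clades at once, but it
keeps each query's remaining relatives intact and makes the expected
retreat exact: one rank per exclusion level. Identical proteins shared
across clades, which in real databases force mapping-file edits instead of
sequence removal, do not arise because the generator gives every species
its own accessions.

Problem sizes throughout (50 queries × 4 levels in the benchmark; 100
queries against the brute-force assignment oracle; 200 random LCA sets)
are chosen so the full suite exercises every code path on hundreds of
distinct queries while remaining comfortable to run interactively.

## Known limitations

* Bit-scores from different aligners (or score matrices) are not
  calibrated against each other; use one aligner per run.
* The classifier never re-estimates alignment significance: the e-value
  filter at parse time is the only gate, as the aligner is trusted to
  report sensible bit-scores.
* Support values are not probabilities and are not calibrated; they are
  monotone evidence fractions.
* Viral sequences, plasmids and other taxa with shallow or unstable
  taxonomy will classify only as deep as the reference taxonomy allows.
* The output formats are semantically equivalent to, but not byte-level
  clones of, other implementations of this algorithm family.
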