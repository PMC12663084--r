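---
title: "Primer-aware placement-based taxonomy: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primer-aware placement-based taxonomy: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotaxa)
```

## The problem

Amplicon surveys sequence a short hypervariable window of a marker gene
(16S rRNA V1V2, V4V5, ...), and different windows resolve taxa to
different depths: two genera cleanly separated over the full gene can be
indistinguishable over one region. Classifiers that ignore this either
over-claim (a single label where the region cannot support one) or
under-claim (no label where a small set of candidates is defensible).
phylotaxa makes the region explicit: it trims an aligned full-length
reference database to the primer-delimited window, builds a
region-specific phylogeny, learns per-rank cophenetic distance
thresholds on that tree, propagates tip taxonomy to interior nodes --
keeping *one-to-many* label sets where the region genuinely cannot
discriminate -- and classifies queries by phylogenetic placement against
those labeled nodes.

## Threshold optimization

For a candidate threshold $t$ at rank $r$, the rooted reference tree is
cut into groups: the maximal clades whose *tip diameter* (largest
cophenetic distance among member tips) is strictly below $t$. Each group
is named for its plurality taxon at rank $r$. Two error terms are
counted:

* **over-merging** -- each additional distinct ground-truth taxon inside
  a group beyond the majority taxon adds one;
* **over-splitting** -- each additional group carrying an already-used
  majority name adds one.

Their sum, divided by the number of tips labeled at rank $r$, is the
tree-wise error in $[0, 1]$; the grid arg-min is carried forward,
independently per rank. Normalizing by the labeled tip count is our
choice (any positive constant leaves the arg-min unchanged); it is
bounded because over-merging is at most the labeled-tip count minus the
group count and over-splitting at most the group count minus one.

Numerical choices, all deliberate:

* Strict inequality `diameter < t`, so $t = 0$ yields one singleton per
  tip; the default grid therefore tops out just *above* the tree
  diameter so a single all-tips group stays reachable.
* The default grid (200 points) is half linear over $[0, \mathrm{diam}]$
  and half geometric over four decades, because genus and species optima
  live one to two orders of magnitude below the tree diameter.
* Ties take the smallest threshold -- the most conservative grouping.
* Majority ties inside a group break lexicographically, keeping the
  whole optimization deterministic.
* Tips with a missing designation at the scored rank are excluded from
  both error terms: an unclassified tip cannot witness an error.
* Cutting is clade-wise (a group is always the tip set of one node),
  not distance-only, so groups are monophyletic by construction.

## The binomial dominance model

When a node qualifies at a rank (tip diameter within that rank's
threshold), the labels of its descendant tips are not simply
majority-voted. Assuming each tip label is wrong independently with
probability 0.05, a label seen $k$ times among $n$ tips is retained iff
$P(X \ge k) \le 0.20$ for $X \sim \mathrm{Binomial}(n, 0.05)$: it is too
frequent to be annotation error. Several labels can pass -- that *is*
the one-to-many mechanism -- and if none passes, all observed labels are
kept. The direction of the inequality is the one reading under which
abundant labels survive and rare ones are absorbed; the opposite reading
(`tail_rule = "ge"`) is implemented and tested, because the informal
phrase "exceeds the error threshold" admits both.

After a rank resolves ambiguously, finer ranks descend hierarchically:
the tip multiset is partitioned by each retained label and the model
runs inside each partition, results unioned. A pooled alternative
(`hierarchical = FALSE`) is provided; per-partition is the default
because it prevents a large sister taxon from drowning out the species
structure of a smaller retained taxon.

The species rank is special. The learned species threshold tends to be
too permissive when false positives cost more than true positives are
worth, so an extra multiplier scales it: **specific** mode (default)
uses 0.1, **sensitive** mode 1.0, and any positive value can be set
directly. The multiplier applies both during node labeling and during
query assignment, so the two stages never disagree about what "within
the species threshold" means. The coarsest rank (Kingdom/Domain) has no
threshold of its own and is gated by the Phylum threshold.

## Query classification

Queries are aligned to the trimmed reference alignment NAST-style: a
shared-k-mer search picks the template, Needleman-Wunsch aligns query to
the degapped template, and the query is projected into reference
columns following the template's gap pattern; insertions relative to
the template move into adjacent template gap columns, or are trimmed
(counted) when none exist, so the alignment width never changes.
Coverage is the fraction of template positions aligned to a query base;
queries under 80% coverage are dropped (the boundary itself is kept).
If the reverse complement shares more k-mers with the reference than
the forward read, the query is flipped first.

Placement comes either from a jplace file (the fidelity route --
pplacer/EPA-ng output maps directly; edge numbers resolve to the child
node of each edge) or from the built-in distance placer: the top five
k-mer candidates are scored by Jukes-Cantor distance, scores become
normalized weights $w_i \propto e^{-L (d_i - \min d)}$ (an LWR analog),
and the attachment is at the candidate tip with pendant length $d_i$.
An exact sequence match pins the placement. This placer is a documented
approximation of maximum-likelihood placement, not a re-implementation
of it.

Placements within 50% of the best likelihood weight ratio survive
(inclusive). For each, the *index node* -- the child node of the
placement edge -- proposes a level: the finest rank at which the query's
distance to every tip under the index node is within the rank's
effective threshold. Query-tip distances are
`pendant + distal + path(index node, tip)`, where `distal` is the
distance from the attachment point to the index node; a switch
(`use_distal = FALSE`) ignores the along-edge position, since placement
tools differ in how meaningfully they report it. Across surviving
placements, the modal proposed level wins (ties toward the coarser
level), label sets are unioned rank by rank down to that level, and
finer ranks are emptied. A query farther than the Phylum threshold from
everything is reported unassigned.

## Evaluation conventions

A prediction containing at least one member of the truth counts as
correct even when it is a multi-label set; an empty prediction is
correct exactly when the truth is absent from the classification
database. The default metric accounting treats correct non-assignments
as true positives (precision and recall both reward leaving a novel
sequence unlabeled); because that convention is unusual, a standard
accounting (correct non-assignments as true negatives) is one switch
away. Undefined ratios (zero denominators) are reported as `NA`, never
as 0 or 1.

## What the synthetic generator emulates -- and what it does not

`simulate_fixture()` builds a rank-nested tree whose clades *are* taxa:
every parent taxon spawns a fixed number of children per rank, species
spawn tip sequences, and branch lengths follow a per-rank ladder.
Default conditions: 2 phyla x 2 classes x 1 order x 2 families x 2
genera x 2 species x 3 sequences (96 tips), 1500 bp sequences
(full-length marker-gene scale), and branch scales chosen to mirror
typical 16S divergence -- within-species tip diameters 0.6%,
between-species distances ~3%, between-genus ~9%, between-family ~19%.
These separations make the threshold-recovery problem well-posed: at
every rank the within-taxon diameter is strictly below the smallest
between-taxon distance, so a zero-error threshold interval exists, and
at 1500 bp the Jukes-Cantor estimation noise is small relative to those
margins. Sequences evolve by per-site independent substitution with
probability $\tfrac{3}{4}(1 - e^{-4d/3})$ per branch of length $d$ --
a Jukes-Cantor process, deliberately simpler than the GTR model a
maximum-likelihood tree builder assumes. Mis-annotation is emulated by
swapping a fraction of database lineages after truth is recorded; gap
decoration and an explicit region window emulate alignment structure
and primer trimming.

What passing tests on these fixtures show: the optimizer, dominance
model, placement logic and metrics implement their definitions exactly,
and the whole pipeline is consistent end-to-end when the data satisfy
the method's own assumptions. What they do not show: performance on
real 16S data, where taxa are para- and polyphyletic, rank depths are
wildly uneven, alignment columns are not independent, and regions
differ in entropy profile -- none of which the generator attempts to
mimic beyond its branch-length and noise knobs.

## Tree building and other substitutions

The internal tree builder is neighbor joining on Jukes-Cantor distances
with pairwise deletion, midpoint-rooted, with negative branch lengths
clamped to zero. It is a documented lightweight stand-in: the intended
production route is an external maximum-likelihood tree (FastTree or
similar) ingested as Newick, which preserves GTR-based distances.
Midpoint rooting is used because threshold cutting needs a root and
unrooted input carries none. Subspecies and strain designations are
collapsed on ingest by truncating the species token to its first two
words; this is simple and predictable but will also truncate
"Candidatus X y z" style names -- a known, flagged limitation rather
than a guessed-at rule.

## Problem sizes in the shipped tests

The test suite and the acceptance script regenerate everything in code:
96-tip default fixtures (24-tip reduced fixtures where tree shape is
irrelevant), 100 random trees of up to 12 tips against brute-force
oracles, exhaustive binomial-tail enumeration to $n = 25$, and holdout
experiments of 16-36 queries per scheme aggregated over several seeds.
These sizes were chosen so that every check has a margin-backed
expected outcome; all randomness flows from fixed seeds.
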