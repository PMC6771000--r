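---
title: "panlin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panlin: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panlin)
```

panlin analyses collections of bacterial genomes the way genus-level
pangenome studies do: proteomes are clustered into gene families at a fixed
identity threshold, the families are partitioned into core / accessory /
strain-unique sets, pangenome growth is summarised by accumulation curves
and a Heaps-law openness verdict, whole-genome relatedness is measured by
fragment-based average nucleotide identity (ANI) and reciprocal-best-hit
average amino-acid identity (AAI), and proteomes are screened for
xenobiotic (aromatic/lindane) degradation enzymes, including isoform
typing of the γ-hexachlorocyclohexane dehydrochlorinase LinA. This
vignette explains the models, the tunable parameters, and the design
decisions where the design was genuinely open.

## Pairwise alignment and identity

Every stage reduces to optimal pairwise alignment with affine gaps
(Gotoh's three-state recurrence). A gap of length $L$ costs
$\mathrm{open} + \mathrm{extend}\cdot L$, the BLAST convention. Defaults
are BLOSUM62 with open 11 / extend 1 for protein and +2/−3 with open 5 /
extend 2 for nucleotide — the blastp/blastn defaults, chosen for
comparability since no alternative is dictated by the method being
emulated. Equal-scoring tracebacks are resolved deterministically
("high road": diagonal, then up, then left), so identical inputs always
yield identical alignments.

Percent identity is **policy-explicit**, because the two tools this
pipeline emulates disagree:

* `shorter`: matches divided by the length of the shorter sequence —
  CD-HIT's convention, used for clustering and LinA typing;
* `alignment`: matches divided by alignment length including gap columns —
  BLAST's convention, used for local screening hits and AAI.

Ambiguous residues never count as an identity match (`X`/`*` for protein,
`N` for nucleotide). Values are kept at full precision internally and
rounded to one decimal place only in reports.

E-values use the Karlin–Altschul form $E = K\,m\,n\,e^{-\lambda S}$ with
the standard gapped BLOSUM62 constants ($\lambda = 0.267$, $K = 0.041$).
This is an approximation — no composition adjustment, no finite-size edge
correction — and is adequate here because e-values are only ever used as a
pass/fail gate ($<10^{-5}$ for screens, $\le 10^{-3}$ for AAI hits), far
from the regime where the approximation matters.

## Greedy clustering (CD-HIT semantics)

Records are sorted by length, longest first (ties broken by identifier,
radix order), and processed in turn: a record joins the **first** existing
cluster whose representative it matches at identity $\ge c$ (shorter
denominator) and length ratio $\mathrm{len(short)}/\mathrm{len(long)} \ge
s$; otherwise it founds a new cluster and becomes its representative.
Defaults $c = 0.8$, $s = 0.9$. Because representatives are founders in a
longest-first scan, a representative is always a longest member. Members
are only ever compared to representatives (no transitive closure), which
is what CD-HIT does; this makes borderline assignments order-dependent in
principle, hence the canonical sort. A `best = TRUE` mode assigns to the
highest-identity eligible cluster instead of the first.

A word prefilter skips hopeless comparisons: a pair is aligned only if at
least 10 % of the shorter sequence's 4-mers occur in the longer one. At
$c = 0.8$ roughly 40 % of the shorter sequence's 4-mers survive
mutation ($0.8^4 \approx 0.41$), while unrelated proteins share close to
none, so the cut-off has a wide safety margin — but it is a heuristic, not
a theorem (the provable CD-HIT-style bound is vacuous at 0.8). It is
property-tested against threshold-straddling pairs and can be disabled
with `prefilter = FALSE`.

## Pangenome partition and the unique-cluster filter

With $G$ genomes, a cluster is **core** when present in all $G$,
**unique** when present in exactly one (only defined for $G > 1$; a
single-genome collection is all core), and **accessory** otherwise.

A cluster can be called unique spuriously when its homolog in another
genome diverged past the clustering threshold. `filter_unique()` re-tests
each unique representative by local alignment against every protein of
every other genome; a hit with e-value $\le 10^{-5}$ and identity
$\ge 50\,\%$ reclassifies the cluster to accessory. The thresholds reuse
the screening gates — the closest documented choice, configurable — and
reclassified clusters are moved, never deleted, so the partition stays
exhaustive. Every removal is logged with the offending hit.

## Accumulation curves and openness

For each of `R` genome orderings (random permutations under a mandatory
seed), the pangenome size and core size are recorded after each added
genome; per-step medians and IQRs (type-7 quantiles, stated because IQRs
are method-sensitive) summarise the orderings. When `R` $\ge G!$ (and
$G \le 9$) all orderings are enumerated instead, making medians exact.

Openness is decided by fitting the Tettelin-style power law to the median
number of **new** clusters contributed by the $k$-th genome,
$n(k) = \kappa\, k^{-\alpha}$, by least squares on the log–log scale
(exact on a noise-free power curve; steps contributing zero new clusters
are dropped, and a curve with fewer than two positive steps is saturated,
hence closed). The verdict is **open** iff $\alpha < 1$ — the regime where
the cumulative pangenome grows without bound ($\gamma = 1 - \alpha > 0$) —
rather than an eyeballed judgement of curve flatness.

Per-genome unique-cluster counts can be correlated with each genome's
nearest patristic distance on a user-supplied tree (Spearman, average
ranks for ties, two-sided p). Note one structural subtlety: the
nearest-distance vector always contains at least one exact tie (the
mutually closest pair), so $\rho = 1$ is only attainable when the counts
carry the same tie structure.

## ANI and AAI

**ANIb-style ANI.** The query genome is cut into consecutive 1020-bp
fragments (terminal remainder kept when $\ge$ half a fragment). Each
fragment is placed on the subject by exact 15-mer seeds voting on binned
diagonals — both strands, best bin wins — and then optimally locally
aligned against the winning window (the seed-and-extend role BLASTn plays
in conventional ANIb; full DP against a megabase subject would be
$10^{12}$ cells). A fragment is **used** iff its alignment reaches 30 %
identity over 70 % of its length (the Goris/Richter gates); ANI is the
mean identity of used fragments, reported as missing — never 0 — when no
fragment is usable. Direction is query→subject; reports also carry the
symmetrised mean.

**AAI.** All proteins of two proteomes are locally aligned once per pair;
a hit is eligible at e-value $\le 10^{-3}$, identity $\ge 30\,\%$ and
coverage $\ge 70\,\%$ of the shorter protein. Reciprocal best hits
(deterministic tie-break by subject id) define the pair set; AAI is their
mean alignment-length identity and is symmetric by construction because
both directions reuse the same alignments.

## Pathway screen and LinA typing

The screen aligns every query protein against a user-supplied,
route-labelled reference FASTA (`route=` key in the header; a small fully
synthetic fixture mimicking the route structure — catechol 1,2-/2,3-
dioxygenation, naphthalene–salicylate, biphenyl–benzoate, gentisate — is
bundled; the published aromatic-degradation database is not
redistributable). Hits must pass **strictly** e-value $< 10^{-5}$ and
identity $> 50\,\%$ — boundary values are excluded, matching how printed
filter inequalities read; the unique-cluster filter above is inclusive,
matching its own contract. Copy number counts distinct query proteins per
(genome, reference) pair; fractions of references hit once / twice /
thrice / ≥4 times are reported.

`type_lina()` globally aligns a candidate against named LinA variants
(shorter-denominator identity, 1 d.p.). Diagnostic residues are read off
the query at reference-frame positions 20, 23, 25, 35, 73, 96, 129, 131
(1-based on the 154-residue LinA frame), projected through the alignment
so insertions in the query never shift reported positions. The catalytic
call requires D25, H73 and R129; the enantioselectivity call is
`minus_preferring` when K20, L96 and A131 are all present, `indeterminate`
when any of the three positions is unreadable (gap or unaligned), and
`plus_preferring` otherwise — the published diagnostic rule only defines
the (−)-preferring signature, so its complement is the package's own
reading, flagged here. A query under 60 % identity to every reference is
reported `best_variant = "none"` with residues unset.

## The synthetic-data generator

`simulate_pangenome()` emits exactly the world the analysis assumes:
independent random family ancestors (kept pairwise below 40 % identity by
rejection sampling with a retry cap), core families in all genomes,
accessory families present per genome with probability `accessory_p`,
unique families private to one genome, and every copy mutated from its
ancestor at the configured per-site divergence. Substitutions are uniform
over the alternative residues — deliberately unrealistic, because it makes
expected identities analytically exact ($\mathbb{E}[\mathrm{id}] =
1 - d$ to the ancestor, $\approx (1-d)^2$ between members). A count-exact
mode substitutes exactly $k$ chosen positions, used for fixtures like the
154-residue pair at exactly $152/154 = 98.7\,\%$. Truth classes are
derived from the **realized** presence pattern, so "recovered equals
truth" is well-defined even when an accessory family happens to land in
every genome. Companion nucleotide genomes reverse-translate each
proteome with wobble bases steered toward a target GC; a star-with-noise
tree is emitted alongside.

What a green test does establish: threshold arithmetic, partition logic,
curve statistics and calibration of ANI/AAI against known divergence.
What it does not: robustness to indels, rate heterogeneity, paralogy,
horizontal transfer or annotation noise — none of which the generator
models. Defaults (divergence 0.05, proteins 200–400 aa, accessory
presence 0.5) sit in the regime where exact truth recovery is guaranteed
with margin: at divergence 0.05 a member is ~90 % identical to its
representative, five binomial standard deviations above the 0.8
threshold for a 300-aa protein; at 0.08 recovery still usually succeeds
but occasional family splits are expected and observed.

## Numerical and degenerate-input choices

* Feature intervals are 1-based inclusive (GFF convention); unions are
  computed with IRanges, which shares that convention, so no coordinate
  shift occurs at the boundary.
* GC% excludes ambiguity codes from numerator and denominator; they still
  count toward total length.
* Missing Newick branch lengths become 0 with a warning; negative lengths
  are an error; unbalanced parentheses report the character offset.
* ANI/AAI of incomparable inputs is `NA`, never 0.
* `heaps_fit` refuses non-monotone pan curves (they violate the
  accumulation invariant) and needs $\ge 3$ genomes.
* Seeds are mandatory wherever randomness exists; generator output is
  byte-identical under a fixed seed.

## Known limitations

The aligner is exact, not heuristic — fine for desk-scale collections
(hundreds of proteins per proteome), not for 44 real proteomes at 4,000
proteins each, where a seeded search would be needed. ANIm
(MUMmer-style maximal exact matching) is out of scope; report schemas
reserve a column for externally computed values. The e-value model is a
gate, not a statistic to report. COG-style category tallies consume a
finished annotation table; assignment is out of scope.
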