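---
title: "Methods: sugar-transporter classification, promoter scanning and macroarray quantification"
author: "vitisugar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sugar-transporter classification, promoter scanning and macroarray quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitisugar)
```

`vitisugar` implements the desk side of a classical plant
sugar-transporter family study: similarity-based classification of
candidate transporter proteins, cis-regulatory element analysis of
their promoters, and quantification of dedicated cDNA macroarray
membranes. This vignette records the models, the tunable parameters,
the numerical choices, and the design decisions that were genuinely
open — and what the synthetic-data validation does and does not show
about real data.

## 1. Percent similarity and subfamily assignment

### Model

Two protein sequences are compared by an optimal **global alignment
with affine gaps** (Needleman–Wunsch–Gotoh, implemented in C++). A gap
of length $k$ scores $g_o + (k-1)\,g_e$; switching the gapped sequence
opens a new gap. The default scoring is match $1$, similar $0.5$,
mismatch $0$, $g_o = -10$, $g_e = -0.5$. "Similar" means the two
residues share one of the classic strong conservation groups
(STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW).

Percent similarity is computed from the alignment as

$$S(a, b) = 100 \cdot
  \frac{\#\{\text{residue/residue columns identical or similar}\}}
       {\min(|a|, |b|)}.$$

Dividing by the *shorter* sequence makes $S$ length-robust: a fragment
fully contained in a longer protein scores 100, which is the desired
behaviour when partial ORFs are compared against full-length
references. Because the numerator counts only residue/residue columns,
$S \in [0, 100]$ always holds.

Legacy desktop alignment suites report "percent similarity" under
unpublished parameterizations, so printed similarity values from older
family surveys should be treated as context: this package's $S$ is a
reproducible measure in the same spirit, not a byte-exact reimplementation
of any commercial tool. All results that matter downstream
(subfamily assignment, tree shape) are threshold- and rank-based, not
absolute-score-based.

**Tie-breaking.** The traceback prefers diagonal over up (gap in the
second sequence) over left. This makes alignments — not just scores —
deterministic.

### Assignment

A query is assigned the subfamily (SUC plus monosaccharide subfamilies
I–VII) of the panel entry with maximal $S$. Three outcomes are
distinguished: `assigned`; `unassigned` when the best similarity falls
below `minSimilarity` (default 30%, chosen below the lowest
within-family similarity typically reported for these families,
≈ 36%); and `ambiguous` when two subfamilies tie at machine precision
($10^{-9}$), in which case both candidates are returned rather than an
arbitrary winner. The margin to the best other-subfamily hit is always
reported so borderline assignments are visible.

### Distance tree

The family tree is neighbor joining on $d = (100 - S)/100$ with **no
multiple-hit correction**: it is a descriptive summary of pairwise
similarity standing in for a likelihood phylogeny, not an evolutionary
estimate, and is documented as such. Rarely, NJ produces negative
branch lengths; these are clamped to zero with the deficit moved to
the sister branch, preserving the sibling–sibling path length. For
additive inputs NJ is exact, which the tests verify to $10^{-9}$ on
random trees of 5–12 leaves.

## 2. Promoter extraction

The promoter is the region of at most 2 kb (`maxLen`) immediately
upstream of the start codon, clipped at the chromosome edge and at the
nearest upstream annotated feature, **exclusive** of that feature's
proximal boundary. Annotations rarely distinguish a neighbouring
gene's stop codon from its annotated end; we truncate at the annotated
feature bound, the conservative reading. Minus-strand genes take the
genomic window downstream of `cds_start`, reverse-complemented, so the
result always reads 5'→3' toward the start codon. A promoter shorter
than `maxLen` carries `truncated = TRUE`; a zero-length window (start
codon at position 1) is an error rather than an empty sequence.

## 3. Motif scanning and classification

### Matching semantics

Motifs are IUPAC-degenerate consensus words, compiled to per-position
allowed-base sets. Three deliberate choices:

* **Forward strand by default.** The historical plant cis-element
  databases do not state a strand convention; forward-only avoids
  silently double-counting self-complementary patterns such as
  `CANNTG`. `strands = "both"` counts (start, strand) pairs on both
  strands with *no* palindrome deduplication, and is documented loudly.
* **All overlapping matches count.** Short elements like `ATATT` reach
  dozens of copies per 2 kb only if overlaps are counted.
* **Sequence ambiguity codes are conservative.** An `N` in the
  promoter (assembly gap) satisfies no motif position except motif-`N`.

The packaged library holds exactly the 30 elements whose consensus
strings the workflow is built around — 20 near-universal elements, 9
single-gene elements, and the sugar/ABA S-box `CACCTCCA`. Other
sugar-signalling elements (SURE boxes, sucrose box 3, AMY boxes,
pyrimidine-box variants, ...) must be supplied by the user through the
JSON library format: the package performs no silent external lookups.

### Classifications

From the promoter × motif count matrix:

* **Common** — present in all but at most `toleranceMissing` promoters
  (default 0). Real promoter sets often include one severely truncated
  promoter missing a handful of otherwise universal elements, so the
  tolerance is an explicit flag, not a hard-coded exception; the
  missing genes are always reported.
* **Unique** — present in exactly one promoter (undefined, hence an
  error, for a single-promoter table).
* **Family-restricted** — all carriers in one family, with at least
  two carriers (one carrier is "unique", keeping the two sets disjoint
  by construction).
* **Sugar repertory** — per gene, the number of *distinct* motifs from
  a user-chosen sugar-responsive set, ranked.
* **Composite** — all components present anywhere in the promoter
  (`all_present`), with no spacing constraint: the classical
  gibberellin-response complex is described by co-occurrence of the AMY
  boxes and a pyrimidine box, and no inter-element distance is stated
  in the source literature.

## 4. Macroarray quantification

The processing chain per membrane: background subtraction clipped at
zero → strict presence call (`mean(gene spots) > mean(negative-control
spots)`; equality is absence) → division of every spot by the
membrane's reference factor, the mean over the four reference genes
(actin, EF1α, EF1γ, GAPDH) of their mean corrected intensities. A
membrane whose reference gene fails the presence call is unusable and
raises an error naming the gene.

Decisions worth recording:

* **Normalization precedes pooling.** Each membrane is normalized to
  its own references before the six replicates (3 spots × 2
  membranes) are pooled at **spot level**; this removes membrane-level
  exposure differences exactly, which the scale-invariance tests
  verify to $10^{-12}$. Pooling at spot level rather than
  membrane-mean level weights both membranes' spots equally and keeps
  the spot-level variance visible in the reported SD.
* **Absent genes contribute zeros, not missing values**, to the
  per-condition mean of all genes — the denominator of the "red point"
  high-expression call (`mean(g, c) > condition mean`). This
  reproduces the all-genes-mean semantics of the original figures.
* **Spot mass asymmetry** (50 ng transporter vs 100 ng reference cDNA)
  is not corrected: values are relative units, matching the original
  presentation.
* **Preferential/induced rules are a declared surrogate** for the
  qualitative bold/underline summary of the original study:
  preferential means `mean(g, c) ≥ fold ×` the gene's mean across
  conditions (default fold 2); induced over an ordered stage series
  means non-decreasing across stages with final ≥ fold × first and a
  nonzero endpoint. The most-expressed genes per condition are
  restricted to the above-mean set, so a flat condition highlights
  nothing.
* The Northern-style variant normalizes to a single reference gene
  (GAPDH), mapping the reference to 1.0.

## 5. Synthetic data: what it emulates, and what it does not

The generators define the validation conditions; their defaults are
fixed once:

* **Promoters** (`simulatePromoters`): 2 kb sequences on poly-C,
  uniform-ACGT or fixed-GC backgrounds with planted motif copies at
  random positions separated by ≥ 10 background bases (the widest
  packaged motif), so two planted words can never compose a spurious
  third one. On poly-C the truth table equals the scanner output
  *exactly* for any motif requiring a non-C base; on random
  backgrounds chance hits come on top, and only then. The validation
  set mirrors the study scale: 29 promoters with planted copy numbers
  spanning 1–45, the range the common elements reach in real 2 kb
  promoters.
* **Membranes** (`simulateMembranes`): 3 spots per gene, 2 membranes
  per condition, four reference genes at levels 800/1000/900/1300
  (arbitrary units), negative controls at 40 (implying a detection
  threshold of 0.04 relative units), per-membrane exposures (1, 1.5),
  and log-normal multiplicative spot noise — intensities are positive
  and hybridization noise is proportional — with unit mean
  ($\sigma = \sqrt{\ln(1 + cv^2)}$, $\mu = -\sigma^2/2$). The additive
  local background is drawn per spot and recorded, so subtraction is
  exact. At $cv = 0$ the pipeline must (and does) return the truth
  matrix exactly; at $cv = 0.1$ the recovered matrix correlates with
  truth at $r > 0.95$ over 24 genes × 6 conditions.
* **Families** (`simulatePanel`, `simulateFamily`): one random
  200-residue ancestor per subfamily, two members each at 5% within-
  subfamily divergence, queries at an i.i.d. substitution rate ≤ 0.5
  (above which assignment is unidentifiable and rejected). Unrelated
  random proteins share only ≈ 5–10% identity, so subfamilies are well
  separated and assignment at ≤ 20% divergence is expected to be
  nearly perfect — which is the property being verified, not a claim
  about real transporter families.

Every generator derives its RNG stream from the root seed via a
labelled hash (`deriveSeed`), so adding one generator never perturbs
another's draws, and identical seeds give bit-identical outputs.

**Limitations.** The synthetic backgrounds have no real promoter
composition, chromatin context or motif clustering; the noise model
has no spatial (print-tip) structure, no probe cross-hybridization and
no saturation; the protein model has i.i.d. substitutions with no
indels, rate heterogeneity or conservation structure. Passing the
validation therefore demonstrates that the *rules are implemented
exactly as stated* and are numerically stable — not that the rules
recover truth on real membranes or real genomes. Equally, exact
reproduction of any historical study's printed similarity percentages,
copy counts or expression values is out of scope: those depend on a
specific genome release, a full external motif inventory, and
unpublished membrane images.

## 6. Problem sizes and numerics

The shipped validation uses 200 random 500-bp sequences against all 30
motifs for the scanner-vs-oracle check, exhaustive alignment
enumeration for all sequence pairs up to length 3 plus a seeded sample
covering every length combination up to 6×6, 500 queries for
subfamily recovery, 1000 random tables for classification
disjointness, and 20 random trees for NJ recovery — sizes at which the
independent oracles (regex window counting, recursive alignment
enumeration, closed forms) remain exact and fast. Floating-point
tolerances: $10^{-12}$ for scale invariance, $10^{-9}$ for tree path
lengths, machine tolerance elsewhere; strict inequalities in presence
and red-point calls are tested at exact equality boundaries.
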