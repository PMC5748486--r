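---
title: "Methods: multi-region intratumor heterogeneity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region intratumor heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`regionith` analyses genetic intratumor heterogeneity (ITH) from
multi-region tumor sequencing in which each spatially distinct biopsy is
split into a tissue half and a matched in-vitro spheroid culture, with
optional lymph-node metastases (LNMs) and a matched germline sample.  The
package covers the computational stages downstream of variant calling:
presence filtering, shared/regional classification, mutational-spectrum
testing, rooted sample phylogenies scored by character compatibility,
binary-distance clustering, biopsy–spheroid concordance statistics, and an
allele-frequency purity estimate.  Everything upstream (alignment, somatic
calling, copy-number analysis) and everything RNA-based is out of scope.

Because the patient-level data such a study produces is controlled-access,
the package carries a synthetic clonal-evolution cohort simulator with full
ground truth; every analysis stage is validated against simulations whose
latent state is known exactly.

# Input model and filtering rules

The unit of input is a read-count matrix: for every candidate somatic SNV
and every sample, reference and alternate read counts, plus a matched
germline column with its own counts.  Counts may arrive as per-sample VCFs
with `AD` fields or as a single TSV matrix; sites are keyed by
`(chrom, pos, ref, alt)` in 1-based VCF convention, SNVs only.

Filtering follows three rules applied in order:

1. **Germline rule.**  A mutation is admitted only if the matched germline
   shows 0–1 alternate reads; two or more germline reads exclude it from
   the matrix entirely.  The boundary is read literally: one stray germline
   read (sequencing error at ~79x) does not disqualify a somatic call.
2. **Presence rule.**  Within admitted mutations, a sample is called
   *present* when it has ≥ 2 alternate reads, *absent* otherwise.
   Mutations present in no sample are flagged uncalled and dropped.
3. **Coverage mask.**  A *regional* mutation whose negative (absent)
   samples include one with site depth < 10 cannot be distinguished from a
   false negative.  Two treatments are provided because they serve
   different consumers: `drop` removes the mutation (used for heatmap and
   distance matrices, where a spurious absence would distort clustering),
   and `missing` converts only the unreliable cells to an explicit missing
   state (used for tree scoring, where a missing cell simply constrains
   nothing).  Shared mutations are never masked.  Defaults: `drop` for the
   heatmap matrix, `missing` for the phylogeny input.

**Sharing labels.**  With $n$ samples for a patient, a mutation present in
$n$ or $n-1$ samples is *shared*; present in at least one but fewer than
$n-1$ is *regional*.  The $n-1$ allowance absorbs single false-negative
samples (low purity or coverage) without demoting truly clonal mutations.

# Mutational spectrum and CpG enrichment

Substitutions are collapsed to the six pyrimidine-reference classes
(C>A, C>G, C>T, T>A, T>C, T>G): a purine-reference change is
reverse-complemented together with its trinucleotide context, so the
classification is strand-symmetric by construction.  The CpG flag is true
when the (possibly complemented) context has the mutated C immediately
followed by G; NpCpG sites on the minus strand therefore count through the
complemented representation, the standard convention for "C>T at CpG".
Contexts must be supplied with the input (the simulator emits them); the
package deliberately does not fetch a reference genome.

The enrichment test collapses the spectrum to a 2×2 table,
$\{\text{C>T at CpG}, \text{other}\} \times \{\text{shared},
\text{regional}\}$, and applies Pearson's chi-squared test with 1 df,
without continuity correction by default (counts in this design are large;
a `correct` flag is available).  A zero margin — an empty group or no
C>T-at-CpG mutations at all — refuses the test with an explanatory error
rather than returning a degenerate statistic.

# Rooted sample phylogenies by maximum compatibility

Each retained mutation is a binary character over the samples.  For a
rooted binary tree whose leaves are the samples, a mutation is
**compatible** when some clade (including single leaves, and the full leaf
set, i.e. the trunk) contains every sample in which the mutation is
present and excludes every sample in which it is explicitly absent;
missing cells constrain nothing.  The tree score is the number of
compatible mutations, and the best tree is a maximum-compatibility tree.
Each compatible mutation is assigned to the incoming edge of the
*smallest* such clade (which is unique, clades being laminar), so edge
supports — the branch lengths — count the mutations supporting each
separation, with truncal mutations accumulating on the trunk above the
root.  Incompatible (homoplastic) mutations support no edge and are
reported separately: under the perfect-phylogeny null they indicate either
noise or genuine parallel events, and silently spreading them over edges
would distort branch lengths.

Scoring counts mutations unweighted.  Weighting by allele frequency was
considered and rejected: AF conflates purity with clonality, and the
presence/absence abstraction is what the branch-support semantics ("number
of mutations supporting this separation") is defined on.

**Search.**  Two modes:

* *Exhaustive* — every rooted binary leaf-labeled topology is generated by
  sequential leaf insertion ($(2n-3)!!$ shapes) and scored in compiled
  code; feasible to the default limit of 9 samples (2,027,025 topologies,
  about a second of CPU).
* *Hill climbing* — steepest ascent over a composite neighborhood:
  nearest-neighbor interchanges, root relocation to every edge, and leaf
  prune-and-regraft.  The first start is the average-linkage join tree on
  binary distances (a good initial guess since clustering and
  compatibility usually agree on strong signal); the remaining starts
  (10 by default) are uniform random topologies.  NNI alone explores too
  few rearrangements at these sizes; adding root moves and leaf SPR lifts
  the empirical hit rate against the exhaustive optimum from ~90% to ~99%
  on random matrices with up to 8 samples.

Score ties are broken by the lexicographically smallest canonical newick
(children ordered by smallest leaf label), so results are deterministic
given the seed.  Newick output writes edge supports as branch lengths and
the trunk support on the root (e.g. `(A:2,B:3):5;`).

# Clustering, concordance, clone blocks, purity

**Binary distance.**  $d(x,y)$ is the fraction of mutations carried by
exactly one of the two samples among mutations carried by at least one,
computed over cells where both are non-missing; joint absences are ignored
(the "binary" distance of standard statistical software).  Average
(UPGMA-style) linkage then orders samples for heatmaps and dendrograms.

**Concordance.**  For each area's biopsy/spheroid pair, the union of
mutations present in either member is partitioned into *tumor-only*,
*spheroid-only*, *pairwise-private* (present in both members and in no
other sample of the cohort) and *concordant-elsewhere*; the four fractions
sum to one, and the headline concordance is the fraction present in both
members.  Pairwise-private mutations are deliberately kept a subset of the
concordant set and reported separately — they are concordant between the
pair yet private to the area, which is exactly what makes them
evolutionarily informative.  *Private* mutations are present in exactly
one sample cohort-wide; the per-sample private fraction uses that sample's
observed mutations as denominator.  A `coding_only` switch restricts all
counts to coding point mutations, with silent, missense and nonsense all
counting as coding.

**Clone blocks.**  Sample-subset presence patterns (present in all of set
X, explicitly absent in all of set Y, unconstrained elsewhere) extract
mutation blocks such as the *metastatic block* (present in all LNMs and
the seeding tumor region, absent elsewhere) and the *nonmetastatic block*
(present in all tumor regions, absent in all LNMs).  On clean simulated
cohorts these patterns recover the corresponding clone-tree branches
exactly; the demonstrations use error-free reads at depth ≈ 300 because
exact set equality is only meaningful when presence calling itself is
noise-free.

**Purity.**  Under the diploid heterozygous model a clonal mutation in a
sample of purity $p$ has expected AF $p/2$, so the estimate is
$\min(1, 2 \cdot \mathrm{median}(\mathrm{AF}_{\text{truncal}}))$.  The
median resists subclonal contamination of the truncal set and individual
outlier sites; at least 3 usable truncal AFs are required, otherwise the
estimate is missing with a warning.  This is a deliberately simple
estimator for diploid simulations and sanity checks — it is not a
replacement for CNA-aware purity callers, and it will be biased wherever
truncal mutations sit on copy-altered segments.

**Rank tests.**  Spheroid-vs-biopsy purity uses the paired Wilcoxon
signed-rank test; matched-pair vs cross-area tree distances (path length =
sum of edge supports between two leaves) use the two-sided Wilcoxon
rank-sum test.  Both use the exact null distribution whenever the data are
tie-free — exactness is cheap and deterministic at cohort sizes, so the
exact path is not restricted to very small $n$ — and fall back to the
tie-corrected normal approximation with continuity correction otherwise.
Degenerate inputs (identical groups, all-zero differences) return $p = 1$
with a warning instead of erroring.

# The simulator

The generator emulates the sampling design the analysis targets:

* a clone phylogeny (uniform random recursive tree when unstructured, or a
  fixed design for specific scenarios), rooted at the ancestral clone;
* a **truncal block** on the root edge drawn from a truncal spectrum
  dominated by C>T at CpG (weight 0.45), and regional/private mutations on
  every other edge from a flatter spectrum (C>T-at-CpG weight 0.15, more
  C>A).  These weights are configuration values chosen to produce a
  detectable spectrum contrast of the kind aging-related deamination
  creates on the trunk; they are not estimates of any particular cohort;
* 3–5 tumor regions, each a biopsy/spheroid pair: the biopsy mixes the
  ancestral clone, a region clone and a biopsy-private subclone
  (0.20/0.55/0.25); the spheroid subsamples the biopsy's clones, keeping
  the region clone and enriching a different subclone (0.05/0.75/0.20),
  which yields biopsy-private, spheroid-private and pairwise-private
  mutation sets of realistic size;
* biopsy purity uniform on 0.4–0.7 with a spheroid uplift of 0.15–0.3
  (capped at 1), so spheroids are purer than their matched biopsies, as
  culture enrichment of cancer cells produces in practice;
* per-site depth negative-binomial with mean 79 and size 8 — the
  whole-exome coverage scale this design targets, with site depths
  spreading over roughly 30–170x — and alt reads binomial with success
  probability $0.5\,p\,f + \varepsilon$, where $f$ is the summed mixture
  fraction of carrier clones and $\varepsilon$ (default 0.001) adds stray
  error reads so the germline and negative-sample filters are actually
  exercised;
* an LNM scenario in which the metastatic clone seeds all LNMs but is a
  minor clone in exactly one tumor region, while a nonmetastatic sibling
  clone occupies all tumor regions and no LNM;
* a tree-like validation design in which every sample is a pure draw from
  a distinct subclone, so the induced sample tree and all branch supports
  are known exactly.

All randomness flows from a single seed; identical seeds give
bit-identical cohorts.  Deliberately **not** modeled: copy-number events
and non-diploid states, indels, multi-allelic sites, subclonal copy-state
mixtures, and context-dependent sequencing error.  Passing tests on these
simulations therefore demonstrates correctness of the analysis logic under
the diploid SNV model, not robustness to CNA-driven AF distortion or
FFPE artifacts in real cohorts.

# Numerical and design choices

* Exhaustive search limit 9 samples; larger cohorts (a patient with many
  LNMs can reach 13 samples) use the hill climb, and the pipeline logs the
  fallback.
* Validation problem sizes: perfect-phylogeny recovery uses 6-sample
  cohorts over 100 seeds; search benchmarking uses 50 random matrices per
  size for 3–8 samples; spectrum calibration uses 1,000 replicates of 500
  mutations per group; purity recovery uses purities 0.2–1.0 in steps of
  0.1 with 200 truncal mutations and 50 replicates.
* AF at zero depth is undefined (`NA`), never 0 — a depth-0 cell carries
  no evidence in either direction.
* Binary distance for a pair with no jointly observed cells is missing
  with a warning; average linkage refuses incomplete matrices.
* Mutations with an empty carrier set reaching the tree stage are skipped
  with a warning (they can arise when masking turns all carriers missing).
* Duplicate genes in an annotation list resolve first-wins with a warning;
  unknown genes are flagged `none`.
* Identical-seed pipeline reruns write byte-identical JSON summaries; all
  logging (stage progress, filter counts, timings) goes to stderr and
  never into result files.

# Known limitations

* The compatibility score treats all mutations equally; systematic
  false-negative structure (e.g. one very impure sample) is better
  absorbed by the missing-cell mechanism than by reweighting.
* With 3 areas the paired purity test has a minimum two-sided exact
  p-value of 0.25 — direction is reported, significance needs ≥ 5 pairs.
* The purity estimator assumes diploid heterozygosity; it has no notion of
  LOH, subclonal copy number, or FFPE degradation.
* Hill climbing guarantees only a local optimum; the packaged benchmark
  quantifies (but cannot eliminate) the residual risk of missing the
  global maximum on adversarial inputs.
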