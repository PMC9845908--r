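---
title: "Methods: maternal RNA provisioning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maternal RNA provisioning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question and the design

Insect females load maturing oocytes with mRNA and miRNA that direct the
earliest stages of development, before the embryo's own transcription
starts at the maternal-to-zygotic transition (MZT). If females adjust
those provisions in response to internal condition (body/lipid state) or
external cues (time of season, i.e. photoperiod), maternal RNA becomes a
mechanism of maternal effects — for example, of maternally controlled
facultative diapause in solitary bees. The design this package analyzes is
a paired two-tissue layout: each of 22 females contributes one maturing
oocyte and one 24-h egg (past the MZT), spread over the four cells of a
season (early/late) by condition (control/poor) factorial with cell sizes
6/4/6/6, nesting in two cages. Effects present in oocytes but absent in
eggs indicate provisioning signals that do not persist past the MZT.

`matprov` implements the full statistical path of such a study —
expression filtering, TMM normalization, moderated differential expression
(DE), weighted coexpression modules with module–trait correlation,
cross-tissue module correspondence statistics, miRNA locus curation, and
consensus target / ortholog calling — together with a synthetic-data
generator that emulates the design with known ground truth, so every stage
is testable without the original sequencing data.

# Count model and normalization

Counts are modeled as negative binomial with gene-wise log-normal baseline
means and a common dispersion. Before any inference, features are filtered
by the standard CPM rule: a feature is kept when its CPM reaches the
cutoff implied by `min_count = 10` reads in the median-sized library in at
least *k* samples (*k* = the smallest group size), and its total count
reaches `min_total = 15`. Library composition is corrected with the
trimmed mean of M-values (TMM): per sample versus a reference (the sample
whose upper-quartile CPM is closest to the mean upper-quartile; ties to
the first sample), per-feature log-ratios M and mean log-abundances A are
formed over features positive in both libraries, the extreme 30% of M and
5% of A on each tail are trimmed by rank, and the surviving M-values are
averaged with inverse asymptotic-binomial-variance weights; factors are
rescaled to geometric mean 1. Expression is then carried as
`log2((count + 0.5) / (lib * factor + 1) * 1e6)`.

The TMM estimator is implemented from its definition and cross-checked in
the test suite against `edgeR::calcNormFactors` on random matrices (they
agree to 1e-10). One property worth stating precisely: because the
precision weights depend on depth, TMM is not *exactly* invariant to
scaling one sample's counts by a constant — the factor shifts by a
fraction of a percent. The tests assert the invariance at 0.02 log2 units
rather than machine precision, and assert the exact two-sample pure-depth
case (`B = 2A` gives factors (1, 1)) at machine precision.

# Differential expression

The model is the non-intercept group parameterization `~ 0 + group` over
the four season-by-condition cells, so coefficients are group means and
the contrasts of interest are formed directly:

* condition = (earlyPoor + latePoor)/2 − (earlyControl + lateControl)/2
* season = (lateControl + latePoor)/2 − (earlyControl + earlyPoor)/2
* interaction = (latePoor − lateControl) − (earlyPoor − earlyControl)

Precision weights follow the mean–variance trend: a lowess (span 0.5) of
the square root of each feature's residual standard deviation on its mean
log-CPM, evaluated at each observation's fitted value and raised to the
power −4. With fewer than 10 features the trend is not estimable and
equal weights are used with a warning. Weighted least squares, contrast
estimation, and empirical-Bayes moderation are delegated to limma
(`lmFit`, `contrasts.fit`, `eBayes`): the prior (d0, s0²) comes from
moment matching on log residual variances, posterior variances are
(d0·s0² + d·s²)/(d0 + d), and moderated t statistics are referred to
d0 + d degrees of freedom. `fit_moderated()` also accepts an explicit
(d0, s0²) override, which applies the posterior formula directly; the
d0 = 0 limit reproduces ordinary t statistics to 1e-8 and anchors the
tests. BH adjustment is per contrast (not global), matching the way
headline DE counts are reported per contrast at adjusted p < 0.05 and
< 0.1; oocytes and eggs are always analyzed separately, and the paired
structure enters only through the generator's female-level library-size
intercept, not the DE model. Outlier samples are removed via an explicit
drop list (`drop_samples`), a judgment we deliberately do not automate in
the DE branch; the network branch has its own dendrogram-based screen.

Calibration is part of the contract: on a null simulation (2,000 genes,
4 × 5 samples, no planted structure) the fraction of raw p < 0.05 must
lie in [0.035, 0.065] for every contrast, and planted 30-up/20-down
season effects at |log2FC| = 2 must be recovered within ±20% at BH 0.05.

# Coexpression networks and modules

The network is unsigned: adjacency `a = |cor|^beta` with Pearson
correlations on pairwise-complete observations and default soft power
beta = 4. The power scan reports, per candidate beta, mean connectivity
and the scale-free fit index (R² of log10 binned connectivity frequency
on log10 bin centers, 10 bins, sign-flipped when the slope is positive).
The topological overlap matrix is

TOM_ij = (Σ_u a_iu · a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij),

with connectivities excluding the diagonal, and `1 − TOM` is the
clustering dissimilarity.

Module detection is a deterministic variable-height cut of the
average-linkage dendrogram, not a re-implementation of the published
dynamic-hybrid algorithm: the tree is cut at a fraction
`0.95 − 0.1 · deep_split` of its height range (deep split 2 by default,
so 0.75 — over-splitting is intentional, because the eigengene merge step
re-joins fragments of one true module while genuinely distinct modules
stay apart), branches of at least `min_module_size = 30` genes become
candidates, and membership is refined for two passes by topological
connectivity: a gene joins its best candidate module only if its mean TOM
to that module reaches both half the module core's median connectivity
and three times the background (median off-diagonal) TOM. The second
floor dissolves incoherent branches that average linkage chains together
from uncorrelated genes; candidates falling below the minimum size during
refinement are discarded. The contract for this stage is recovery: on the
default synthetic design (five planted modules of 80/70/60/50/40 genes,
22 samples), adjusted Rand index ≥ 0.8 against the planted truth in at
least 80% of 20 seeds.

Eigengenes are first principal components of the per-gene standardized
module submatrix, unit variance, sign-oriented so the mean correlation
with member genes is positive. Modules whose eigengenes correlate above
0.75 (dissimilarity < `merge_cut_height = 0.25`) merge iteratively to a
fixed point. Module–trait association is the Pearson correlation of each
eigengene with 0/1-coded cage, season and condition, with two-sided
p-values from the t transform on n − 2 degrees of freedom and a
significance flag at 0.05.

# Cross-tissue module correspondence

To ask whether oocyte module structure survives into eggs, egg module
labels are first matched against the oocyte reference by a greedy rule:
repeatedly pair the (source, reference) modules with the smallest
hypergeometric overlap p over the shared universe, relabel, and remove
both; ties break toward larger overlap then smaller reference label;
unmatched source modules get fresh labels; label 0 never matches. Greedy
matching mirrors standard practice; an exhaustive assignment search is
used only as a test oracle on toys.

Overlap statistics use one universe for everything: the genes assigned
(label ≠ 0) in **both** partitions by default — the reading of "genes
placed into module assignments" we adopted — with
`include_unassigned = TRUE` available because the alternative reading
(all filtered genes) is defensible; the flag is recorded in the output.
Per module pair we report the overlap count k, the overlap fraction of
the source module, the upper-tail hypergeometric p `P(X ≥ k)`, and the
representation factor `k·N/(n_source·n_target)`. Modules of interest
(those significantly tied to season or condition) are additionally tested
against a size-aware bootstrap null: 10,000 draws of module-size gene
sets without replacement from the universe, with the empirical p the
fraction of draws whose target-module proportion **strictly exceeds** the
observed one (per the procedure's definition); zero exceedances are
reported as the upper bound `p < 1/n_iter` rather than zero, and an
optional add-one estimator exists but is off by default. The bootstrap is
validated two ways: against exact enumeration of all draws on universes
≤ 25 (within 3 Monte-Carlo standard errors at 10,000 iterations) and for
calibration (over 200 random partitions the fraction of p < 0.05 must lie
in [0.02, 0.09] — the strict-inequality convention makes the p slightly
conservative, which the band accommodates). A flow summary bins overlap
fractions into the bands <1%, 1–10%, ..., 60–70%, >70% for module-flow
reporting.

# miRNA curation

Candidate precursor–mature records (one row per sample and precursor)
pass curation only if not flagged rRNA/tRNA, with at least 5 reads on
both the mature and star strands, and a hairpin-randomization
(randfold-style) p strictly below 0.05 — the 0.05 boundary itself is
rejected. Novel precursor sequences surviving in any sample are
deduplicated and appended to the known list (known first, then novel
lexicographically) as the second-pass reference. Precursors with
identical mature sequences merge into one locus when their genomic
intervals overlap by at least 1 bp on the same chromosome and strand,
taking connected components so chains merge transitively; identical
matures at disjoint locations remain distinct loci — this is why a study
can report more distinct miRNAs than unique mature sequences. Intervals
are held as GRanges (1-based closed, the Bioconductor convention;
overlap semantics are identical to any half-open formulation). The locus
count table sums mature counts over merged members and feeds the same
normalization and DE machinery as mRNA.

Homology calls are gapless: the shorter sequence slides along the longer,
the best-identity offset wins, identity is matches over **query** length
(the denominator is a documented choice; alignment-length is the other
reading), and a hit is accepted only when identity exceeds 90%, at most
two positions mismatch, and no mismatch falls in the seed region
(positions 2–7 from the 5' end). Acceptance is symmetric for equal-length
sequences.

# Targets and orthologs

Consensus targets require both predictors: the alignment-based table
(pre-thresholded at score ≥ 140 and energy ≤ −20 kcal/mol) and the
hybridization-based table (energy ≤ −20) with p strictly below 0.01,
intersected at the (miRNA, gene)-pair level (site-level intersection is
the stricter unimplemented alternative). Orthologs are reciprocal best
hits: best = lowest e-value, ties by higher bitscore then lexicographic
subject, pair emitted only when best in both directions and both
e-values pass the cutoff. The printed cutoff "10 × 10⁻⁵" is ambiguous
between 1e-4 and the conventional 1e-5; the default is 1e-5 and the
argument is exposed. Gene-set overlap between predicted targets and DE
sets reuses the hypergeometric machinery and additionally reports the
coverage fraction of the first set found in the second.

# The synthetic-data generator

The generator is the package's test bed and defines the study conditions:

* **Design**: 22 females × 2 tissues, cells 6/4/6/6 (the stage-4 oocyte
  counts of the study design; `samples_per_group` gives a balanced
  alternative), two cages balanced within cells, each female's oocyte and
  egg sharing a library-size random intercept (sd 0.1 on the log scale).
* **Modules**: five planted modules of 80/70/60/50/40 genes. Each module
  has a latent factor per tissue; member genes load on it with Gaussian
  magnitudes (mean 1, sd 0.3 on the log2 scale) and balanced random
  signs. The signs matter: modules contain both positively and negatively
  responding genes (what an unsigned network presumes), and sign balance
  prevents a planted module from dragging the whole library composition
  with it, which at a few hundred simulated genes would induce spurious
  anti-correlation across the background. Modules 1–3 are season-coupled:
  their factors are built with exact sample correlation r = 0.6 against
  the season coding.
* **Cross-tissue map**: fractions 0.519/0.451/0.652 of modules 1–3 are
  re-assigned together into egg module 1 — the planted analogue of three
  season-linked oocyte modules converging into one large egg module —
  while modules 4–5 carry 80% of their genes into egg modules of their
  own; unmapped genes dissolve into the egg background.
* **Noise**: NB dispersion 0.1 for mRNA (0.2 for miRNA mature counts),
  gene baselines log-normal (log2 sd 1.5), library sizes log-normal with
  log-mean log(2e7) per tissue (the scale of a typical deeply sequenced
  bulk library) and sd 0.15. A fraction 0.3 of the unstructured genes is
  "silent" (baseline shifted down 8 log2 units), so the expression filter
  retains roughly 70% of genes — the band seen in real oocyte/egg data —
  instead of trivially keeping everything.
* **Planted effects**: 30 up- and 20 down-regulated season genes in
  oocytes at |log2FC| = 2 (drawn from the unstructured background so DE
  truth and module truth never overlap), and 2 up- / 11 down-regulated
  season miRNA loci at |log2FC| = 1.5 in oocytes; eggs carry no planted
  effects, mirroring the contrast between the two tissues.
* **miRNA complications**: 75 final loci with 3 duplicate-mature disjoint
  pairs (75 loci over 72 unique matures), 5 loci split over two
  overlapping precursors that must merge back, and 15 precursors designed
  to fail each curation rule in turn.
* **Reproducibility**: all randomness flows from one master seed; each
  table seeds its own stream via a label hash (`substream_seed`), so any
  table can be regenerated alone, and identical seeds give bit-identical
  output.

What the generator does **not** emulate: sequence-level realism (reads,
quality scores, mapping ambiguity), gene length effects, correlated
dispersions, batch structure beyond cage, overlap between DE and module
membership, or modules with non-factor (e.g. banded) covariance. Passing
the recovery suites therefore shows the statistical machinery is correct
and calibrated under the stated model — not that any particular real
dataset satisfies that model.

# Numerical choices and problem sizes

Scale matters for the network stage (the TOM is cubic in gene count), so
the validation suites run at reduced gene counts while keeping the design
fixed: module recovery uses 500 genes (the five planted modules plus
background) and 22 samples over 20 seeds; DE calibration and recovery use
2,000 genes; the workflow under `analysis/` runs at 2,500 genes; library
sizes are scaled with gene count to hold per-gene coverage realistic.
Bootstrap checks use 10,000 iterations against enumeration and 2,000
iterations per replicate in the 200-replicate calibration. The
end-to-end driver (`run_pipeline`) re-run with one configuration must
reproduce every numeric output byte-for-byte; only the run log, which
carries wall-clock timestamps, is exempt.

Other deliberate numerics: correlations use pairwise-complete
observations; constant genes are removed before network construction
(`good_genes_filter`) and constant traits yield missing correlations with
a warning rather than errors; module labels are ordered by decreasing
size with 0 reserved for unassigned genes; every greedy loop has a
deterministic tie-break (documented at the function) so all outputs are
reproducible; sample outliers are flagged as dendrogram singletons
joining strictly above the 0.99 quantile of merge heights.

# Known limitations

The branch cut is a deliberate simplification of dynamic tree cutting;
its contract is recovery on latent-factor modules, and strongly nested or
overlapping module structures may be handled differently than the
published hybrid algorithm would. Cage enters only as a trait
correlation, not as a random effect in the DE model. The bootstrap null
conditions on module sizes but not on any covariate structure among
genes. The homology rule is gapless by construction and will reject true
homologs whose alignment requires an indel.
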