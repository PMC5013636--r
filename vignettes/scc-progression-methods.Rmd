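---
title: "Methods: cross-species genomic analysis of squamous cell carcinoma progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species genomic analysis of squamous cell carcinoma progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Cutaneous squamous cell carcinoma (cuSCC) develops from chronically
sun-exposed "normal" skin (NS) through a preneoplastic intermediate, the
actinic keratosis (AK); UV-driven mouse models recapitulate the sequence as
chronically irradiated skin (CHR) → papilloma (PAP) → SCC. `sccprogress`
implements, as reusable and tested components, the statistical machinery
needed to characterize that progression across species from somatic variant
lists, bulk RNA-seq count matrices, small-RNA profiles and survival tables:

1. mutation-spectrum statistics (96-class catalogues, per-Mb loads,
   recurrently mutated genes, within-patient site overlap);
2. non-smooth NMF deconvolution of mutation catalogues into sparse
   signatures, plus exposure refitting;
3. a per-gene linear mixed-effects progression classifier with one-to-one
   homolog intersection across species;
4. ranked-list gene-set enrichment, transcription-factor target concordance
   filtering and co-target networks;
5. miRNA quantification and miRNA–mRNA anti-correlated functional pairs;
6. z-score-sum expression signatures with quartile log-rank survival tests.

Because the underlying patient exomes are protected and the expression data
live in external repositories, the package ships a seeded synthetic-data
generator that emits every input type *with ground truth*, so each stage is
testable end to end. This vignette records the models, the parameter
choices, and the design decisions taken where the methodology left choices
open.

# Synthetic data: what it emulates and what it does not

`sim_config()` fixes the study-shaped defaults. The mutation generator
mirrors the targeted cohort design: three lesion classes with mean somatic
variant counts 372 (NS), 1,186 (AK) and 2,927 (SCC), six patients with
complete lesion sets, and a callable footprint of 64.05 Mb (the footprint
implied by 2,927 variants at 45.7 per Mb; it is a configuration scalar, and
`mutation_load()` always takes the footprint as an explicit argument).
Per-sample totals are Poisson around the class mean by default: the class
mean is the parameter of record, and over-dispersion is available through
`count_dispersion` (negative binomial with variance $\mu + a\mu^2$) for
users who want the wide per-patient ranges seen in real cohorts. Mutation
contexts are drawn from a known signature mixture (`truth_signatures`,
`truth_exposures`) and placed at positions of a uniform-random 1-Mb
reference whose trinucleotide matches the drawn context on either strand,
without position reuse within a sample; placement failures error rather than
silently bias the spectrum. Within a patient, a fraction
`shared_clone_fraction` (default 0.003, matching the near-chance overlap
scale of the cohort the defaults mimic) of each later lesion's variants is
copied site-identically from earlier lesions, which is what the overlap
statistics are meant to detect. Variant allele frequencies are Beta draws
whose shapes shift toward higher values in later classes, emulating
increasing clonality; they are descriptive only and carry no ground truth.

The expression generator plants *early* genes (shift at NS→AK, persisting),
*late* genes (shift only at AK→SCC) and *stepwise* genes (both transitions)
with per-transition effect `effect_size_log2` and random sign, on top of
subject random intercepts (`subject_sd`, log2 units), per-gene signed batch
shifts, and negative binomial counts (dispersion 0.1). Truth labels are
concordant for the one-to-one homolog fraction (default 0.8); the remainder
is split between many-to-many groups and unmapped genes to exercise the
homolog filter. The miRNA generator perturbs a subset of miRNAs
monotonically across stages and moves each mapped target oppositely with
probability `penetrance`. The survival generator draws exponential event
times with rate $\exp(\beta \cdot z)$ where $z$ is the standardized
z-score-sum signature score, so `hazard_coef` is the log hazard ratio per
score standard deviation; censoring is independent with probability
`censor_rate` at a uniform time before the event.

What the generators do *not* emulate: sequencing reads and their error
modes, alignment and calling artifacts, copy number, isoform structure,
cellular heterogeneity, or dose–response to UV. Passing tests therefore
demonstrate the correctness and calibration of the statistical machinery
under its stated model, not robustness to upstream artifacts.

# Mutation spectra

Catalogues follow the standard pyrimidine-centric 96-class layout
(`sbs96_classes()`): six substitution types × 16 flanking contexts, with
purine-reference calls reverse-complemented. Adjacent same-sample SNVs are
collapsed into dinucleotide records before spectrum summaries
(`collapse_dnps()`); runs of three or more merge left-to-right into a single
left-anchored multi-nucleotide record — the convention adopted here, since
only pairwise collapsing is standard. CC→TT classification requires both
positions to be C>T on the pyrimidine-annotated strand (GG→AA counts via its
reverse complement); with zero dinucleotide variants the CC→TT fraction is
reported as undefined (`NA`), never as 0. Site overlap is keyed on
(chromosome, position, alternate allele) — the reference allele is implied
by position — and duplicated lesion classes within a patient (e.g. two
carcinomas) contribute each pairwise combination, flagged. Cohort means
average over the observed sample pairs. The gene filter retains genes
recurrently mutated in at least `min_pairings` (default 7) tumour/control
pairings that are either previously implicated (an input gene list) or
carry a COSMIC-recorded mutation count strictly above `cosmic_threshold`
(default 400); the COSMIC count is interpreted as the total recorded
mutation count for the gene, and missing annotations are treated as 0 with
a message.

# Non-smooth NMF

The deconvolution model is $X \approx W\,S(\theta)\,H$ with $S(\theta) =
(1-\theta)I + (\theta/k)J$. The smoothing matrix absorbs noise: because any
uniform component of a signature can be represented through $S$, the
multiplicative updates drive both $W$ (signatures) and $H$ (exposures)
toward sparseness as $\theta$ grows. $\theta$ defaults to 0.5 and is
recorded in the fitted object; $k$ is caller-supplied (model-order selection
is out of scope).

Updates are multiplicative Kullback–Leibler rules applied with the smoothed
partner matrix (update $H$ against $W S$, update $W$ against $S H$), with
$W$ kept column-stochastic at every sweep. Since $S$ is doubly stochastic,
$\mathbf{1}^\top W = \mathbf{1}^\top$ implies $\mathbf{1}^\top WS =
\mathbf{1}^\top$, which makes the constrained model the probabilistic form
of KL-NMF; each conditional update is then an EM M-step, the divergence is
non-increasing (asserted with slack $10^{-8}$), and the reported
normalization is exact rather than a post-hoc rescale that would perturb
the reconstruction. An $\varepsilon$-floor of $10^{-12}$ guards the
divisions. Defaults: 10 random restarts (best final divergence kept),
convergence at relative divergence change below $10^{-6}$, at most 2,000
sweeps. Exposure refitting (`fit_exposures()`) minimizes KL divergence (or
squared error) against a fixed basis and returns proportions; evaluation
matches estimated to true signatures by greedy maximum-cosine pairing,
which is adequate for the well-separated bases used in testing. One caveat
worth knowing: a *uniform* signature cannot be recovered sparsely at
$\theta > 0$, because the smoothing term itself explains it — the
four-signature synthetic basis therefore uses peaked processes, as real
signature catalogues are.

# Expression processing

Normalization is the median-of-ratios scaling-factor method, rescaled to
geometric mean 1, with a total-count fallback (warned) when no gene is
expressed in every sample. The variance-stabilizing transform of the
original count-model machinery is replaced by the documented stand-in
$\log_2(x/s_j + 1)$: downstream steps depend only on monotone variance
flattening, and the dispersion-trend fitting of a full count model is out
of scope here. Batch correction is a per-gene additive shift on the log
scale equalizing every batch's median to the gene's global median —
"scaled to the same value per gene" is ambiguous between additive and
multiplicative; the additive log-scale shift is chosen because the
transform already lives on the log scale, and the operation is idempotent.
Differential expression between two groups is a Welch t-test on transformed
values (paired mode available), with BH control across genes; this is a
documented stand-in for a negative-binomial Wald test, calibrated (type-I
error ≈ nominal on null data) and powered for the planted effects used in
testing. Clustering uses $1 - r$ (Pearson) distance with complete linkage;
PCA components are oriented so each component's largest-magnitude loading
is positive, making outputs deterministic. The chromosomal-instability
score sums normalized counts over an input CIN70 gene list (shipped as
data by the caller, not embedded), transforms as $\log_2(x+1)$, and adjusts
by least-squares residuals on subject/batch indicator covariates;
rank-deficient designs drop redundant columns with a warning.

# The progression classifier

Per gene, transformed expression is modelled as stage (fixed effect) plus a
subject random intercept, restricted to subjects with complete three-stage
sets and fitted with `lme4`. All three stage contrasts (AK−NS, SCC−NS,
SCC−AK) and their covariance come from a single fit; the derived third
contrast is mathematically identical to refitting with the other reference
level, and the test suite asserts that identity to $10^{-6}$. Fits are
REML, and Wald tests use Student t with the containment denominator degrees
of freedom for within-subject effects, $N - n_{\text{subjects}} -
p_{\text{within}}$ (10 for six subjects × three stages) — the convention of
the classic mixed-model software this analysis models after. The normal
approximation was rejected because at six subjects it is measurably
anti-conservative (a nominal 5% gate firing at ~10% in null simulation),
which would corrupt the designation step. Per-gene fits reuse a template
model via `refit()` for speed (~19 s for 2,000 genes).

Designation: a gene must first pass the gate, nominal $p < \alpha$ (default
0.05, no multiplicity correction at this step) on the full SCC−NS contrast;
it is *early* if the AK−NS contrast is also nominally significant with a
matching sign, *late* if SCC−AK is, *stepwise* if both are, *none*
otherwise. Non-converged or zero-variance genes are excluded (flagged, not
errors). Because the two transition contrasts each correlate 0.5 with the
gating contrast, the expected fraction of null genes designated is ≈1.9%
at $\alpha = 0.05$ even under perfectly calibrated tests — a structural
property of the rule worth keeping in mind when reading designation counts.
The cross-species step is where stringency accrues: after per-species
fitting (never before), calls are merged through a homology map filtered to
exact one-to-one pairs, and a pair is conserved only with identical
designation and coefficient sign in both species; null genes essentially
never survive the intersection (<0.1% in simulation), while strongly
planted genes are recovered at >90%. Signed fold changes are computed in
linear space and in a paired manner — the within-subject ratio of
anti-logged stage means, averaged across subjects — and reported alongside.

Motif overrepresentation reports, per motif target set, the one-sided
Fisher exact p and a Bayes factor comparing a saturated association model
(uniform Dirichlet over the 2×2 cells) with an independence model
(independent uniform Beta priors on the margins); both marginal likelihoods
are closed-form, and the implementation is verified against numerical
integration. The published tool this emulates does not publish its Bayes
factor formula; this conjugate stand-in is reported with the Fisher p
always alongside, and BF > 3 is flagged.

# Enrichment

The ranked-list enrichment score is the standard weighted
Kolmogorov–Smirnov running sum (weight exponent 1 by default; 0 recovers
the unweighted statistic, invariant under monotone score transforms).
Significance uses gene-label permutation — on a fixed ranked list, sample
permutation is not available, so the null redraws member labels — with NES
defined as ES over the mean magnitude of same-sign null scores, add-one
empirical p, and BH q within each direction. Permutation p-values are
verified uniform on random sets and the machinery detects planted
top-decile sets at q < 0.25 with 1,000 permutations.

The transcription-factor concordance filter selects a factor when (i) some
adjacent comparison (NS→AK = early, AK→SCC = late) shows significant
(q < 0.25) target enrichment in the *same direction in both species*, and
(ii) the full NS→SCC comparison is also significant in a direction shared
by both species. The stage label records which adjacent comparison fired
(both ⇒ global); early and late may fire in opposite directions and both
directions are recorded. The co-target network connects selected factors
whose target sets overlap more than chance within the regulated universe
(one-sided Fisher, default threshold $10^{-4}$), with overlap size as edge
weight.

# miRNA functional pairs

Reads shorter than 10 nt, or ending in a single-base homopolymer run of
9 nt or more, are discarded; abundance is parts per million of usable
reads. The read-to-reference matcher is a documented stand-in for
BLAST-based assignment: a read matches a miRNA when it equals the reference
or a prefix of it with at most one mismatch, and multi-matching reads split
fractionally. Differential expression per pairwise stage comparison is a
t-test on $\log_2(\text{ppm}+1)$ with a 1.5× fold-change requirement;
*recurrence* demands significance in at least two of the three comparisons
*with a consistent direction* (the direction-consistency requirement is
this package's choice; recurrence without it would count a miRNA that flips
sign). Functional pairs: for each significant miRNA and comparison, a
one-sided Fisher test asks whether its predicted targets (an input map;
a synthetic seed-match map generator is provided) are overrepresented among
genes moving in the opposite direction (q < 0.25, fold change > 1.25×),
BH-corrected across miRNAs; passing miRNAs are paired with each
anti-directional differentially expressed target, and pairs are ranked by
the number of comparisons in which they are significant. Conservation
requires the same direction pattern in both species after mapping genes
through the one-to-one homolog map and miRNAs through a family-name map.

# Signatures and survival

Cohort signatures are derived at fold change > 2 and nominal p < 0.05,
split into up and down sets. Cohort ranking scores each cohort as
$\sum \text{NES}^2$ over its significant (q < 0.25) signature directions
minus $\lambda$ per non-significant direction; the penalty is exposed as an
explicit parameter with default 0, because the original penalty is
unspecified, and the ranking is invariant to cohort input order. The
survival signature replaces each gene with its within-cohort z-score and
scores each sample as the sum over upregulated genes minus the sum over
downregulated genes (zero-variance genes contribute 0). Samples are sorted
by score with ties broken by sample identifier for determinism; the top and
bottom quartiles are compared with the standard two-group log-rank test
(1 df) and Kaplan–Meier step functions are returned. All-censored input
yields an undefined-statistic sentinel with a message.

# Numerical choices and problem sizes

Tolerances: nsNMF convergence $10^{-6}$ relative, monotonicity slack
$10^{-8}$, $\varepsilon$-floor $10^{-12}$; LME reparameterization identity
asserted at $10^{-6}$; batch-median equality at $10^{-12}$. Tie-breaks:
quartile membership by sample id; signature matching by greedy maximum
cosine; PCA orientation by largest-magnitude loading. Degenerate inputs
(zero catalogues, constant genes, empty target sets, all-censored tables)
return typed sentinels or flags rather than exceptions, as documented per
function.

The test suite exercises the full pipeline at deliberately desk-sized
problems chosen to keep the suite fast while leaving comfortable
statistical margins: signature recovery at $k=4$ with 200 samples × 2,000
mutations; the progression classifier at 2,000 genes × six subjects per
species (planted effects at two log2 units per transition — the strong-
effect regime the recovery claims are stated for); GSEA calibration with
200 random sets; survival power at 100 replicates of n = 200. Seeds are
fixed throughout; every generator is a pure function of its configuration.

# Known limitations

The DE and VST stand-ins are not a count-model pipeline and will differ
from one in power at low counts. The miRNA matcher ignores isomiR
complexity beyond prefix-with-mismatch matching. The Bayes factor is a
conjugate surrogate for an unpublished formula and should be read
comparatively, not as a calibrated posterior odds. Greedy cosine matching
can be suboptimal for highly correlated signature bases. The survival
module implements the two-group log-rank comparison, not Cox modelling,
and the per-species designation step inherits the ~1.9% structural null
rate discussed above.
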