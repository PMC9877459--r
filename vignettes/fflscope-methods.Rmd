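---
title: "fflscope: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fflscope: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fflscope` chains six analysis stages: differential expression with
subtype-exclusivity algebra, PPI hub ranking and module detection,
regulatory-prior filtering with correlation validation, feed-forward-loop
classification, immune signature scoring, and survival stratification.
This vignette records the statistical models behind each stage, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic cohort does and does not emulate.

## Differential expression and exclusivity

Each contrast is a two-group comparison on log2-scale expression with
empirical-Bayes variance moderation. For feature $g$ with pooled sample
variance $s_g^2$ on $d_g$ degrees of freedom, the posterior variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and the moderated t uses $\tilde s_g^2$ with $d_0 + d_g$ degrees of
freedom. The prior $(d_0, s_0^2)$ is fitted by moment matching on the
log sample variances: with $e_g = \log s_g^2 - \psi(d_g/2) +
\log(d_g/2)$, the excess of $\mathrm{var}(e_g)$ over $\psi'(d_g/2)$
identifies $d_0$ through the inverse trigamma (Newton iteration,
relative tolerance $10^{-10}$), and the mean of $e_g$ identifies
$s_0^2$. Zero-variance features are excluded from the fit; an
underdispersed variance distribution yields $d_0 = \infty$ (all features
shrunk to $s_0^2$). Setting $d_0 = 0$ recovers the ordinary
pooled-variance t exactly, which the tests exploit. Only two-group
contrasts are supported — the pipeline never needs a design matrix.

DEG calling is deliberately literal about its boundaries: strict `<` on
the BH-adjusted p (0.05 for mRNA, 0.1 for miRNA) and inclusive `>=` on
|log2FC| (1 for mRNA, 0.58 for miRNA). Exclusivity is a set difference
of gene lists: a gene differentially expressed in *any* comparator
subtype, in *either* direction, is disqualified. The direction-agnostic
rule is a documented assumption, not an inference — Venn-style
intersection tools operate on unsigned gene lists — and a reader who
wants direction-aware exclusivity can intersect the per-direction calls
directly. Well-differentiated carcinoma and adenoma comparators are
merged by unioning their DEG *sets* (never their samples) before
subtraction. Batch handling is limited to optional per-batch median
centering (`batch_center`); full empirical-Bayes batch correction is out
of scope.

## PPI hubs and modules

Edges are kept at confidence strictly above 0.4 (the conventional
medium-confidence cut). Maximal clique centrality is
$\mathrm{MCC}(v) = \sum_{C \ni v} (|C|-1)!$ over exact maximal cliques;
a node whose only maximal clique is itself scores $0! = 1$. Enumeration
is exact with exponential worst case, which is acceptable because input
graphs are DEG-sized (at most a few hundred nodes). Ties in the score
are broken by degree and then lexicographic id, so rankings are
deterministic rather than matching any particular GUI plugin's arbitrary
order.

MCODE follows the published three-stage scheme with the published
defaults (vertex weight percentage 0.2, haircut on, fluff off): vertex
weights are the density of the highest k-core of the closed neighborhood
times that core's $k$; complexes grow breadth-first from the
highest-weighted unassigned seed, admitting neighbors with weight above
$(1-\mathrm{vwp})$ of the seed weight; the haircut reduces each complex
to its 2-core. Nodes visited during expansion are treated as assigned
even if the haircut later removes them — this keeps complexes disjoint
and the procedure order-deterministic. Module score is density × size,
with densities computed without self-loops (excluded by construction).

## Regulatory network and feed-forward loops

Prediction priors carry their native evidence scores: TF→gene pairs a
normalized enrichment score (kept at NES strictly > 5.0), miRNA→gene
pairs a supporting-tool count (kept at ≥ 2), with the miRNA additionally
required to be called down in tumor. Every pair surviving the filters is
then validated on expression: Spearman correlation on tumor samples,
with layer-specific retention — miRNA→gene edges must be significantly
*negative* (repression), TF→miRNA edges significantly *positive*, and
TF→gene edges significant with either sign recorded (the network keeps
both repressors and activators; the sign drives loop coherence). The
retention level defaults to 0.05; the package exposes it (`cor_alpha`)
because annotated heatmaps in this literature often mark a weaker
p < 0.1 tier, and whether such pairs belong in a "validated" network is
a judgment call rather than a fact. Correlations default to tumor
samples only — normal-tissue co-variation would mix tissue composition
into the regulatory signal — with an explicit `samples` argument to
override.

A feed-forward loop is any (TF, gene, miRNA) triple with all three edges
present; it is coherent iff the direct sign equals the product of the
indirect signs, $s_{tg} = s_{tm} \cdot s_{mg}$. The classifier is
re-checked in the tests against exhaustive enumeration of all eight sign
patterns. The canonical planted pattern is the repressor loop
$(-1, +1, -1)$: the TF inhibits the gene directly and promotes the miRNA
that also inhibits it.

## Signature and immune scoring

The single-sample enrichment score ranks features per sample
(descending, average ranks for ties; ordering ties broken by feature id
for determinism) and sums, along the ranked list, the difference between
the weighted in-set cumulative (weights $r^{\alpha}$, $\alpha = 0.25$,
normalized to one) and the unweighted out-of-set cumulative. The *sum*
(not the maximum deviation) of the running difference is used. TF, hub
and miRNA signature scores are range-normalized within the scored batch;
stromal and immune scores are left unnormalized, following the
convention of the two-signature purity method, whose cosine calibration
$\mathrm{purity} = \cos(0.6049872018 + 0.0001467884 \cdot
(\mathrm{stromal} + \mathrm{immune}))$ is applied verbatim. That
calibration was fitted on a specific platform, so purity outputs should
be read as "purity (ESTIMATE formula)" rather than an absolute fraction.
Whether signature scores were range-normalized in the motivating
analyses is not stated anywhere; the flag is therefore exposed rather
than hidden.

Group membership is a mean split: `high` iff the score strictly exceeds
the cross-sample mean (an all-equal score vector is thus all-`low`).
Set members absent from a matrix are dropped with a warning and scoring
proceeds on the remainder — mirroring the common situation where a
platform lacks a few signature members — and aborts only when no member
remains.

## Survival

The log-rank statistic is the standard two-group O/E/V chi-square.
The optimal cutpoint scans midpoints between consecutive distinct score
values whose split leaves at least `minprop = 0.1` of samples on each
side, and returns the cutoff maximizing the statistic; ties prefer the
more balanced split, then the lower cutoff. The reported p-value is the
*plain* log-rank p at the selected cutoff: the maximally-selected-
statistic correction is deliberately not applied, matching how such
optimal-cutoff p-values are usually reported, and is flagged here as
anti-conservative. Proportional-hazards fits use Efron tie handling —
the generator produces month-resolution times with heavy ties, where
Efron is markedly more accurate than Breslow — with convergence at
coefficient change below $10^{-9}$ and divergence (|β| > 15) reported as
probable separation. Multivariate rows adjust for stromal score, immune
score and tumor purity.

## What the synthetic cohort emulates

`generate_cohort()` is first-class, tested code, not a fixture. The
default design is the 362-sample combined-cohort configuration (ATC 24,
MTC 54, PTC 142, FTC 22, OTC 8, FTA 27, OTA 16, normal 69) with 2000
genes and 300 miRNAs. Baseline expression is Normal(7, 1) per feature on
the log2 scale with Normal(0, 0.7) noise. On top of that:

* 80 up / 20 down MTC-exclusive genes with effects uniform in
  [1.2, 2.5] — straddling the |log2FC| ≥ 1 threshold so calling is
  exercised on both sides — plus per-comparator-subtype DEG blocks and a
  small MTC∩ATC overlap block that the exclusivity subtraction must
  remove;
* a 15-gene hub block loaded (1.5) on a latent per-sample factor, with
  its own effect range U[2, 3]: hub genes model the cohort's strongest
  exclusive markers (each should separate tumor from the rest at
  AUC > 0.8 and anchor the top module), and an effect barely above the
  calling threshold would contradict that role;
* a repressor TF (−1.3 on the hub factor, +0.8 on a second factor shared
  with the miRNAs, shifted −1.5 in MTC) and 13 regulator miRNAs (−1.5 on
  the hub factor, +0.6 on the shared factor, −1.5 in MTC), giving the
  planted sign structure: hub–hub positive, TF–hub negative, miRNA–target
  negative, TF–miRNA positive;
* an immune latent factor with correlation −0.8 to the hub factor,
  loading 1.5 on the stromal/immune/TIL/ICG sets. The magnitude is
  chosen so that the designed high-hub ⇒ low-immune contrast is
  detectable by a rank-sum test at n = 54 tumor samples under ordinary
  sampling fluctuation of a latent correlation — a weaker coupling makes
  the designed property of the generator itself unreliable at the
  cohort's size;
* exponential survival with linear predictor $-0.7\,z(\text{hub proxy})
  + 0.7\,z(\text{miRNA proxy})$, uniform censoring (roughly a third of
  subjects), times rounded up to whole months.

All latent factors are centered within each subtype. This is a
deliberate identifiability choice: the planted shifts are the *only*
source of between-group mean differences, exactly as the design
describes, and a chance latent draw cannot move every loaded feature's
fold change in lockstep. Within-group covariation — everything the
correlation-validation and scoring stages measure — is unaffected.

Prior export draws NES in [5.5, 9] for true TF pairs and tool counts in
{2..6} for true miRNA pairs; decoys (default one per true pair) get NES
in [2, 5] and tool count 1, so the standard filters separate them by
construction and the recovery tests measure the *correlation-validation*
stage, not the filters. The PPI export wires the hub block as a complete
subgraph (scores 0.6–0.95) over sparse background edges (0.2–0.9,
straddling the 0.4 cut).

What the generator does **not** emulate: array physics and
normalization artifacts, batch effects, count-based (RNA-seq) mean–
variance relationships, heavy-tailed expression, correlated decoy priors,
and competing risks. Every downstream statistic is rank- or mean-based,
so monotone structure is what matters; passing tests demonstrate that
the pipeline recovers planted monotone structure at realistic noise, not
that it is robust to raw-data pathologies upstream of its inputs.

## Problem sizes and determinism

The test suite runs oracle-equivalence checks (exact maximal-clique
enumeration vs. MCC on 200 random graphs up to 12 nodes; rank-sum
enumeration, step-up BH, O/E/V log-rank, running-sum ssGSEA, pairwise
AUC), boundary checks on every stated threshold, and recovery suites on
the full default cohort: 20 seeds for regulatory-edge and loop recovery,
50 seeds at n = 500 for proportional-hazards parameter recovery, and a
single seeded cohort for exclusivity and immune-direction checks. These
sizes keep the default suite comfortably within a few minutes on one
core while leaving the binomial pass criteria (≥ 90% of seeds)
meaningful. Every stochastic step is seed-driven; identical
configuration and seed reproduce every output table byte for byte.

## Known limitations

* The moderated-t prior fit assumes a common $d_g$ across features
  (complete two-group data); features with missing values get pairwise
  means but share the pooled-variance machinery.
* Spearman p-values use the t-approximation uniformly; exact permutation
  p-values for tiny n are not implemented, and |rho| = 1 reports the
  smallest representable tail.
* The optimal-cutpoint p-value is anti-conservative (see above).
* MCC and MCODE are exponential-worst-case exact algorithms; graphs far
  beyond DEG scale (thousands of nodes, dense) are out of design range.
* Purity values inherit the platform assumptions of the published cosine
  calibration.
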