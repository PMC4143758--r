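---
title: "Trio-SVM: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-SVM: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(triosvm)
```

## The model

`triosvm` tests, gene by gene, whether the rare variants (RVs) a child
received deviate from Mendelian expectation differently in affected and
unaffected children. The unit of analysis is the trio: a phenotyped child
with both parents genotyped.

**Transmission encoding.** At site $j$, with parental rare-allele counts
$f_j, m_j \in \{0,1,2\}$ and child count $c_j$, the feature is
$$x_{ij} = c_j - \tfrac{f_j + m_j}{2},$$
the observed minus the Mendelian-expected transmission. Conditional on the
parents, $E[x_{ij}] = 0$ under the null in every population stratum — the
family-based association test (FBAT) conditioning device. Only matings
with at least one heterozygous parent are informative; the scores live in
$\{-1, -\tfrac12, 0, \tfrac12, 1\}$. Sites whose score column is constant
across the analyzed trios ("noninformative", which subsumes sites at which
no rare allele was observed) are removed, and the removal is counted in
the QC output. For unrelated case-control samples the analogous encoding
is the raw rare-allele count (`case_control_encode()`).

**Classifier.** Affected children are labeled $y=-1$, unaffected $+1$. A
soft-margin SVM is trained in its dual form with the Gaussian kernel
$K(x, x') = \exp(-\lVert x - x'\rVert^2 / 2\sigma^2)$; the box constraint
$0 \le \alpha_i \le C$ encodes the misclassification penalty. The dual is
solved by sequential minimal optimization (SMO) over maximal violating
pairs, implemented in C++; the offset $b$ is the mean of
$y_s - \sum_i \alpha_i y_i K_{is}$ over unbounded support vectors, falling
back to the midpoint of the feasible KKT interval when every support
vector is at a bound. Because the kernel maps each variant through its own
coordinate nonlinearly, risk and protective variants both contribute;
their effect directions need not align.

**Test.** The composite score of child $i$ is
$f(x_i) = \sum_s \alpha_s y_s K(x_s, x_i) + b$. Scores are oriented
(negated) so that stronger distortion in affected children maps above 0.5,
and the gene's statistic is the Mann–Whitney AUC $\hat\theta$ comparing
affected with unaffected scores, ties counted one half. The hypothesis
$H_0{:}\ \theta \le 0.5$ vs $H_a{:}\ \theta > 0.5$ is tested one-sided with
$z = (\hat\theta - 0.5)/\mathrm{SE}(\hat\theta)$, asymptotically standard
normal, with the DeLong placement-variance SE. The statistic is centered
at the null value 0.5: published AUC/SE/p triples (e.g. 0.637, 0.040
$\to$ 3.2e-4) are reproducible only with the centered form, which the test
suite checks as a worked example. DeLong rather than Hanley–McNeil because
it is distribution-free and matches the reported SE magnitudes
($\approx 0.04$ at 66 cases / 209 controls).

## Which scores carry the test: a measured design decision

The natural-looking choice — score every trio out-of-fold with 5-fold
cross-validation and test the pooled AUC — is **miscalibrated**. In null
simulations at the reference condition (below), the pooled 5-fold CV AUC
has standard deviation 0.051–0.057 while its DeLong SE is 0.041, giving a
type I error of 0.14 at $\alpha = 0.05$ with a *fixed* penalty, and 0.21
when C is additionally chosen to maximize that same CV AUC. The excess
variance is not a fold artifact: per-fold centering, per-fold AUC
averaging, score averaging over repeated CV partitions, and even a 2-fold
swap with disjoint training halves all remain inflated (0.08–0.14).
The root cause is that out-of-fold scores are functions of the *other
trios' labels*, so scores are mutually correlated in a way the DeLong
variance (which assumes independent scores) cannot see. A control
experiment scoring each replicate with a model trained on an independent
replicate is exactly calibrated (0.050 at 200 replicates), isolating the
mechanism.

`gene_test()` therefore uses **split-sample evaluation**: the trios are
split into stratified halves keyed to trio ids; the penalty is selected by
stratified 5-fold cross-validated AUC *within the training half*; the
final model is fit on the training half; and the AUC test uses only the
held-out half, whose labels never touch any fit. Conditional on the
training half, the evaluation scores are independent and the DeLong z-test
applies exactly; a 1000-replicate null run gives rejection 0.052 at
$\alpha = 0.05$ and mean AUC 0.4986. Penalty selection by CV AUC cannot
bias the test because it never sees evaluation labels. The price is that
the model is fit on half the trios and the AUC is estimated on the other
half; the reported `n_case`/`n_control` are the evaluation-half counts.
`resubstitution = TRUE` exposes the optimistic alternative (full-data
refit scored on its own training rows) for comparison only.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `sigma2` | 1 | Gaussian kernel scale $\sigma^2$; transmission scores share the $[-1,1]$ scale by construction, so features are not standardized and a unit scale is appropriate |
| `penalty_grid` | 1–10 (integers) | candidate box penalties C; exact ties in CV AUC break toward the smallest C |
| `folds` | 5 | stratified CV folds for penalty selection; fold membership is a deterministic hash of (trio id, seed), so it is reproducible and invariant to row order |
| `maf_threshold` | 0.01 (file pipeline), 0.03 (simulations) | sites enter when $0 < \mathrm{MAF} <$ threshold; MAF is computed on founders by default to avoid double-counting transmitted alleles |
| `seed` | 1 | keys the fold hash and the half split |

## The simulator and what it does (not) emulate

`sim_config()` defaults define the reference study condition used by the
calibration experiments and the acceptance script: a 50-site gene with
per-site MAF uniform on $[0.001, 0.03]$, Hardy–Weinberg parents, Mendelian
transmission (each parent transmits the rare allele with probability
count/2), a logistic disease model on the child's causal-allele counts
with baseline prevalence 0.2, and ascertainment into 66 affected-child and
209 unaffected-child trios. Causal effects default to alternating
$\pm 2$ log-odds per rare allele — large per-allele effects carried by a
handful of rare sites with mixed directions, the regime the method
targets; the power experiments use 16/51 quotas (67 trios at the ~1:3
case:control ratio) before bootstrap resampling to 500 and 1000 trios.
Bootstrap resampling preserves each trio's label and gives resampled
trios fresh ids, so class proportions match the source in expectation.

The simulator intentionally does **not** reproduce: multigenerational
pedigrees with long-range within-pedigree LD (in real pedigree data trios
are *not* independent, and RVs riding a causal common haplotype can
produce false positives — treat significant genes in pedigree data with
that caveat in mind); between-site LD; quantitative traits with
longitudinal measurements and covariate adjustment; or genotype
imputation error. Passing calibration here therefore shows the statistic
behaves correctly for independent trios, not that pedigree LD artifacts
are handled.

Experiment sizes used by the test suite and acceptance script — 200 null
replicates for calibration, 100 replicates per power condition — give
Monte-Carlo standard errors of about 0.015 and 0.04 on a rejection rate
near 0.05 and 0.5 respectively.

## Numerical choices and degenerate inputs

* SMO stops when the maximal KKT violating-pair gap is below `tol`
  (default $10^{-6}$), iteration cap $10^5$; the attained dual objective
  matches a generic interior-point QP solver to $10^{-6}$ relative on
  random small instances in the test suite.
* Kernel matrices are symmetrized and given an exact unit diagonal;
  negative squared distances from floating cancellation are clipped at 0.
* Missing child or parent genotype at a site, and Mendelian-inconsistent
  trio-site combinations (child count outside the transmissible range),
  are scored 0 (uninformative) and counted in the QC report rather than
  treated as fatal — imputed pedigree data contain such records.
* Monomorphic sites are excluded even below the MAF threshold; a
  multiallelic site is dropped with a warning (the encoding is biallelic).
* Perfect separation or all-tied evaluation scores give SE $= 0$; the
  asymptotic test is then undefined and the gene is reported with an `NA`
  p-value and reason `degenerate_se` rather than $p = 0$.
* Children sharing parents each form their own trio, treated as
  independent; no deduplication of half-siblings is attempted.
* No multiple-testing correction is applied across genes; the file
  pipeline logs a note when more than one gene is tested.

## Known limitations

**Stratification robustness is partial.** FBAT conditioning makes every
site's conditional *mean* zero in every stratum, so mean-based burden
statistics are immune to population structure. A Gaussian-kernel SVM,
however, also sees the per-row score *variance*, which tracks parental
heterozygosity and hence stratum allele frequencies. When strata differ in
both MAF and disease prevalence, case status correlates with score
variance and the classifier finds real — but non-causal — separation. In
the package's two-subpopulation stress test (MAF $\times 3$, baseline
log-odds $+1$), the null rejection rate rises to about 0.14 at
$\alpha = 0.05$ with mean AUC 0.52. This is a property of the method, not
of the implementation; the corresponding acceptance check is expected to
fail and is retained as a regression marker of the limitation. With equal
prevalences (or equal MAFs) across strata the test stays nominal.

**Pooled-CV AUC inference is invalid** (see the design-decision section);
anyone extending the package should resist reverting to it.

**Power at small trio counts is modest**: with 67 trios the evaluation
half holds only ~8 cases. The bootstrap route to 500–1000 trios restores
power but, because resampled copies of one source trio can land in both
halves, bootstrap power estimates are optimistic relative to truly larger
samples; they are used for qualitative trend checks only.
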