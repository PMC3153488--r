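---
title: "Control-marker-corrected association testing: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-marker-corrected association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmassoc)
```

## The problem

LD-based association mapping infers that a marker is near a
trait-affecting locus from the correlation between marker genotype and
phenotype. When the sample pools subpopulations with different allele
frequencies *and* different trait means, that correlation acquires a
component that has nothing to do with physical linkage: every marker
whose frequency differs between subpopulations correlates with ancestry,
and ancestry correlates with the trait. `cmassoc` implements a
regression analysis that removes this spurious component locally, using
a single *control marker*, without estimating the population structure
itself.

## Model and assumptions

The population is an instant admixture of two randomly mating
subpopulations in proportions $m$ and $1-m$. Three biallelic loci enter:
a QTL (allele A, frequency $q^{(i)}$ in subpopulation $i$) with
genotypic values $d$, $h$, $-d$ for AA, Aa, aa plus
$\mathcal N(0,\sigma^2)$ residuals; a test marker (allele T, frequency
$p^{(i)}$, score $X \in \{0,1,2\}$) in within-subpopulation LD $D^{(i)}$
with the QTL; and a control marker (frequency $c^{(i)}$, score $Z$)
assumed to be in linkage equilibrium with both other loci *within* each
subpopulation. Within a subpopulation the joint marker–QTL genotype
distribution is the product of gamete probabilities with
$Q = P(T\mid A) = (pq + D)/q$ and $R = P(T \mid a) = (p(1-q)-D)/(1-q)$
(`joint_genotype_distribution()`); all mixture moments follow in closed
form (`mixture_moments()`) and every closed form in the package is
tested against brute-force enumeration of this distribution.

Key identities (all exact, not approximations):

* mixture LD: $D_{mix} = mD^{(1)} + (1-m)D^{(2)} + m(1-m)\delta_T\delta_Q$
  with $\delta_T = p^{(1)}-p^{(2)}$, $\delta_Q = q^{(1)}-q^{(2)}$;
* covariance decomposition:
  $\mathrm{Cov}(X,Y) = \sum_i w_i\, 2D^{(i)}(d + (1-2q^{(i)})h) +
  2m(1-m)\delta_T(\mu_1-\mu_2)$, genuine plus spurious;
* control-marker signal: $\delta = \mathrm{Var}_{obs}(Z) - 2\bar c(1-\bar c)
  = 2m(1-m)\delta_C^2 \ge 0$ — the Wahlund variance excess.

Because the stratification components of $\mathrm{Cov}(X,Z)$,
$\mathrm{Cov}(Z,Y)$ and $\delta$ all factor through the same latent
ancestry indicator, the correction

$$\mathrm{Cov}^* \;=\; \mathrm{Cov}(X,Y) \;-\;
\frac{\mathrm{Cov}(X,Z)\,\mathrm{Cov}(Z,Y)}{2\delta}$$

removes the spurious term *exactly* at the population level:
$\mathrm{Cov}^* = \sum_i w_i \mathrm{Cov}_i(X,Y)$. This identity is the
package's central invariant; the test suite verifies it to $10^{-10}$
over 1000 random parameter draws, and `theoretical_coefficient()` is
defined through it. The corrected slope is $b^* = \mathrm{Cov}^*/
\mathrm{Var}(X)$ — note the denominator is the *mixture* marker
variance, so $b^*$ is a structure-free association signal but not the
within-subpopulation slope (the membership regression targets that
instead, which is why the two methods report different non-null slopes).

## Inference: the standard error of the corrected slope

The sample version plugs in complete-case sample covariances and the
estimated $\hat\delta$. Its t statistic uses $n-3$ degrees of freedom
(one parameter each for intercept, slope and the structure correction).
Two standard errors are available in `fit_corrected()`:

* **`se = "delta"`** (default): a delta-method (influence-function)
  estimate that treats $b^*$ as a smooth function of the five sample
  moments $(S_{xy}, S_{xz}, S_{zy}, S_{xx}, \hat\delta)$ and accumulates
  the empirical influence contributions. It accounts for the sampling
  noise of the correction term itself.
* **`se = "ols"`**: the naive residual-based slope standard error.

The choice matters. Under the built-in strong-structure null (below) at
$n = 200$, Monte Carlo gives $\mathrm{sd}(b^*) \approx 0.125$; the
delta-method se averages the same value and yields a rejection rate of
about 0.04 at $\alpha = 0.05$, while the naive OLS form averages
$\approx 0.11$ and inflates the type-I error to about 0.08. Calibration
under stratified nulls is the criterion by which the default was fixed;
the OLS form is retained because it is the conventional formula and
useful for comparison. The same applies to power prediction:
`predict_power_for_spec(method = "corrected")` uses the exact asymptotic
variance of $b^*$, computed by enumerating the expectation of the
squared influence function over the joint $(X, G, Z)$ distribution, so
that predicted and empirical power refer to the same test.

`fit_simple()` and `fit_structured()` use the classical least-squares
standard errors ($n-2$ and $n-3$ degrees of freedom): those estimators
are linear model fits and need no such adjustment.

### The δ gate

The correction divides by $\hat\delta$, whose population value is
nonnegative but whose estimate under weak structure can be small or
negative. `fit_corrected()` therefore requires
$\hat\delta > k\,\widehat{SE}_{jack}(\hat\delta)$ (default $k = 2$,
jackknife over individuals computed in $O(n)$). Below the gate the
control marker carries no usable signal: the fit raises a typed error
(`cmassoc_no_structure_signal`), or with `fallback = TRUE` degrades to
the simple regression with a warning — appropriate because an
undetectable $\delta$ means undetectable structure. A negative
$\hat\delta$ is never used as a divisor. Control markers with small
subpopulation divergence genuinely degrade the analysis (false positives
and lost power), which is why `select_control_marker()` maximizes
$\hat\delta$ over the screened candidates and why practice should prefer
strongly divergent control markers.

## Power prediction

Power of the slope t-test is $P(|T'_{v,\lambda}| > t_{\alpha/2,v})$ with
$v = n-3$. The noncentrality is
$\lambda = b\sqrt{n\,\mathrm{Var}(X)/\sigma^2_{\mathrm{eff}}}$ times, in
the default `"gamma"` form, the moment-matching factor
$\sqrt{2/v}\,\Gamma(v/2)/\Gamma((v-1)/2)$, which makes
$E[T'_{v,\lambda}]$ equal the expected t ratio; it is below 1 and
vanishes as $v \to \infty$, and `ncp_form = "asymptotic"` omits it. The
$v = n - 3$ convention is applied uniformly across methods (for the
simple regression the test itself uses $n-2$; the difference is
negligible at the sample sizes where power analysis is meaningful).
Invariants: power $= \alpha$ exactly at $b = 0$ and is monotone in $|b|$
and $n$.

## The simulator and the scenario library

`simulate_admixed_sample()` draws each individual's origin
Bernoulli($m$), its (QTL, test-marker) genotype from the exact two-locus
distribution of that subpopulation at the haplotype level, its control
genotype Binomial(2, $c^{(i)}$), and its trait as genotypic value plus
Gaussian noise. `simulate_marker_panel()` extends this to many loci as a
Markov chain along haplotypes with exact adjacent-locus LD.
`run_replicate_study()` splits one study seed into per-replicate seeds
by counter, so studies are reproducible and the replicate stream is
independent of which methods are requested. The latent QTL genotype is
never passed to the association fits — they see only $X$, $Z$, $Y$ and
membership, as in real use.

The built-in library (`default_scenarios()`) fixes the study conditions
used throughout validation: $n = 200$, $m = 0.5$, $d = 1$, $h = 0$,
$\sigma^2 = 1$, subpopulation frequencies $0.5 \pm \delta/2$ with
$\delta \in \{0.2, 0.4, 0.6\}$ and within-subpopulation
$D \in \{0, 0.05, 0.08\}$: four stratified nulls, five non-null
scenarios, and a strong null with reversed effect sign. The control
marker is fixed at $c = (0.8, 0.2)$ in all scenarios because the
analysis selects the *maximum-delta* candidate, so the realistic
operating point is a strongly divergent control; dominance defaults to
zero in the library (the machinery supports $h \ne 0$ throughout).
"Strong structure" (the $\delta = 0.6$ null) is the default calibration
scenario. What the simulator does *not* emulate: genotyping error,
missingness mechanisms, cryptic relatedness, more than two source
populations, multi-QTL traits, or LD decay along real recombination
maps — so passing tests establish correctness under the model's own
assumptions, not robustness to these violations.

## Hardy–Weinberg diagnostics

Merging divergent subpopulations produces a genome-wide heterozygote
deficit (Wahlund effect). `hwe_tests()` provides the 1-df Pearson
chi-square against HWE expectations at the sample allele frequency and
the conditional exact test (enumeration of heterozygote counts given the
allele counts, summing probabilities no larger than the observed
configuration's — the standard exact HWE formulation, chosen because
only the test's name, not its formulation, is conventionally specified).
`genomewide_hwe_scan()` applies either test per marker at the
Sidak-corrected threshold $1-(1-\alpha)^{1/n_{tests}}$ over the markers
actually tested; monomorphic markers report $\chi^2 = 0$, $p = 1$ and
are flagged. In validation, a merged sample of two simulated
subpopulations with frequency divergence 0.5 across 1000 markers yields
hundreds of violators while each unmixed subpopulation yields about the
family-wise expected count (≈ 0.05).

## eQTL scan definitions

`scan_trait()` fits one marker at a time (complete-case per marker),
aligning samples strictly by id and reporting unfittable markers with a
reason. For the corrected scan with `control = "auto"`, candidates are
ranked once by $\hat\delta$ and each test marker uses the best-ranked
candidate on a *different* chromosome. `call_peaks()` defines an eQTL as
an independent peak in the per-chromosome p-value profile: every
significant marker seeds a peak and peaks are merged by single-linkage
chaining at 5 Mb (a significant marker joins a peak if it is within 5 Mb
of any member). Seeding from every significant marker rather than local
maxima is the more direct reading of "independent peak"; since distinct
merged peaks are necessarily > 5 Mb apart, the operation is idempotent
and order-invariant. The peak location is the member with the smallest
p-value, ties broken to the lowest position. `classify_cis_trans()`
calls a peak cis when any member lies within 500 kb upstream of the
transcript start to 500 kb downstream of the 3′ end, resolved by strand
(for minus-strand transcripts upstream means higher coordinates; with
the default symmetric windows the strand does not change the interval,
but asymmetric windows are supported and strand-aware). Default scan
significance is family-wise $\alpha = 0.05$ Sidak-corrected over all
markers × traits actually tested; per-trait correction is available
(`--correction-scope per-trait` in the CLI). Coordinates are 1-based
inclusive throughout; BED annotation is converted on input.

## Numerical and interface conventions

* Missing data: complete-case per fit (pairwise for simple, triple-wise
  for corrected); `n_used` is always reported.
* Monomorphic test markers and $n$ below the minimum are errors, not NA
  results; scans convert them to `status` flags.
* Degenerate fits (zero residual variance) report $p = 1$ when $b = 0$
  and the smallest positive double otherwise, keeping $p \in (0, 1]$.
* Genotypes are counts of the file-declared allele (ALT for VCF, as
  coded for TSV); the counted allele is kept in the provenance record
  because the slope's sign depends on it.
* Sample variance uses the $n-1$ denominator everywhere, making the
  observed control-marker variance an unbiased estimator of its
  population value.
* Tie-breaks are deterministic: control-marker selection by lowest
  chromosome then position then id; peak location by lowest position.

## Validation problem sizes

The test suite checks: exactness of the correction (1000 random
scenarios, tolerance $10^{-10}$); type-I calibration (1000 replicates of
the strong-structure null at $n = 200$, 99% binomial band around 0.05,
with the simple method's rate required to exceed 0.5); power agreement
(five scenarios × 500 replicates vs the noncentral-t prediction within
3 binomial SE); consistency of all three estimators at $n = 50{,}000$
(within 3 SE of their theoretical slopes); Wahlund diagnostics on 1000
markers; and the peak/window definitions on constructed fixtures. The
replicate-study consistency check runs at $n = 2000$ because $b^*$ is a
ratio-type estimator with an $O(1/n)$ small-sample bias (at $n = 200$
its replicate mean sits a few percent below the population value —
visible in the README example, and the same order as the bias the
noncentral-t power prediction absorbs).

## Known limitations

Two source populations only (merge less divergent cohorts before
analysis, correct for the dominant divergence); a single biallelic QTL
per trait model underlies theory and simulator; the control-marker
assumption (no LD with QTL or test marker within subpopulations) is not
checkable from the admixed data alone; the delta-method se is asymptotic
and the δ gate makes the corrected fit unavailable, by design, when
structure is undetectable; expression preprocessing and normalization
are assumed done upstream.
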