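---
title: "Mapping QTL in achiasmate F2 populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTL in achiasmate F2 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkqtl)
```

## The problem

In the silkworm (*Bombyx mori*), as in *Drosophila* males, meiosis in one sex
proceeds without crossing-over: the female transmits each chromosome to her
offspring as an intact parental haplotype (achiasmata). An F2 individual
therefore carries one non-recombinant maternal chromosome and one freely
recombining paternal chromosome. This changes the joint distribution of
marker and QTL genotypes relative to the standard F2 design, and with it the
expected coefficients that interval-mapping models attach to a putative QTL
given its flanking markers. Applying the ordinary chiasmate F2 formulas to
silkworm data biases both effect estimates and positions; `silkqtl`
implements the mapping machinery with the correct achiasmate conditional
probabilities, and quantifies the bias one would incur without them.

## Conditional QTL-genotype probabilities

Consider a QTL $Q$ between flanking markers $M_+$ and $M_-$ with
recombination fractions $r_1$ ($M_+$–$Q$), $r_2$ ($Q$–$M_-$) and
$r = r_1(1-r_2) + r_2(1-r_1)$ across the interval (no interference;
$s_i = 1-r_i$, $s = 1-r$). Under achiasmata the female gamete is one of the
two parental haplotypes, each with probability 1/2, so the maternal marker
alleles are always in coupling; the paternal gamete follows the usual
no-interference two-interval law. Enumerating the $2 \times 8$ gamete
combinations yields the conditional law of the QTL genotype given each
flanking-marker class. For example,

$$P(QQ \mid M_+M_+M_-M_-) = \frac{s_1 s_2}{s}, \qquad
  P(Qq \mid M_+M_+M_-M_-) = \frac{r_1 r_2}{s},$$

first-order in the recombination fractions, whereas the chiasmate
counterparts ($s_1^2 s_2^2/s^2$, $2 s_1 s_2 r_1 r_2 / s^2$, ...) are second
order. Two flanking classes — opposite homozygotes $(M_+M_+, m_-m_-)$ and
$(m_+m_+, M_-M_-)$ — are impossible under achiasmata for linked markers;
`cond_prob_achiasmate()` raises a dedicated error for them (rather than
returning zeros) so that design mismatches in real data surface loudly.
`tests/testthat` verifies every entry of both laws against a brute-force
gamete-enumeration oracle to $10^{-10}$.

Expected effect coefficients use the coding $a$: $+1/0/-1$ for $QQ/Qq/qq$
and $d$: $+0.5$ for the heterozygote, $-0.5$ for homozygotes:
$x_A = P(QQ) - P(qq)$, $x_D = \tfrac12 P(Qq) - \tfrac12(P(QQ)+P(qq))$.
Epistatic coefficients are the per-locus products
($x_{AA} = x_A^{(i)} x_A^{(j)}$, etc.).

All distances pass through the Haldane map function
$r = \tfrac12(1 - e^{-2d})$ (d in Morgans): a 10 cM interval corresponds to
$r \approx 0.09$ and a 20 cM interval to $r \approx 0.16$, matching the
convention used throughout the package's reference analyses.

## The genetic model

The phenotype of individual $i$ of sex $h$ is modelled as

$$y_{hi} = \mu + \sum_k (x_{A_{ik}} a_k + x_{D_{ik}} d_k)
  + \sum_l (x_{AA_{il}} aa_l + x_{AD_{il}} ad_l + x_{DA_{il}} da_l
  + x_{DD_{il}} dd_l) + S_h + \text{(QTL} \times \text{sex terms)}
  + \varepsilon_{hi},$$

with the main and epistatic effects fixed, and the sex effect and all
QTL-by-sex interaction effects random with per-term variance components.
Sex enters as a two-level pseudo-environment: every random term's levels
come in (sex 1, sex 2) pairs constrained to sum to zero.

## The mapping procedure

1. **Background-marker selection.** Every pair of adjacent markers is
   tested through its eight per-sex additive/dominance columns against the
   sex-means-only model, with a permutation threshold (95th percentile of
   the per-permutation maximum F over all intervals). Retained intervals
   are pruned by backward stepwise elimination so that "ghost" intervals
   tagging the same QTL drop out; the strongest interval is never removed.
2. **1D scan.** A cM grid is walked over the whole genome. At each
   position the four per-sex QTL columns ($x_A$, $x_D$ split by sex, from
   the achiasmate or chiasmate backend) are tested by the partial-F
   statistic with the background terms in the conditioning set, excluding
   any background interval within a 10 cM window of the tested position so
   the background cannot absorb the QTL (the composite-interval-mapping
   exclusion-window convention). We walk genome-wide rather than only
   inside the selected intervals because the selection stage — a
   marker-pair test — regularly tags an interval *adjacent* to the true
   QTL; a walk confined to selected intervals then peaks at an interval
   edge several cM from the QTL, which in our replicate studies roughly
   halved power and quadrupled the false discovery rate. A
   `scope = "selected"` option restores the confined walk. Peaks above the
   stage's permutation threshold become detected QTLs after peak
   separation (at least one marker-interval width apart) and stepwise
   elimination.
3. **Interval-pair selection and 2D scan.** All interval pairs are tested
   through their sixteen per-sex epistatic marker-product columns; selected
   pairs are walked on a 2D grid testing the four per-sex epistatic effects
   of the putative QTL pair, conditioning on the detected main effects and
   the other pairs' marker terms.
4. **Full-model estimation.** The detections assemble the full mixed
   model; variance components are estimated by REML (analytic-gradient
   L-BFGS on log variances), fixed effects by GLS, random effects by
   BLUP with the adjusted-unbiased rescaling (predicted levels centred and
   scaled so their empirical variance matches the estimated component), and
   these initialize a Gibbs sampler whose posterior means/SDs are reported
   with $t = \text{mean}/\text{SD}$ significance tests.

All stage tests use the extra-sum-of-squares (Henderson III) partial F
computed through pivoted orthogonal decompositions:
$F = \frac{SSR(Q|M)/[\mathrm{rank}(X_{QM})-\mathrm{rank}(X_M)]}{SSE/[n-\mathrm{rank}(X_{QM})]}$.
The denominator degrees of freedom use the full-model rank, which makes the
statistic identical to the textbook two-fit nested-model F (verified to
$10^{-8}$ in the tests); ranks come from pivoted QR with relative tolerance
$10^{-10}$, so rank-deficient designs (e.g. overlapping interval pairs, or
paired QTLs on one achiasmate chromosome, where only seven two-locus
genotype classes segregate) are handled by reduced degrees of freedom
rather than failure.

### Model variants

* **I** — achiasmate probability backend, epistasis included;
* **II** — chiasmate backend (the standard F2 model applied, incorrectly,
  to achiasmate data), epistasis included;
* **III** — achiasmate backend with all epistasis stages skipped.

The variants differ *only* in these two switches, so any performance gap on
simulated achiasmate data isolates the modelling choice.

## Gibbs sampler details

The sampler uses a flat prior on fixed effects and scaled-inverse-$\chi^2$
priors on every variance component, with weakly informative defaults
$\nu_0 = 0.002$, $s_0^2 = 1$ (both exposed as arguments). Conditionals are
normal for fixed and random effects (random terms sampled blockwise) and
scaled-inverse-$\chi^2$ for variances. Random-effect levels are projected
onto the sum-to-zero constraint of their sex pair after every draw, which
both matches the model and keeps the chain identified against the
intercept; the variance conditionals use the correspondingly reduced
degrees of freedom. Divergent variance draws are capped at $10^6$ times the
phenotypic variance and flagged. Defaults are 11,000 iterations with 1,000
burn-in and no thinning; the evaluation study scales this down (below).
Chains are exactly reproducible under a seed.

Because each variance component is informed by few levels (two for the sex
main effect), its posterior is heavy-tailed and its reported mean can be
unstable; the effect-level posteriors, which are what the significance
tests use, are well behaved. This is an intrinsic feature of
sex-as-environment designs, not of the sampler.

## The simulator

`simulate_f2()` generates gametes per chromosome: the maternal gamete is an
intact parental haplotype (fair coin) in the achiasmate design, or a
recombinant gamete in the chiasmate contrast mode; the paternal gamete is a
first-order Markov walk over markers and QTL pseudo-loci with per-interval
Haldane recombination fractions (no interference). QTLs are inserted as
pseudo-loci in the walk so marker and QTL genotypes are jointly consistent.
Phenotypes follow the model above with the *true* QTL genotype codings.

Sex-structured effects are realized once per data set. They can be drawn
from variance components under the sum-to-zero constraint ($(z, -z)$ with
$z \sim N(0, \sigma)$), or supplied as explicit per-sex tables; the
built-in `silkworm_scenario()` uses explicit tables so that predicted
random effects can be compared against known realized values. The scenario
places 7 QTLs on 5 chromosomes of 11 markers at 10 cM spacing (two QTLs,
Q6 and Q7, have no main effects and act only through epistasis), three
epistatic pairs spanning the with/without-main-effect combinations, and
QTL-by-sex interactions for a subset of loci; n = 300 with equal sexes.

The residual variance default (`var_e = 18.75`, with `var_S = 2`) was
calibrated once by a 200,000-individual audit of the *parameter-level*
variance decomposition: the fixed genetic effects account for 50.5% of the
phenotypic variance and the QTL-by-sex variance components (taken at
6.24 per nonzero component) for 19.5% — a realistic structure for sexually
dimorphic cocoon traits — and was then frozen. Because the scenario fixes
the *realized* sex-interaction effects to its explicit tables (so that
predictions can be compared against known values), the realized
interaction share in any one data set is smaller than the parameter-level
19.5%; the residual variance is deliberately calibrated against the
parameter-level bookkeeping, which is the only accounting under which both
stated fractions can hold at once.

What the simulator does **not** emulate: genotyping error, segregation
distortion, crossover interference, sex-chromosome transmission, and
missing-data patterns of real genotyping platforms (missingness can be
introduced manually and is handled by conditional-expectation imputation on
the nearest informative flanking markers, the fast path of the
transition-matrix approach; a full multipoint pass is unnecessary for
complete simulated data). Passing simulations therefore demonstrate
correctness of the machinery under the stated genetic model, not robustness
to real-data artefacts.

## The coefficient-difference analysis

`coefficient_difference(r)` holds the interval fraction $r$ fixed, sweeps
$r_1$ over an interior grid of $(0, r)$ (plus the exact midpoint, where the
absolute-difference envelopes peak) with $r_2$ from the no-interference
identity, and records $D = |x_a - x_c|$ and $R = D/|x_a|$ per feasible
flanking class for both coefficients, where $x_a$ and $x_c$ are the
achiasmate and chiasmate values. Classes with $x_a = 0$ are excluded from
relative differences. At $r = 0.09$ the maximum absolute additive
difference is about 0.0025 and grows to about 0.009 at $r = 0.16$ —
small per locus, but systematic across every locus and individual, which is
how the chiasmate model loses power and gains bias on achiasmate data.
`scripts/acceptance.R` recomputes these envelope extrema from scratch.

## Evaluation-study defaults

`run_simulation_study()` defaults are deliberately scaled down so a full
comparison runs on a laptop: 50 replicates, 200 permutations per threshold,
2,000 Gibbs iterations (500 burn-in), a 1 cM one-dimensional walk (the
two-dimensional epistasis walk uses at least 2 cM), and a 10 cM
detection-matching window (one marker interval — the map's natural
resolution unit; matching is greedy by descending F to the nearest
unmatched true QTL on the same chromosome). All of these are arguments, so
the full-scale design (300 replicates, 1,000 permutations, 11,000
iterations) is one call away. Power is the fraction of replicates in
which a true QTL is matched; the false discovery rate pools detections over
replicates and carries a binomial Monte-Carlo standard error.

## Known limitations

* Epistasis between QTLs on the *same* chromosome is not fully identifiable
  in an achiasmate F2 (seven segregating two-locus classes against eight
  effects); the rank-aware F tests still locate such pairs, but individual
  effect estimates are aliased. Placing interacting QTLs on different
  chromosomes (nine classes) avoids this.
* Sex-chromosome (Z/W) loci, crossover interference and map estimation are
  out of scope.
* Permutation thresholds are recomputed per stage from the same shuffled
  phenotype stream seeded per stage; thresholds are stored in every result
  object for audit.
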