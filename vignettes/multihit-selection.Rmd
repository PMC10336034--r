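---
title: "Detecting episodic diversifying selection with synonymous rate variation and multinucleotide substitutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting episodic diversifying selection with synonymous rate variation and multinucleotide substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bustedmh)
```

## The problem

Branch–site codon models detect *episodic diversifying selection* (EDS): a
nonzero fraction of branch–site pairs in a protein-coding alignment evolving
with a nonsynonymous/synonymous rate ratio ω > 1. Two confounders are known
to distort this inference:

* **Synonymous rate variation (SRV)** — the baseline synonymous substitution
  rate varies from site to site. Ignoring it misattributes rate variation to
  the ω distribution.
* **Multinucleotide (multi-hit, MH) substitutions** — instantaneous codon
  changes at two (2H) or three (3H) nucleotide positions. Standard models
  force such events to be explained as successions of single-nucleotide
  changes; on short branches the cheapest explanation is often a spuriously
  large ω, which inflates false-positive rates of EDS tests —
  catastrophically so for plausible 2H rates.

`bustedmh` implements the full model hierarchy that addresses both at once:
the baseline random-effects branch–site model (BUSTED), its SRV extension
(+S), the multi-hit extension (+MH), the combined model (+S+MH), and the
intermediate +S+2H (double hits only). The hierarchy is nested
(BUSTED ⊂ +S ⊂ +S+2H ⊂ +S+MH and BUSTED ⊂ +MH ⊂ +S+MH), so models can be
compared by likelihood-ratio tests or information criteria.

## The substitution model

The state space is the 61 sense codons of the universal genetic code,
ordered lexicographically over A, C, G, T. The instantaneous rate from codon
*i* to codon *j* differing at positions *n₁..n_d* is

$$ q_{ij} \;=\; m_d \;\omega^{[\text{nonsyn}]}\; \alpha_s
   \prod_{n} \theta_{i_n j_n} \, \pi^{(n)}_{j_n}, $$

where

* *m₁ = 1*, *m₂ = δ*, *m₃ = ψ* are the hit-class multipliers: δ and ψ are
  alignment-wide rates of instantaneous double and triple changes relative
  to the single-hit synonymous baseline. Setting δ = ψ = 0 recovers the
  single-hit model *exactly* (entrywise). Both synonymous and nonsynonymous
  triple changes carry ψ; a `strict_nonsyn_psi` switch (off by default)
  restricts ψ to nonsynonymous triples for users who prefer the narrower
  reading of the rate parameterization.
* ω is the branch–site nonsynonymous/synonymous ratio, drawn independently
  for each branch–site pair from a K-bin general discrete distribution
  (GDD) with 0 ≤ ω₁ ≤ … ≤ ω_{K−1} ≤ 1 ≤ ω_K (K = 3 by default; 2K − 1 free
  hyperparameters). The *selection test* asks whether the ω_K > 1 class is
  needed.
* α_s is a site-level synonymous rate multiplier drawn from an L-bin GDD
  (L = 3 by default) whose mean is constrained to one for identifiability
  against branch lengths (2(L − 1) free hyperparameters). No
  branch-to-branch variation of α is modeled.
* θ are the five identifiable GTR nucleotide biases (θ_AG = 1); the HKY
  model with transition/transversion ratio κ embeds as θ_AG = θ_CT = 1 and
  transversions = 1/κ.
* π⁽ⁿ⁾ are positional nucleotide frequencies estimated by the CF3×4
  procedure: a 9-parameter maximum likelihood fit of the model in which
  codon frequencies are proportional to the positional product restricted
  to sense codons. The optimization is a bounded quasi-Newton pass on
  position-wise logits initialized at the F3×4 tallies, with tolerance
  1e-8 on the multinomial log-likelihood. A plain F3×4 fallback is
  exported.

MH substitutions spanning codon boundaries are deliberately not modeled:
allowing them breaks site independence and with it the tractability of the
pruning likelihood; omitting them is conservative because boundary-spanning
events are then absorbed as independent single hits.

Because the ω draws are iid across branches, the likelihood factorizes into
per-branch mixture transition matrices
$M_b = \sum_k p_k \exp(\alpha\, Q(\omega_k)\, s\, t_b)$, computed by
symmetric eigendecomposition (the chain is reversible with respect to the
positional-product codon distribution — one decomposition per ω category
serves every branch and α category, since α only rescales eigenvalues). The
root is closed with the stationary distribution, under which the likelihood
is invariant to root placement; site patterns are compressed; per-node
scaling guards against underflow on deep trees. Gaps and IUPAC ambiguity
codes become indicator ("partial") vectors over compatible sense codons;
columns containing in-frame stop codons are rejected unless the user masks
them to missing data.

### Units and the flux decomposition

One scaling constant `C = Σ_k p_k B(ω_k)` — the expected codon substitution
flux `B = Σ_{i≠j} q_{ij} π_j` averaged over the ω mixture (the unit-mean α
mixture contributes a factor of one) — normalizes the generator so branch
lengths are *expected substitutions per nucleotide site* (codon flux ÷ 3),
making reported tree lengths comparable across models and with other
software. Restricting the flux sum to codon pairs differing at exactly two
or three positions gives B2H and B3H; the ratios
`frac2H = B2H/B` and `frac3H = B3H/B` are the biologically interpretable
expected fractions of substitutions realized as double and triple hits
(δ and ψ themselves are not directly interpretable because the rate terms
also carry θ and π factors). Under the 4-taxon simulation parameterization
(equal positional frequencies, κ = 2, the neutral-null ω mixture):

```{r interp}
og <- omega_grid(c(0.1, 0.5, 1.0), c(0.5, 0.25, 0.25))
branch_length_decomposition(hky_bias(2), positional_frequencies(), og,
                            mh_rates(delta = 0.25, psi = 0))
```

δ = 0.25 corresponds to ≈ 8.5% of substitutions being double hits — the
high end of empirical estimates; across δ ∈ [0, 1] the fraction spans 0%
to ≈ 27%, and with δ = 0.25 the ψ grid [0.1, 1] spans ≈ 0.5% to 5.2% of
triple hits. The two interpretability sums (target-weighted, as printed
above, and source-weighted) coincide by reversibility; both are asserted in
the test suite. The decomposition averages over the ω mixture: the
reproduction of the anchor values at δ = 0.25 and along the ψ grid confirms
the mixture-average reading over a single-ω one.

## Fitting

`fit_model()` maximizes the likelihood for one configuration:

1. Positional frequencies are estimated once by CF3×4 and held fixed (they
   are counted as parameters but not iterated — the standard treatment of
   frequency parameters).
2. Unseeded fits initialize branch lengths and θ from a nucleotide-level
   GTR fit (via `phangorn`); seeded fits start at a nested model's optimum,
   which guarantees the monotone-nesting property
   lnL(+S+MH) ≥ lnL(+S) ≥ lnL(BUSTED) etc. When a seed without SRV is
   expanded to an SRV configuration the α mixture starts *spread* rather
   than at the degenerate all-equal point (where the gradient vanishes);
   if that start ever ends below the seed's optimum, the fit is repeated
   once from the exact nested expansion and the better result kept.
3. Optimization is bounded quasi-Newton (PORT) on transformed parameters:
   the below-one ω values via cumulative products of [0, 1] increments,
   ω_K = 1 + e^u (the ω₃ = 1 null simply drops u), mixture weights via
   stick-breaking, the α grid as L − 1 ratio increments relative to its top
   bin with the overall scale solved from the unit-mean constraint, δ and ψ
   boxed at zero, θ on the log scale. A first pass optimizes the
   distributions, MH rates and a single tree-scale factor; `branch_mode =
   "full"` (the default for empirical analyses) adds a joint pass over θ
   and every branch length. During optimization the scaling constant C is
   frozen at its start value — the free tree-scale parameter absorbs the
   reparameterization exactly, so the optimum is unchanged while the
   transition-matrix caches stay valid along finite-difference
   perturbations; branch lengths are converted back to
   substitutions/nucleotide at the returned MLEs.
4. `starts > 1` adds jittered restarts of the mixture hyperparameters from
   a seeded RNG (the caller's RNG stream is saved and restored). Default 3
   for user-facing fits; the simulation harnesses use 1, relying on
   hierarchy seeding instead.
5. A warning is raised when adjacent grid rates differ by < 0.1% relative
   or any weight falls below 1e-4 — signatures of an overparameterized
   mixture. (These thresholds are the package's own; they are heuristics,
   not tests.)

Parameter counts follow the closed forms B + 13 + 2K (BUSTED),
B + 11 + 2(K + L) (+S), B + 15 + 2K (+MH), B + 13 + 2(K + L) (+S+MH), with
B the number of free branches of the unrooted topology (2N − 3; rooted
inputs are unrooted, which is also required for branch-length
identifiability under reversibility). AICc uses
`n = (number of sequences) × (number of codon sites)` as the sample size;
this convention is not universal, so absolute AICc values are comparable
only within one convention — AICc *differences* between models on the same
data, which are all the package uses, are insensitive to it.

## Hypothesis testing and model averaging

The EDS test compares each model against its ω_K = 1 constrained null.
Because the null pins a boundary-plus-constraint, the LRT statistic is
referred to a 50:50 mixture of χ²₀ and χ²₂:
`p = 0.5 · Pr(χ²₂ ≥ max(LRT, 0))`, so a nonpositive statistic reports
exactly p = 0.5 (the capped value that tabulated analyses print as
0.5000). Statistics marginally negative from optimizer noise (> −0.01) are
clamped to zero; anything more negative triggers a warning to refit the
alternative from the null's optimum (the harness does this repair
automatically).

MH rates are tested by the nested chain +S → +S+2H → +S+MH: δ > 0 and
ψ > 0 each against a conservative χ²₁ (the boundary null makes this
conservative; degrees of freedom for the single-rate tests follow the same
conservative convention as the joint test), and δ = ψ = 0 jointly against a
conservative χ²₂.

Model selection uses Akaike weights
`w_m ∝ exp((AICc_best − AICc_m)/2)`, normalized to sum to one, and the
**model-averaged p-value** `p_MA = Σ_m w_m p_m` — a convex combination that
always lies within the component range and converges to the best model's p
as its AICc advantage grows. Screening across many alignments applies
Benjamini–Hochberg FDR control (`bh_fdr()`, q ≤ 0.2 as the screening
default). `model_test()` orchestrates the four fits with their nulls and
reports the per-model table, weights, p_MA, the AICc-best model and a
detection pattern with bits ordered (+S+MH, BUSTED, +S, +MH, Averaged,
Best).

## Diagnostics

* `site_evidence_ratios()` — per-site likelihood ratios between two fits;
  their logs sum to the total log-likelihood difference.
* `branch_site_ebf()` — empirical Bayes support for selection at each
  branch–site pair: the focal branch's ω distribution is collapsed onto the
  selection class (all other branches keep the full mixture — this is what
  makes the conditional likelihood in the posterior formula well defined
  per branch), and the posterior equals that conditional likelihood times
  the alignment-level weight p₃ over the marginal site likelihood. With SRV
  active, numerator and denominator marginalize the α categories with their
  fitted weights, keeping the two consistent. EBFs are posterior/prior odds
  ratios; they are noisy and intended for hot-spot exploration, not formal
  site tests.
* `lrt_site_profile()` — per-site decomposition of the EDS LRT, the number
  of sites carrying > 80% of the statistic, and the count of branch–site
  pairs with EBF > 100. A detection carried by one or two sites (often a
  single multinucleotide event on a short branch) warrants manual
  inspection for alignment error.
* `plot_ebf_tree()` colors branches by the EBF ratio between two fits;
  values are exported raw, without clipping, since informative ranges vary
  by orders of magnitude across datasets.

## The simulator and the experimental harnesses

`simulate_alignment()` performs *exact event-time simulation*: each site
draws an α category, each branch–site pair draws an ω category, and the
site evolves from a stationary root state via exponential waiting times on
the generator's off-diagonal rates. Every substitution event is logged with
its hit class — endpoint sampling would hide 2H/3H events, and the event
log is what lets simulated event-class fractions be checked against the
analytic B2H/B and B3H/B (they agree within binomial error; the law of
large numbers bridges the simulator and the flux analytics).

The default harness conditions are the 4-taxon study design: 800 codons,
equal (0.25) positional frequencies, HKY κ = 2, an unrooted quartet with
five branches of 0.2 expected substitutions/nucleotide (the tree used in
the original experiments is published only as a figure; 0.2 is the
package's fixed choice of baseline with the two tip branches to `c` and `d`
scannable over {0.01, 0.05, 0.1, 0.2, 0.5}, covering the short-branch
regime where single-hit models are most vulnerable). The null generator
uses the ω mixture (0.1 @ 50%, 0.5 @ 25%, 1.0 @ 25%); power generators use
(0.1 @ 50%, 0.5 @ 40%, ω₃ @ 10%) with ω₃ ∈ {1.25, 1.5, 2, 4, 8, 16}, or a
25% selected fraction variant. The generating α distribution is not stated
in the study designs; the package fixes a moderate, realistic SRV of
(0.5, 1, 2) with weights (0.25, 0.5, 0.25) (coefficient of variation ≈
0.5, mid-range among empirical estimates) and uses it for both null and
power harnesses. Replicates default to 100 per cell with a `--reps`
override; the packaged acceptance checks use 20 replicates per cell to keep
a desk-scale run in minutes, which widens the binomial tolerance bands
accordingly (e.g. "100% power" is asserted as ≥ 19/20).

`run_null_grid()` and `run_power_grid()` simulate, fit the requested
models with hierarchy seeding (each fit starts from the candidate nested
fit with the highest log-likelihood after adaptation; constrained nulls
choose between the nested models' nulls and the model's own alternative
with the selection class pinned), repair any lnL-ordering violations by
refitting, and tabulate rejection rates. Because the null surface of the
multi-hit models is multimodal on multi-hit data — a null seeded without
the fitted δ/ψ can stall tens of log-likelihood units short, which
inflates the LRT — the harness re-optimizes the null with full effort
whenever the statistic lands where the decision could flip or the
alternative shows the ω-absorption signature (an extreme selection-class
rate at tiny weight). This targeted effort is what keeps the +S+MH test
calibrated on double-hit data while leaving genuine detections untouched. The harnesses fit with `branch_mode = "scale"`,
a single start and a slightly relaxed optimizer tolerance
(`rel_tol = 3e-6`, about 0.03 log-likelihood units at the 800-codon
problem size) — decisions at the 0.05 level are insensitive at this
precision, and the relaxation keeps a full grid cell to seconds.

What the simulator does *not* emulate: indels and alignment error,
recombination, codon-boundary-spanning multi-hit events,
context-dependent mutation (e.g. CpG), and among-branch variation in α.
Passing the harness checks therefore demonstrates correct behavior of the
estimators under the model class, not robustness to real-data pathologies
outside it.

## Numerical choices and edge cases

* Symmetric eigendecomposition of the similarity-transformed generator;
  reconstructed transition matrices are clamped at zero (reconstruction
  error ~1e-13) and verified row-stochastic to 1e-12 in tests.
* Zero branch lengths are legal (transition matrix = identity); zero-rate
  states in the simulator terminate the waiting-time loop.
* A likelihood of exactly zero at a site raises an error naming the site
  rather than returning −Inf silently.
* Mixture ties: the GDD is invariant to permuting equal rates; the
  ordering constraints make the representation unique, and the overfit
  warning flags near-ties.
* LRT statistics in [−0.01, 0] are treated as 0 (p = 0.5); beyond that the
  harness refits rather than reporting a negative statistic.

## Reproducibility scale

The packaged checks run at deliberately reduced scale: 20 replicates per
simulation cell (the original experiments use 100), the enumeration oracle
at ≤ 3 sites and K = L = 2, and parameter recovery at 20 replicates.
Benchmark-alignment and genome-screen results (and the power numbers tied
to specific empirical datasets) require external alignments and are out of
scope here; the generative harnesses cover the corresponding behavior on
synthetic data. The `run_*_grid()` functions accept any `FitResult`-shaped
generator parameters, so empirically-conditioned simulations work when
such data are supplied.
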