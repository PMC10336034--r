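# bustedmh

Branch–site codon models for detecting **episodic diversifying selection**
(EDS) in protein-coding alignments, jointly accounting for two confounders
that standard dN/dS tests ignore:

* **synonymous rate variation** (SRV) — site-to-site variation of the
  baseline synonymous rate α, and
* **multinucleotide (multi-hit) substitutions** — instantaneous codon
  changes at two (rate δ) or three (rate ψ) nucleotide positions.

Unmodeled multi-hit substitutions are absorbed by single-hit models into
inflated ω estimates, which drives false-positive selection detections —
up to 100% at plausible δ. `bustedmh` implements the full model hierarchy
(BUSTED, +S, +MH, +S+MH, and the intermediate +S+2H), the selection
likelihood-ratio test, AICc model averaging, branch–site empirical Bayes
diagnostics, and an event-logging simulator with false-positive-rate and
power harnesses.

## The model

The instantaneous rate between sense codons *i* and *j* differing at
positions *n₁..n_d* is

    q_ij = m_d · ω^[nonsyn] · α_s · Π_n θ(i_n, j_n) π^n(j_n),

with hit-class multipliers m₁ = 1, m₂ = δ, m₃ = ψ; ω drawn per branch–site
pair from a 3-bin general discrete distribution with
0 ≤ ω₁ ≤ ω₂ ≤ 1 ≤ ω₃; α_s drawn per site from a unit-mean 3-bin
distribution; θ the five GTR nucleotide biases (θ_AG = 1); and π the
CF3×4 positional frequencies. The EDS test compares each model to its
ω₃ = 1 null with a 50:50 χ²₀/χ²₂ boundary mixture:
p = 0.5 · Pr(χ²₂ ≥ LRT), reported as 0.5 when the statistic is
nonpositive. Models are combined through Akaike weights
w_m ∝ exp((AICc_best − AICc_m)/2) and the model-averaged p-value
p_MA = Σ w_m p_m.

The interpretable summary of the multi-hit rates is the flux decomposition
B2H/B and B3H/B (fractions of expected substitutions realized as double
and triple hits), where B = Σ_{i≠j} q_ij π_j restricted by hit class and
averaged over the ω mixture.

## Worked example

Simulate a quartet alignment under the +S+MH generator with a moderate
double-hit rate and no positive selection, then run the model-testing
procedure:

```r
library(bustedmh)

spec <- simulation_spec(mh = mh_rates(delta = 0.25, psi = 0), seed = 42)
sim  <- simulate_alignment(spec)
sim
#> <simulated_alignment: 4 taxa x 800 codons, 2456 events ( 181 x 2H, 0 x 3H )>

mt <- model_test(sim$alignment, sim$tree, models = c("+S", "+S+MH"),
                 branch_mode = "scale", seed = 42)
mt
#> <busted_modeltest: 2 models | best: +S+MH | model-averaged p = 0.4788 >
#> # A tibble: 2 × 7
#>   model    lnL     k   aicc weight     lrt     p
#>   <chr>  <dbl> <dbl>  <dbl>  <dbl>   <dbl> <dbl>
#> 1 +S+MH -9437.    30 18934.  0.846 0.00711 0.498
#> 2 +S    -9440.    28 18937.  0.154 0.591   0.372
#> detection pattern (+S+MH, +S, Averaged, Best): 0000

mt$fits[["+S+MH"]]$mle$mh$delta
#> [1] 0.2604706
```

The double-hit-aware model is preferred by AICc despite its two extra
parameters, recovers the generating rate (δ̂ = 0.26 vs. the true 0.25),
and no model claims selection — the correct negative on data containing
181 logged double-hit events that a single-hit model would have to explain
with inflated ω. Analytic interpretation of a fitted δ:

```r
branch_length_decomposition(hky_bias(2), positional_frequencies(),
                            omega_grid(c(0.1, 0.5, 1), c(.5, .25, .25)),
                            mh_rates(delta = 0.25))
#> # A tibble: 1 × 5
#>       B    B2H   B3H frac2H frac3H
#>   <dbl>  <dbl> <dbl>  <dbl>  <dbl>
#> 1 0.922 0.0779     0 0.0845      0
```

i.e. δ = 0.25 corresponds to ≈ 8.5% of substitutions being instantaneous
double hits. Fitted objects have `tidy()`/`glance()` methods; grid results
are tibbles with `summarize_rejections()` and plotting helpers; a thin CLI
lives at `exec/bustedmh` (subcommands `fit`, `modeltest`, `simulate`,
`null-grid`, `power-grid`, `diagnose`).

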