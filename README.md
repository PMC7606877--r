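# alpdyn

Mean-field population-balance modeling of human mesenchymal stem-cell
(hMSC) cultures undergoing osteogenic differentiation, with and without
electrical stimulation.

## The problem

In osteogenic cultures, two bulk read-outs are followed over weeks: the
total number of cells `N(t)` (LDH assay) and the total alkaline-phosphatase
activity `Φ(t)` (ALP assay, an early differentiation marker). Typical time
courses show quadratic cell growth while total ALP activity rises, peaks
around two weeks, and then falls — and a weak applied electric field shifts
the ALP curve without changing the counts. `alpdyn` provides the
quantitative machinery to explain and exploit those curves: it models the
full distribution `n(a, t)` of cells over per-cell ALP activity `a` with a
Smoluchowski-type balance equation

```
∂n/∂t = −½ ∫₀ᵃ n(a,t) k_d(a−a′, a′) da′ + ∫₀^∞ n(a+a′,t) k_d(a, a′) da′
        − ∂(s_i(a) n)/∂a + ∂(d_o(a) n)/∂a − k_f(a) n ,
```

whose terms are cell division (kernel `k_d`), intracellular ALP synthesis
`s_i` and degradation `d_o`, and terminal differentiation `k_f`. The
moments `N = ∫ n da` and `Φ = ∫ a·n da` connect the single-cell processes
to the assay read-outs.

Two concrete differentiation mechanisms are built in, both with symmetric
non-conserved divisions at effective rate `k_d = 2/t`:

* **PSCD** (progressive differentiation): gradual per-cell ALP decay,
  `d_o(a) = d₀·a`. Closed forms `N(t) = N̄₀ t²` and
  `Φ(t) = Φ̄₀ t² e^{−d₀ t}` — a rise-and-fall ALP curve peaking at
  `t = 2/d₀`.
* **ISCD** (instantaneous differentiation): sudden whole-cell loss at
  constant rate `k_f`. Both moments grow as `t²`, so total ALP is
  monotone — which is exactly why data with an interior ALP peak reject
  this mechanism.

The package contains:

* a numerical solver for the full balance equation on an activity grid
  (conserved-division quadrature, upwind advection, CFL-guarded explicit
  stepping) and moment extraction;
* the closed-form solutions, peak-time, and the division-rate-versus-
  density curve `k_d(ρ) = 2√(N̄₀/(ρV))` implied by eliminating time;
* an event-driven stochastic single-cell simulator (division /
  differentiation / deterministic ALP drift, thinning for time-dependent
  rates) that serves as an independent check on the mean-field moments;
* weighted/unweighted least-squares fitting of the closed forms to assay
  time courses with χ² goodness of fit, delta-method errors on `1/d₀`,
  control-versus-stimulated comparison, and PSCD/ISCD model selection;
* a synthetic-assay generator emulating the study design (days 7, 14, 21,
  28; four samples per condition; CV-scaled truncated-Gaussian noise).

## Worked example

Generate a synthetic control/stimulated pair at the reference parameters
(count amplitude `N̄₀ = 535` cells/day²; control ALP `Φ₀ = 0.8007`,
`1/d₀ = 5.84` d; stimulated `Φ₀ = 0.84`, `1/d₀ = 6.2` d at reference day
`t0 = 7`) and re-estimate everything by least squares:

```r
library(alpdyn)

pair <- generate_paperlike_pair(seed = 1)
fit_c <- fit_alp_activity(pair$control)
fit_s <- fit_alp_activity(pair$stimulated)
fit_c
#> <fit_result> model: pscd_alp
#>          estimate        se
#> Phi_bar0 0.054276 0.0025065
#> d0       0.170960 0.0024456
#> inv_d0   5.849400 0.0836750
#> Phi0     0.803680 0.0260510
#>   chi2 (weighted): 0.22491   RSS (unweighted): 0.00077906   dof: 2

compare_conditions(fit_c, fit_s)
#> <condition_comparison>
#>   1/d0: control 5.849 d, stimulated 6.239 d
#>   d0 ratio (stim/control): 0.9376
#>   delta(1/d0) = 0.3891 +/- 0.09495 d
#>   verdict: stimulated d0 lower => slower ALP degradation under field

model_selection(pair$control)
#> <model_selection> preferred: pscd
#>   chi2 pscd: 0.22491   chi2 iscd: 1065.9
#>   iscd flagged: TRUE (empirical ALP peak is interior: a monotone (ISCD)
#>   curve cannot reproduce it)

fit_cell_counts(list(pair$control, pair$stimulated))$pooled
#> <fit_result> model: pscd_cells
#>        estimate     se
#> N_bar0   558.51 13.002
```

Reading the output: the ALP degradation time `1/d₀` is recovered at 5.85 d
(control) versus 6.24 d (stimulated) — the field slows per-cell ALP
degradation, shifting the predicted ALP peak (`2/d₀`) from ~11.7 to ~12.5
days — while the pooled count amplitude (559 ± 13 cells/day², truth 535) is
shared between conditions. The monotone ISCD curve fits the same ALP series
three orders of magnitude worse and is flagged structurally.

The grid solver and the stochastic simulator give the same moments as these
closed forms (to <1% and within Monte-Carlo error, respectively); see the
methods vignette (`vignettes/alp-population-balance.Rmd`) for the numerical
scheme, noise model and design choices.

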