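---
title: "Response analysis of molecular competition networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response analysis of molecular competition networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcompete)
```

## The model

`fluxcompete` analyses networks in which `n` molecular competitors
reversibly bind a single shared target resource and the bound complex
carries a productive flux.  The archetypes are sigma factors binding RNA
polymerase core enzyme (the complex transcribes a promoter class) and
mRNAs binding ribosomes (the complex synthesises protein).  Moiety
conservation constrains the species: the target total `T` splits into
free target `t` and complexes `tc_i`, each competitor total `C_i` into
free `c_i` and `tc_i`.

The central objects are steady-state *response coefficients*
`R = d ln J / d ln p`: the relative change of a flux per relative change
of a conserved total.  For this network class they reduce to closed
forms in measurable amounts only,

$$R_i^T = \frac{1 - s_i}{1 - \sum_j f_j s_j}, \qquad
  R_i^{C_i} = 1 - R_i^T f_i, \qquad
  R_i^{C_k} = -R_i^T f_k \;(k \ne i),$$

with saturations `s_i = tc_i / C_i` and bound pool fractions
`f_i = tc_i / T`.  No rate constant appears: two states with the same
`(T, C, tc)` respond identically no matter the kinetics that produced
them.  The numerator of `R_i^T` is the free fraction of competitor `i`;
the denominator discounts the pool by the saturation-weighted bound
fraction.  Direct consequences, all enforced as tested invariants:

* `R_i^T >= 0`, `R_i^{C_i}` in `[0, 1]`, `R_i^{C_k} <= 0` with
  `|R_i^{C_k}| <= R_i^T`;
* the row identity `R_i^T + sum_k R_i^{C_k} = 1 + R_i^T t / T`;
* response ratios `R_i^T / R_j^T = (1 - s_i)/(1 - s_j)` (the less
  saturated competitor always responds more) and
  `R_i^{C_k} / R_i^{C_l} = tc_k / tc_l` (competitor strength is bound
  amount, not saturation);
* `R_i^T > 1` (ultrasensitivity) exactly when the free target lies below
  `sum_{j != i} tc_j (s_j/s_i - 1)`.  The package evaluates the predicate
  in the division-free form `sum_j tc_j s_j > s_i T`, so competitors with
  `s_i = 0` need no special-casing (their threshold value is reported as
  `NA`); the most saturated competitor can never be ultrasensitive.

### Multiple target binding (translation)

An mRNA binds up to `N_i / L` ribosomes (ORF length `N_i` codons,
footprint `L`).  Under an all-or-nothing binding approximation the
single-binding formulas carry over with `s_i = P_i L / N_i` and
`f_i = C_i P_i / T`, where `P_i` is the mean number of bound ribosomes
per mRNA molecule.  `P` is accepted directly, as
occupancy × polysome size, or via a ribosome density (ribosomes per 100
codons; a converter from the per-1000-nucleotides convention is
provided), with that precedence order.  For `N_i = L` the reduction to
the single-binding theory is exact and tested.

## Parameters that matter

* **Ribosome pool `T = 79` µM** and **footprint `L = 12` codons**: the
  yeast-scale defaults used across the translation module.  The physical
  density maximum is `100 / L = 8.33` ribosomes per 100 codons; input
  densities above it are clamped to the cap minus `cap_epsilon`
  (default 0.005 density units, configurable) and counted.
* **Default occupancy 0.75**: transcript compilations usually miss
  occupancy for a few percent of genes; missing entries are filled with
  0.75 (the typical measured mean) and `P` recomputed.  A counterfactual
  variant, `force_full_occupancy()`, sets every occupancy to 1; its
  bookkeeping deliberately overcommits the pool, so pool validation is
  relaxed for exactly this constructor.
* **Perturbation fraction `delta = 0.01`** for finite-difference
  coefficients, measured as a forward log-difference
  `[ln J(p(1+delta)) - ln J(p)] / ln(1+delta)`; a central scheme is
  available for tighter oracle work.  Deviations from the closed forms
  grow monotonically with `delta` (tested at 1/5/10/15%).
* **Validation slack 1e-9 (relative)** when checking conservation
  inequalities on user tables, absorbing rounding in published data.

## The two mechanistic validators

The closed forms are never taken on faith; two simulators measure
coefficients by actually perturbing totals and re-solving.

**Mass-action binding model.**  Complex balances
`d(tc_i)/dt = k_f_i t c_i - (k_r_i + k_cat_i) tc_i` with free amounts
substituted through conservation; fluxes `J_i = k_cat_i tc_i`.  The
steady state has the closed form `tc_i = K_i t C_i / (1 + K_i t)` with
`K_i = k_f_i/(k_r_i + k_cat_i)` and free target the unique root of the
strictly increasing `t + sum_i tc_i(t) - T` on `[0, T]` — bracketed
root-finding to near machine precision is the default engine, with
`lsoda` integration from empty pools (geometric checkpoints, steady
state declared at relative derivative norm `1e-10`) as the independent
route; the two agree to `1e-6` relative on randomised stiff parameter
sets.  The bundled `sigma_network_params()` (binding 24/8/11, unbinding
3/6/30, production 5 per minute, totals 700/370/110) reproduces the
sigma-factor saturation pattern at `T = 700` and anchors the scan tests:
coefficients approach the free competitor fraction at low `T`, zero at
high `T`, and exceed 1 in between only for the less saturated
competitors.

**Ribosome-traffic (polysome) model.**  Each codon of each mRNA species
carries the fraction of molecules with a ribosome *front* there.
Initiation is bimolecular in free ribosomes and the free start window
(first `L` codons); elongation advances a front at
`k_elong p_j (1 - S_{j+1,j+L}) / (1 - S_{j+1,j+L-1})`, the mean-field
conditional probability that the next codon is clear under hard-body
exclusion, with window sums truncated at the stop codon (codons past the
stop treated as free); termination releases from the last codon.  Ribosome
subunit dynamics are not modelled.  Two engines solve it: an exact
steady-state solver — at steady state all per-molecule fluxes along an
mRNA are equal, so the profile follows from the throughput by backward
recursion from the stop codon, leaving two nested monotone bracketed
root-finds (throughput given free ribosomes; free ribosomes from pool
conservation) — and `lsoda` integration of the per-codon ODEs from empty
mRNAs (derivative criterion `1e-9`, solver tolerances `1e-8`/`1e-10`).
They agree to better than `1e-6` wherever both are run; the tests use the
ODE engine on coarse 60-codon systems where integration is cheap, and the
recursion engine at the full 240-codon scale of the two-mRNA benchmark
(`two_mrna_polysome_params()`).

## What the synthetic transcriptome emulates — and what it does not

`generate_transcriptome()` produces tables with the statistical shape of
genome-scale yeast compilations: 4621 genes; log-normal ORF lengths
(median 400 codons, log-sd 0.65, clamped to `[L, 5000]`); log-normal,
positively skewed mRNA abundances (log-sd 1); log-normal ribosome
densities (median 1 per 100 codons, log-sd 0.6) clamped at 8.33; Beta
occupancies with mean 0.75 (concentration 12) of which 2% are blanked
and later filled at 0.75.  The abundance scale is calibrated so the
expected engaged share of the 79 µM pool is 95%, matching the high
ribosome engagement of exponentially growing cells; draws that
overcommit the pool are rescaled down by a common factor on `P` (the
rescale factor, clamp count and fill count are recorded as attributes).
These choices were fixed once, from the biology, and are configuration
rather than constants.

Deliberately *not* emulated: correlations between abundance, length and
density found in real data beyond those induced by the construction;
measurement noise; codon-specific elongation rates; isoform structure.
Passing genome-scale tests therefore shows that the pipeline computes
the intended quantities on realistic marginals, not that any particular
organism's numbers are reproduced.  On these tables the majority of
genes sit above a pool response of 1 — translation flux for most genes
is ultrasensitive to ribosome availability, with a long left tail of
robust low responders — and `tail_bins()` extracts the extreme 5%
deterministically (rank by coefficient, ties broken by gene id, bin size
`floor(fraction * n)`, so 231 genes of 4621).

## Numerical choices and degenerate inputs

* Root-finding: `uniroot` on provably monotone brackets everywhere
  (free-target conservation in both models, per-species throughput via
  plain bisection treating capacity-infeasible throughputs as the high
  side); no Newton iterations, no dependence on starting guesses.
* ODE initialisation from empty pools (`tc = 0`, empty mRNAs); the
  steady states of both model classes are unique, so initialisation only
  affects runtime.  Perturbed polysome runs warm-start from the
  reference profiles.
* Degenerate states raise classed conditions rather than `NA`s: a
  denominator collapse (all target bound to fully saturated
  competitors), zero-flux references for finite differences, saturation
  ratios of competitors holding no target, exclusion violations in
  supplied profiles.  The command-line layer maps validation errors to
  exit code 2 and convergence failures to exit code 3.
* Tie-breaking in tail binning is lexicographic on gene id, making the
  exported lists reproducible byte for byte.

## Known limitations

* The closed forms inherit the all-or-nothing, no-steric-interference
  approximation.  Against the traffic model they are accurate in the
  initiation-limited regime (on the two-mRNA benchmark, within a few
  percent at effective saturations below roughly one half) but
  overestimate pool sensitivity as the system approaches the traffic
  capacity: mean-field hard-body exclusion caps codon coverage at
  `sqrt(L)/(sqrt(L)+1)` (0.776 for `L = 12`), and near that plateau the
  simulated flux becomes elongation-limited and insensitive to the pool
  while the formulas still predict coefficients of 0.2–0.35.  Users
  applying the formulas to heavily loaded transcripts should treat
  coefficients at effective saturations approaching the cap as upper
  bounds.
* Test problem sizes are deliberately modest (60-codon ORFs for ODE
  cross-checks, a few hundred to 4621 genes for distribution tests,
  20-point target grids); they were chosen as the smallest systems that
  exercise every regime of interest.
* The genome pipeline stops at ranked gene lists; functional enrichment
  of the tails requires external annotation resources and is out of
  scope.
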