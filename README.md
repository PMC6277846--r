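# reeflux

Flux-balance and multi-omics analysis of the rare-earth-element (REE)
methanol dehydrogenase switch in methanotrophic bacteria.

Methanotrophs such as *Methylomicrobium alcaliphilum* 20Z carry two
methanol dehydrogenases: calcium-dependent MxaFI and
lanthanide-dependent XoxF. Lanthanum represses *mxaFI* and induces
*xoxF*, and cultures grown with La grow faster but waste more carbon —
they consume more O₂ per CH₄ (observed consumption ratios 1.28 vs 1.12)
and reach lower biomass yields (0.64 vs 1.2 g DCW per g CH₄). The
leading mechanistic explanation is that XoxF oxidizes part of its
formaldehyde product straight through to formate via a cytochrome-linked
reaction, draining both assimilable carbon and NADH-level reducing
power. `reeflux` implements the computational backbone for testing this
hypothesis:

* a reduced core stoichiometric model of C1 metabolism
  (`build_core_model()`) with both methanol-oxidation routes and the
  cytochrome-linked formaldehyde→formate branch (`MXALa`) as an explicit
  reaction, plus TSV and SBML (Level 3 + fbc) import/export;
* an exact FBA/FVA solver (`solve_fba()`, `flux_variability()`) with a
  branch-fraction coupling constraint
  (`apply_branch_fraction()`: v(MXALa) = φ·v(XOXF)), energetic
  calibration against an observed O₂:CH₄ ratio
  (`calibrate_energetics()`), and the φ scan that locates the branch
  fraction best matching observation (`scan_branch_fractions()`,
  `best_matching_phi()`);
* chemostat physiology calculators (`steady_state_summary()`,
  `specific_consumption_rate()` — q = 1000·μ/(Y·M) — and friends);
* the omics decision rules of the study design: BH-adjusted p < 0.05
  with |log2FC| ≥ 1.5 for differential expression (`call_deg()`), the
  averaged-replicates twofold rule for spectral-count proteomics
  (`spectral_fold_changes()`), transcript/protein concordance
  categories (`concordance_matrix()`), metabolite log-ratios with Welch
  tests and Spearman correlation with exact small-n permutation
  p-values (`rank_correlation()`);
* synthetic-data generators (`simulate_offgas()`, `simulate_counts()`,
  `simulate_spectral_counts()`, `simulate_metabolites()`) that plant the
  study's observed physiology and effect sizes as ground truth, so every
  stage is testable offline.

## Worked example: locating the formate branch fraction

```r
library(reeflux)

# 1. calibrate the wild-type (Ca) biomass energetics so the model
#    reproduces the observed wild-type O2:CH4 ratio of 1.18
beta <- calibrate_energetics(
  function(b) build_core_model(ca_config(biomass_atp_cost = b)),
  target_ratio = 1.18)

# 2. scan the formate branch fraction phi on the La-configured model
la <- build_core_model(la_config(biomass_atp_cost = as.numeric(beta)))
wt <- build_core_model(ca_config(biomass_atp_cost = as.numeric(beta)))
rows <- scan_branch_fractions(la, c(0.25, 0.5, 0.75, 1), wt_model = wt)
cat(render_scan_table(rows))
#> scenario  o2_rate  ratio  growth
#> WT        13.78    1.18   3.6078
#> phi=0.25  14.52    1.24   3.3300
#> phi=0.5   15.43    1.32   2.9855
#> phi=0.75  16.34    1.40   2.6410
#> phi=1     17.50    1.50   2.2019

# 3. which phi best explains the observed La consumption ratio of 1.28?
best_matching_phi(rows, 1.28)
#> [1] 0.25
```

Reading the table: `o2_rate` is the solved O₂ consumption
(mmol gDCW⁻¹ h⁻¹ at the fixed CH₄ uptake of 11.67), `ratio` the
O₂:CH₄ consumption ratio and `growth` the biomass objective. The ratio
rises strictly with the fraction of methanol carried through to formate
— diverting carbon and swapping NADH for cytochrome electrons forces
extra respiration — and the wild-type sits lowest. A branch fraction of
about 25% moves the wild-type ratio toward the observed La value, the
same fraction at which the published genome-scale simulations met
observation. (The core model reproduces this qualitative pattern;
reproducing the published scan's absolute values requires importing
that genome-scale SBML via `read_sbml_subset()`.)

The physiology side closes the loop on synthetic data:

```r
cond <- default_conditions()$la_optimal   # D=0.07/h, X=0.75 g/L, Y=0.64
og <- simulate_offgas(cond$spec, cond$yield_biomass,
                      planted_ratio = 1.28, seed = 42)
steady_state_summary(cond$spec, og)
#> steady-state summary [La-optimal]
#>   mu            : 0.070 1/h
#>   yield         : 0.629 g DCW / g CH4
#>   q(CH4)        : 6.94 mmol/gDCW/h
#>   q(O2)         : 8.49 mmol/gDCW/h
#>   O2:CH4 ratio  : 1.22
#>   productivity  : 13.1 mg DCW/h
```

One noisy 24 h series recovers the planted yield (0.64) and ratio
(1.28) to within sensor noise; over a 20-seed ensemble the means
converge on the planted values.

A thin command-line wrapper (`inst/cli/reeflux.R`) exposes the same
stages as subcommands (`build-model`, `fba`, `scan`, `calibrate`,
`physiology`, `omics`, `simulate`, `report`); see `?reeflux_cli`.

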