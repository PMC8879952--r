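# cin2d

Computational indicator of nanotoxicity for two-dimensional nanomaterials
interacting with phospholipid membranes.

A nanosheet approaching a lipid bilayer can do one of four things: nothing
(thermal noise dominates), stick to the head groups (**adsorption**), slide
in between the leaflets (**insertion**), or rip lipids out of the membrane
(**lipid extraction**). Which of these happens is largely decided by two
numbers obtained from steered pulling simulations:

- **g_h** — the adsorption free energy of a lipid *head* group on the
  nanosheet face (kJ/mol, ≤ 0),
- **g_t** — the same for a lipid *tail*.

The indicator is their difference:

```
CIN2D = g_h − g_t
```

and the membrane's resistance to losing lipids is

```
g0 = min over N of ( G_N / N )
```

where `G_N` is the free-energy barrier for extracting `N` lipids at once.
For a POPC bilayer at 310 K the per-lipid barriers 93.3, 152.0/2 and
224.4/3 kJ/mol give `g0 = 74.8 ≈ 75` kJ/mol. The classification is then:

| condition                      | regime            |
|--------------------------------|-------------------|
| \|g_h\| + \|g_t\| < k_B·T      | no_interaction    |
| CIN2D < 0                      | adsorption        |
| 0 ≤ CIN2D < g0                 | insertion         |
| CIN2D ≥ g0                     | lipid_extraction  |

Uncertainty is propagated as the sum of the absolute errors of g_h and g_t;
a call is flagged *not confident* when the error interval straddles a regime
boundary or exceeds |CIN2D| itself.

The package provides four things:

1. **PMF estimation** (`pmf_forward`, `pmf_reverse`, `pmf_bidirectional`,
   `pmf_jarzynski`, `pmf_mean_work`) — turn steered-pulling work curves into
   free-energy profiles (potentials of mean force) with uncertainties.
2. **The indicator** (`adsorption_energy`, `extraction_barrier`,
   `g0_from_series`, `cin2d`, `classify_regime`, `phase_diagram`) — extract
   g_h, g_t and g0 from profiles, compute CIN2D, classify, and draw the
   regime phase diagram.
3. **A synthetic pulling generator** (`model_potential`, `pull_protocol`,
   `simulate_pull`, `make_bidirectional_set`) — an overdamped Langevin
   surrogate for steered MD on model free-energy landscapes, used to
   exercise the estimators end to end with known ground truth.
4. **I/O and a CLI** (`read_work_curves`, `write_profile`,
   `write_report_json`, `run_indicator`, `cin2d_main`) — TSV/CSV/LAMMPS-style
   work and force files, JSON reports, YAML-configured runs, and a `cin2d`
   shell command with `simulate`, `estimate-pmf`, `indicator`, `classify`
   and `diagram` subcommands.

## Worked example

### Classifying reported nanosheets

`nanosheet_energies()` ships literature-reported (g_h, g_t) pairs for six
nanosheet faces. Classify them against the POPC resistance:

```r
library(cin2d)

r <- classify_regime(nanosheet_energies(), g0 = 75, temperature = 310)
tidy(r)[, c("material", "cin", "cin_sd", "regime", "confident")]
#> # A tibble: 6 × 5
#>   material                cin cin_sd regime           confident
#>   <chr>                 <dbl>  <dbl> <fct>            <lgl>
#> 1 GN                    89     13    lipid_extraction TRUE
#> 2 GON                   11     18    insertion        FALSE
#> 3 Mg/Al-LDH             -3.5    1.52 adsorption       TRUE
#> 4 Aloohene              -5.17   1.35 adsorption       TRUE
#> 5 BNN (PAC +/- 1.05 e)  95     15    lipid_extraction TRUE
#> 6 BNN (PAC +/- 0.5 e)  102     11    lipid_extraction TRUE
```

Graphene (GN) and the charged boron nitride faces are predicted to extract
lipids; the layered double hydroxide and aloohene merely adsorb; graphene
oxide (GON) lands in the insertion window but its uncertainty (±18 on a CIN
of 11) straddles zero, so the call is flagged not confident.

The membrane resistance itself:

```r
glance(g0_from_series(popc_extraction_series()))
#> # A tibble: 1 × 3
#>      g0 argmin_n n_sizes
#>   <dbl>    <int>   <int>
#> 1  74.8        3       3
```

`plot_diagram(phase_diagram(r))` draws the four regimes in the (g_t, g_h)
plane with the materials placed as uncertainty ellipses.

### From pulling simulations to g_h

The same numbers can be produced from raw pulling data. Here the synthetic
generator stands in for steered MD: a particle in an adsorption well of
depth −50 kJ/mol (true minimum −49.94 at ξ = 4.00 Å) is pulled at the study
protocol (spring 1000 kJ/(mol·Å²), velocity 1e-4 Å/ps, 310 K), two pulls
per direction:

```r
pot    <- model_potential("adsorption_well", well_depth = -50)
proto  <- pull_protocol(xi_start = 12, xi_end = 2)      # study defaults
curves <- make_bidirectional_set(pot, proto, n_forward = 2, n_reverse = 2,
                                 seed = 2024)
prof   <- pmf_bidirectional(curves)
prof
#> <free_energy_profile> 200 points, xi in [2, 12] A, min dG = -49.5 kJ/mol,
#>   4 replicate(s), estimator: bidirectional

adsorption_energy(prof, "head")
#> # A tibble: 1 × 4
#>   moiety value    sd xi_min
#>   <chr>  <dbl> <dbl>  <dbl>
#> 1 head   -49.5 0.265   4.01
```

The estimator recovers the well depth and location from four pulls. Feed
one such `value`/`sd` pair per face into `cin2d()`:

```r
cin2d(g_h = -14, g_t = -103, g_h_sd = 2, g_t_sd = 11)
#> # A tibble: 1 × 2
#>     cin cin_sd
#>   <dbl>  <dbl>
#> 1    89     13
```

`autoplot(prof)` plots the profile with its uncertainty band.

### Shell interface

The same pipeline from the command line (the `cin2d` script is installed
under the package's `exec/` directory):

```sh
cin2d simulate --potential adsorption_well --depth -50 --velocity 0.02 \
      --n-forward 2 --n-reverse 2 --seed 1 --out curves/
cin2d estimate-pmf --inputs 'curves/*.tsv' --estimator bidirectional \
      --out profile.tsv
cin2d classify --gh -14 --gh-sd 2 --gt -103 --gt-sd 11 --g0 75 --temp 310
```

`cin2d indicator --config run.yaml` runs the whole head+tail workflow from a
YAML configuration and writes a JSON report plus both profiles and a
phase-diagram file.

## Scope and caveats

The Langevin generator is a one-dimensional overdamped surrogate: it
reproduces the statistics that matter for work-based estimators
(near-equilibrium Gaussian work at slow pulling, dissipation growing with
speed, Boltzmann-distributed trap fluctuations) but does not emulate
atomistic detail — no explicit lipids or water, no membrane deformation, no
friction profile along ξ. Reported adsorption energies in
`nanosheet_energies()` are literature values, not recomputed here; `g0` is
membrane- and temperature-specific and is exposed as a parameter throughout.
See the methods vignette (`vignettes/cin2d-methods.Rmd`) for the model,
estimator derivations, and parameter rationale.

## License

MIT — see `LICENSE`.
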