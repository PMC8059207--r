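# dnacondense

How does the length of a DNA molecule decide whether it condenses, and
what kind of condensate it forms? `dnacondense` is an R package for
researchers studying biomolecular condensates of DNA (crowding/cation
induced, linker-histone induced, or chromatinized). It bundles two
things that usually live in separate scripts:

* **Theory.** The Post–Zimm extension of Flory–Huggins theory for DNA
  solutions: the free energy per lattice site

  $$g(\phi,\alpha)=(1-\phi)\ln(1-\phi)+\tfrac{\phi}{N}\ln\phi+\chi\phi(1-\phi)+\tfrac{\phi}{N}A(\alpha),$$

  where the internal single-chain term
  $A(\alpha)=N[(\chi-1)+B_2\omega/(2^{3/2}\alpha^3)+B_3\omega^2/(2\cdot3^{5/2}\alpha^6)]+\tfrac32(\alpha^2-1)-3\ln\alpha$
  couples the coil–globule expansion factor $\alpha$ to the virial
  coefficients $B_2=1/2-\chi$ and $B_3(\chi,q)$. From it the package
  computes single-chain collapse (`expansion_alpha`, global minimum of
  the degree-8 stationarity polynomial over $0\le\alpha\le1.5$),
  chemical potentials, coexisting dilute/dense concentrations by
  chemical-potential equality (`binodal_point`), and full
  length-resolved phase diagrams with the collapse line
  (`phase_diagram`).

* **Measurement.** The analysis pipeline for condensate experiments:
  FRAP normalization and fitting of $\mathrm{FRAP}(t)=a(1-e^{-kt})$
  (`normalize_frap`, `fit_frap`), condensate segmentation and the
  radial aspect-ratio statistic $(R_{max}-R_{min})/(R_{max}+R_{min})$
  (`segment_condensates`, `aspect_ratio`), complete-linkage clustering
  of conditions into liquid-like / intermediate / solid-like classes
  (`classify_conditions`, `annotate_phase_diagram`), and two-channel
  trace extraction, exponential-decay fitting and intensity-based
  molecule counting for surface-anchored condensates under flow
  (`extract_traces`, `fit_decay`, `count_molecules`).

A first-class synthetic-data module (`gen_frap`, `gen_shapes`,
`gen_flow_stack`, `gen_condition_grid`) generates every input with
known ground truth, so the whole pipeline is testable end to end
without microscopy data, and `run_pipeline()` ties the stages into a
reproducible, provenance-stamped run. The methods vignette
(`vignettes/dna-condensation-methods.Rmd`) documents the model, the
parameter choices and the numerical design.

## Worked example

Coexistence for a 2.5 kb and a 200 bp chain in a poor solvent
($\chi = 0.7$):

```r
library(dnacondense)

dna_chain(2500)
#> <dna_chain> 2500 bp | M = 1.625e+06 g/mol | N = 406.2 | omega = 3.775e-06 | <h0^2> = 5.014e-08 cm^2

binodal_point(dna_chain(2500), 0.7)
#> <binodal_point> chi = 0.7 | c_dilute = 1.526e-07 g/mL | c_dense = 0.7231 g/mL | alpha_dilute = 0.01537

binodal_point(dna_chain(200), 0.7)
#> <binodal_point> chi = 0.7 | c_dilute = 0.1565 g/mL | c_dense = 0.4105 g/mL | alpha_dilute = 1
```

The 2.5 kb chain is already collapsed at this solvent quality
(`alpha_dilute` ≈ 0.015, a compact globule) and phase-separates at
~0.15 µg/mL, while the 200 bp chain is still a coil (`alpha_dilute`
= 1) and needs ~157 mg/mL — a six-orders-of-magnitude difference in
critical concentration from a 12.5-fold difference in length. Both
dense phases sit at a few hundred mg/mL, as expected for a DNA-rich
condensate.

Fitting a synthetic FRAP curve from the fast (short-DNA, PEG/Mg)
regime:

```r
cv <- gen_frap(preset = "psi_short", seed = 1)   # truth: a = 0.66, k = 1/99
fit_frap(cv)
#> <frap_fit> mobile fraction a = 0.659 | k = 0.01015 1/s | t1/2 = 68.3 s | residual sd = 0.0193
```

Measuring shapes (one disc, one 2:1 ellipse, one irregular aggregate;
the disc reads ≈ 0, the ellipse ≈ 1/3, the aggregate is clearly
irregular):

```r
sh <- gen_shapes(n_discs = 1, n_ellipses = 1, n_blobs = 1, seed = 3)
condensate_shapes(sh$image)[, c("label", "area", "aspect_ratio")]
#>   label area aspect_ratio
#> 1     1 2817   0.01694915
#> 2     2 1213   0.68373920
#> 3     3 2505   0.34713054
```

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each a thin
script over the package that prints what it found and writes tidy
tables under `results/`:

| script | what it computes |
|---|---|
| `01_theory_phase_diagrams.R` | α(χ) curves, binodal branches and collapse line for 200 bp – chromosome-scale chains; the worked χ = 0.7 predictions |
| `02_frap_recovery.R` | 200-replicate Monte-Carlo FRAP recovery per mobility regime with bias summary |
| `03_morphology_clustering.R` | shape-recovery table and the clustered length–concentration phase diagram |
| `04_flow_stability.R` | registered trace extraction, decay-model selection and molecule counting on a synthetic flow experiment |

Run them from the repository root, e.g.
`Rscript analysis/01_theory_phase_diagrams.R`.

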