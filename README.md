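# cystkit

Phytocystatins are plant proteins of the cystatin superfamily: reversible,
competitive, tight-binding inhibitors of C1A cysteine proteases (papain,
human cathepsins B and L). They dock into the protease cleft through a
tripartite wedge — an N-terminal region with a conserved Gly-Gly, a central
β-hairpin loop with the Q-x-V-x-G motif, and a C-terminal loop with a
tryptophan (usually P-W, sometimes A-W). A subfamily carries a C-terminal
cystatin-like extension with an S-N-S-L motif that adds legumain (C13)
inhibition. Because some of these proteins bind hydroxyapatite and inhibit
the cysteine cathepsins that degrade demineralised dentin collagen, they
are candidates for protecting tooth enamel and dentin against erosive
wear.

cystkit is an R toolkit for the full computational side of characterising
such inhibitors, aimed at people mining transcriptomes for protease
inhibitors and at labs analysing inhibition assays and erosion
experiments:

* **Discovery** — six-frame ORF extraction from assembled contigs
  (initiation *and* termination codon required), a PROSITE-style degenerate
  motif engine, an ordered three-motif screening rule
  (GG → QxVxG → [PA]W within configurable spacing windows) with enumerated
  rejection reasons, C-terminal extension and SNSL detection, group A/B/C
  classification from the phytocystatin N-terminal helix signatures
  (L-A-R-F-A-V-[DEQ]-E-H-N vs I-G-E-F-A-V-D-[EA]-Y-N), and molecular
  weight / isoelectric point (Bjellqvist pKa, bisection).
* **Grouping** — p/Poisson distances from an external alignment, a
  neighbor-joining tree (negative branches clamped), and a k-group cut on
  the longest internal edges.
* **Inhibition kinetics** — apparent inhibition constants from slope
  titrations via the through-origin fit of V0/Vi − 1 = [I]/Kiapp, substrate
  correction Ki = Kiapp/(1 + [S]/Km), per-replicate fits summarised as
  mean ± SD, presets with the papain / cathepsin B / cathepsin L assay
  constants, and a tight-binding diagnostic flag.
* **Erosion statistics** — %SMC = (SMbaseline − SMfinal)/SMbaseline × 100
  from six-indentation Knoop tables, Kolmogorov–Smirnov and Bartlett
  assumption checks, one-way ANOVA and Tukey HSD with a compact letter
  display.
* **Synthetic data with planted truth** — seeded generators for
  transcriptomes (group-specific cystatin scaffolds plus near-miss decoys),
  titration series and erosion experiments, each emitting a truth table so
  recovery can be tested exactly.

## Worked example

```r
library(cystkit)

# 1. simulate a transcriptome with planted cystatins, screen it
sim <- make_transcriptome(seed = 42, n_noise = 100, n_planted = 6,
                          group_mix = c(A = 2, B = 2, C = 2))
res <- screen_transcriptome(sim$contigs)
res$funnel
#> contigs    orfs  passes
#>     156      71       6
subset(res$annotations, pass)[, c("protein_id", "central_variant",
                                  "cw_variant", "group", "mw_da", "pi")]
#>          protein_id central_variant cw_variant group mw_da    pi
#>   planted_A_02|orf1           QVVSG         AW     A 10857 6.384
#>   planted_C_02|orf2           QVVSG         PW     C 10291 4.503
#>  planted_A_01|orf18           QVVAG         PW     A 16655 6.311
#>  planted_B_02|orf29           QVVSG         PW     B 10720 9.127
#>  planted_B_01|orf42           QVVSG         PW     B 10855 7.899
#>  planted_C_01|orf62           QVVSG         PW     C 10471 4.864
```

All six planted cystatins pass (none of the 50 decoy or noise ORFs do),
each with its planted group label; the extended group-A protein shows the
QVVAG central-loop variant of the extended subfamily, and one planted
protein carries the A-W relaxation of the C-terminal motif.

```r
# 2. Ki from a simulated noisy triplicate titration (cathepsin L preset)
setup <- assay_preset("cathepsin_L")
kin <- simulate_inhibition_series(seed = 42, true_ki_nM = 0.38, setup = setup,
                                  cv = 0.02)
est <- estimate_ki(kin$series)
#> Ki = 0.382 +/- 0.006 nM (Kiapp 1.91 nM, tight-binding flag: TRUE)
```

The planted 0.38 nM is recovered within noise. Kiapp = Ki × (1 + [S]/Km) =
0.38 × 5 = 1.9 nM with this preset ([S] = 8 µM, Km = 2 µM); the flag warns
that Kiapp is within ten-fold of the 3.5 nM enzyme concentration, where the
uncorrected linear fit approaches its tight-binding limit.

```r
# 3. erosion experiment replanted from the published enamel summaries
er <- simulate_erosion_experiment(seed = 42, erosion_reference("enamel"),
                                  n_per_group = 20)
stat <- tukey_cld(er$experiment)
#> ANOVA F(6,133) = 21.82, p = 9.48e-18
#>                 mean_smc letters
#> 0.1 MaquiCPI-3     21.89       b
#> 0.25 MaquiCPI-3    25.90       b
#> 0.5 MaquiCPI-3      2.30       a
#> 1.0 MaquiCPI-3     21.04       b
#> CaneCPI-5          19.11       b
#> Control            37.05       c
#> Elmex              22.63       b
```

Groups sharing a letter are not significantly different (Tukey, α = 0.05):
here the 0.5 mg/mL treatment is isolated as the best protector (lowest
%SMC, letter a), the untreated control is isolated as the most eroded
(letter c), and the remaining treatments are statistically
indistinguishable — the qualitative reading of the original enamel
experiment.

A thin command-line wrapper (`inst/scripts/cystkit-cli.R`) exposes the same
stages as subcommands (`simulate`, `screen`, `classify`, `tree`, `ki`,
`erosion`), each writing its artifacts plus a `manifest.json` that makes
the run byte-reproducible.

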