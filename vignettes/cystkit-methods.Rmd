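---
title: "Methods: phytocystatin mining, Ki estimation and erosion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phytocystatin mining, Ki estimation and erosion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystkit)
```

cystkit reimplements, as a tested pipeline, the three computational stages of
a phytocystatin characterisation study: (i) motif-based discovery and
classification of cystatin candidates in assembled transcriptome contigs,
(ii) estimation of tight-binding inhibition constants against cysteine
proteases from fluorogenic assay slopes, and (iii) surface-microhardness
statistics for dental-erosion protection experiments. Every stage has a
seeded synthetic-data generator that plants a known truth, so the whole
pipeline can be validated end to end without access to the original raw
data.

## Sequence screening

### ORF extraction

Candidates are sought in all six reading frames of each contig. An open
reading frame runs from an ATG to the first in-frame stop codon, and only
ORFs with *both* an initiation and a termination codon are kept — an ORF
truncated by the contig edge cannot be a complete precursor. By default one
ORF is reported per (frame, stop codon): the longest, i.e. the one starting
at the first ATG after the previous in-frame stop. Nested ATGs can be
reported by setting `longest_per_stop = FALSE`. Coordinates are 0-based and
half-open on the forward strand (BED-like), so the reported slice — reverse
complemented for minus-strand ORFs — always re-translates to the peptide
plus its stop.

The minimum peptide length defaults to 80 residues. Mature single-domain
phytocystatins are around 100 residues and known precursors run roughly 100
to 225, so 80 keeps every plausible precursor while discarding most random
ORFs; it is a configurable decision, not a biological constant. Codons
containing N translate to `X`, and `X` never satisfies a non-wildcard motif
position, so ambiguous sequence cannot create motif matches.

### The degenerate motif engine

Motifs are written in a dash-separated, PROSITE-like syntax
(`"Q-x-V-x-G"`, `"[LVI]-[AGT]-[RKE]-[FY]-[AS]-[VI]-X-[EDQV]-[HYFQ]-N"`).
`compile_pattern()` turns a pattern into an explicit list of allowed-residue
sets; `scan_motif()` reports every match, including overlapping ones, in
left-to-right order. The scanner is the package's own (a compiled regular
expression with a look-ahead so overlaps are visible); its contract is
equality with a position-by-position brute-force oracle, which the test
suite and the acceptance script enforce on thousands of random
(protein, pattern) pairs.

### The screening rule

A protein passes the phytocystatin screen when it carries, in order along
the chain, the three contact motifs of the tripartite wedge:

1. a Gly-Gly dipeptide in the N-terminal region,
2. the central loop `Q-x-V-x-G` within a spacing window downstream, and
3. the C-terminal `[PA]-W` within a second window.

The C-terminal motif is deliberately `[PA]-W` rather than `P-W`: real
cystatins exist in which the proline is replaced by alanine, and the
tryptophan is the functional residue. The N-terminal helix consensus of
phytocystatins and the SNSL legumain-inhibitory motif are recorded whenever
present but are never required — requiring the helix would reject genuine
divergent cystatins, and SNSL only marks the C-terminally extended
subfamily.

The source study lists the three motifs but not their spacings, so the
windows are package decisions calibrated on canonical phytocystatin
architecture (GG near residue 10, central loop near residue 50, W-loop near
residue 80 of the mature protein): the central loop must start 25–90
residues after the GG ends, and the `[PA]-W` 15–70 residues after the
central loop ends. Both windows are configurable through `screen_config()`
and recorded in the output. Anchoring is deterministic: the first GG after
the (optional, externally supplied) signal-peptide boundary is used, and
ties among candidate loop hits go to the leftmost hit inside the window.
Rejection is a value with a reason (`missing_gg`, `missing_central`,
`missing_cw`, `order_violation`, `window_violation`, `too_short`), which
makes the filter funnel auditable.

A C-terminal extension — the hallmark of the bifunctional, legumain
inhibiting subfamily — is called when at least 50 residues (inclusive)
follow the `[PA]-W` motif or when an SNSL motif lies downstream of it.

### Group classification

Screened proteins are assigned to the three groups seen in phytocystatin
phylogenies using the N-terminal helix signatures: group A for
`L-A-R-F-A-V-[DEQ]-E-H-N` (or any protein with a C-terminal extension,
since the extended cystatins sit inside that clade), group C for
`I-G-E-F-A-V-D-[EA]-Y-N`, and group B when the general helix consensus
matches but neither signature does. Anything else is `unclassified` rather
than forced into a group.

### Molecular weight and isoelectric point

`physchem_properties()` computes the average (not monoisotopic) molecular
mass as the sum of residue masses plus one water, and the pI as the root of
the net-charge function, found by bisection on pH 0–14 until the absolute
charge falls below 1e-4. Charges use the Bjellqvist pKa set in its common
simplified form (fixed N-terminal pKa 7.50 and C-terminal 3.55, side chains
D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0), with free termini.
The net charge is strictly decreasing in pH, so the root is unique;
sequences containing `X` have no defined mass or pI and are reported as
`NA`. An independent implementation (seqinr, with its own pKa compilation)
is used in the tests as an approximate cross-check only.

## Grouping by neighbor joining

The original analysis built a maximum-likelihood tree (WAG, gamma rates,
1000 bootstraps) whose initial tree came from neighbor joining, and read
three groups off it by eye. cystkit retains exactly the part of that
workflow needed for the partition: p-distances (or Poisson-corrected
distances, `-ln(1-p)`) from an externally produced alignment, a
neighbor-joining tree, and an automated cut. Columns with a gap in either
sequence are excluded pairwise from the distance denominator. The NJ
agglomeration itself is delegated to `ape::nj()` — neighbor joining is a
standard step, not this package's contribution — behind `nj_tree()`, which
additionally clamps any negative branch length to zero and shifts the
deficit to its sister edge so path lengths are preserved as far as
possible. On additive matrices NJ is exact, and the tests verify both the
path-length round-trip and, on 6-taxon problems, topological agreement with
an exhaustive least-squares search over all 105 topologies.

`cut_groups(tree, k)` removes the k−1 longest internal edges (ties broken
lexicographically by node pair) and returns the connected components. This
is an automated stand-in for the visual three-group reading of the original
tree: on simulated data with within-clade distances well below
between-clade distances it recovers planted clades exactly, but it is an
approximation of a judgment call, not a reproduction of it. Substitution
model fitting, bootstrapping and the alignment itself are out of scope;
any aligner producing FASTA can feed `pairwise_distance()`.

## Inhibition kinetics

The binding model is classical competitive tight-binding inhibition read
through reaction velocities: V0/Vi = 1 + [I]/Kiapp, with the substrate
correction Ki = Kiapp/(1 + [S]/Km). `fit_kiapp()` performs an unweighted
least-squares fit of y = V0/Vi − 1 against [I] *through the origin*,
because the model has no free intercept; Kiapp is the reciprocal slope, and
R² is reported on the transformed points. Fits are per replicate;
`estimate_ki()` averages the per-replicate Ki values and reports the sample
(n−1) standard deviation, the reading adopted for "mean ± uncertainty over
triplicates" (the alternative, a single pooled regression, is not what a
per-replicate ± can come from).

Units are fixed by convention — [I] and Ki in nM, [S] and Km in µM — and
converted only at parse time. The shipped presets carry the assay constants
of the source experiments: papain 10 nM enzyme, 2.5 µM substrate, Km 10 µM;
cathepsin B 1.9 nM, 20 µM, Km 23 µM; cathepsin L 3.5 nM, 8 µM, Km 2 µM.
With the cathepsin B preset the substrate correction divisor is
1 + 20/23 ≈ 1.870, and with papain exactly 1.25.

No Henderson depletion correction is applied — the source analysis used the
plain linear form — but `estimate_ki()` raises a `tight_binding_flag`
whenever the mean Kiapp falls below ten times the enzyme concentration,
the regime where free-inhibitor depletion starts to bias the uncorrected
fit. Progress-curve analysis, IC50 fitting and the Morrison quadratic are
out of scope.

The simulator inverts the same model (Vi = V0/(1 + [I]/Kiapp)) with
multiplicative Gaussian noise of coefficient of variation `cv` on every
slope and a per-replicate V0 drawn around a nominal slope. Default
titrations place six inhibitor concentrations spanning 0.3–10 × Kiapp.
Noiseless simulation followed by estimation returns the planted Ki to
floating-point accuracy (relative error below 1e-9 on all fifteen published
inhibitor × enzyme values), and at cv = 2% the median relative bias over
500 triplicate simulations is well below 5%. The published Ki table is a
*planted-truth input* for these recovery tests: the raw slope data behind
it are not deposited, so the table cannot be recomputed, only recovered
from simulations that assume it.

## Erosion statistics

The erosion endpoint is the percentage surface-microhardness change,
%SMC = (SMbaseline − SMfinal)/SMbaseline × 100, computed per sample from
the means of six baseline and six final Knoop indentations; positive values
mean softening. The statistical battery mirrors the original protocol:
per-group one-sample Kolmogorov–Smirnov tests against a normal with the
group's own mean and SD, Bartlett's homogeneity test, one-way ANOVA on
per-sample %SMC, and Tukey HSD (Tukey–Kramer under unequal n) at α = 0.05
(configurable). Whether the original KS ran on raw readings or per-sample
%SMC is not stated; per-sample %SMC is used here, consistent with the
ANOVA unit of analysis. Estimating the KS reference parameters from the
sample makes the plain KS anti-conservative (the Lilliefors issue); the
plain test is implemented as specified, with this caveat recorded.

ANOVA, KS, Bartlett and the Tukey p-values come from base R (`aov`,
`TukeyHSD`, `ks.test`, `bartlett.test`); the compact letter display is the
package's own insert-then-absorb construction, assigning letters in
ascending order of group mean. Its defining invariant — two groups share a
letter exactly when their Tukey-adjusted p is ≥ α — is asserted
property-style on random experiments in the test suite.

The experiment simulator draws each sample's target %SMC from its group's
planted Normal(mean, SD), draws baseline indentations around a
tissue-typical Knoop hardness (330 for enamel, 55 for dentin, with 5%
between-sample and 3% within-sample spread — realistic scales for polished
bovine substrates), adds indentation-level noise to the final readings and
then renormalises them so the per-sample %SMC equals its target exactly.
Planted SD = 0 therefore reproduces group means exactly, and the planted
group summaries are recovered to within sampling error otherwise. What the
generator does *not* emulate: correlated indentation errors, non-normal
%SMC distributions, and any within-day repeated-measures structure — so
passing recovery tests demonstrate the statistics pipeline, not robustness
to those real-data features.

Replanting the published enamel summaries (7 groups, n = 20) and asking the
CLD to isolate both the best-performing concentration and the control
reproduces the published reading in most but not all seeded replants
(roughly four out of five). That rate is the true statistical power of the
design under the printed means and SDs — the limiting comparison is the
control against the closest treatment group — and no generator parameter is
adjusted to inflate it. The dentin profile (three high-%SMC groups sharing
a top letter apart from the four protected groups) reproduces in a clear
majority of replants.

## The transcriptome generator

`make_transcriptome()` plants group-specific protein scaffolds (group A
helix ± SNSL-bearing extension, group C helix, group-B consensus-only
helix; central loop QVVAG for extended and QVVSG for unextended proteins,
occasional AW in place of PW), reverse-translates them with uniform
synonymous codon choice, and embeds them between random UTRs on a random
strand with an in-frame stop immediately upstream of the start codon, so
the ORF finder's longest-per-stop rule recovers exactly the planted
peptide. Spacer residues are drawn from a 16-letter alphabet excluding
G, N, Q and W, which makes spurious GG, QxVxG, [PA]W, SNSL or helix-consensus
matches impossible by construction — a deliberate idealisation that makes
recall/precision = 1 a meaningful correctness target rather than a
statistical outcome. Decoys follow a fixed taxonomy (central-loop fixed-
position knockout, GG knockout, C-terminal knockout, order violation,
window violation, shuffled positive, the last rejection-sampled to fail
the screen), so every rejection reason is exercised. Codon-usage bias and
realistic expression levels are deliberately not modelled; the screen
operates on translated peptides and is blind to both.

## Reproducibility and problem sizes

All generators are pure functions of (seed, parameters) and leave the
global RNG state untouched. The validation suite uses problem sizes chosen
to exercise each property at scale while staying quick: 500-contig
transcriptomes, 500 noisy titration simulations, 100 six-taxon NJ problems
against the exhaustive oracle, 1000 random scanner comparisons, and 100
seeded replants per erosion tissue. `scripts/acceptance.R --seed N --out f`
recomputes all of these from scratch with any seed.
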