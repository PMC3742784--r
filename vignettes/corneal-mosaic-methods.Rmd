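---
title: "Quantifying clonal mosaics and epithelial turnover in the mouse cornea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clonal mosaics and epithelial turnover in the mouse cornea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneamosaic)
```

## The biological setting

The adult corneal epithelium is maintained by limbal epithelial stem cells
(LESCs) at the corneal periphery. Their transient amplifying progeny migrate
centripetally in the basal layer, leave it for the suprabasal layers, and are
shed from the surface. In X-inactivation mosaic mice, each cell carries one of
two marker states, and the LESC clones around the limbal ring paint radial
stripes on the adult cornea. Three quantitative readouts follow:

1. **Mosaic patch statistics** in sections of the developing epithelium,
   before stripes emerge, measure how coarsely the two populations are mixed.
2. **Stripe numbers** around the adult cornea reflect the number of active
   LESC clones.
3. **BrdU pulse-chase labelling indices** and **label-retaining cell (LRC)
   counts** measure cell turnover and the slow-cycling (putative stem)
   population.

A coarser adult stripe pattern can mean either fewer stem-cell clones
(hypothesis 1) or less cell mixing during development, so that adjacent clones
share a marker state (hypothesis 2). The package implements the statistics
that distinguish these, and stochastic generators of both scenarios so every
statistic is validated by parameter recovery.

## Patches, clones and the 1/(1 − p) correction

A *coherent clone* is a contiguous group of cells descended from one
progenitor, hence sharing a marker state. A *patch* is a maximal run of
same-marker cells; adjacent same-colour clones merge into one patch. In a
one-dimensional string with labelled proportion $p$, the number of positive
clones inside a positive patch is geometric with mean

$$\mathbb{E}[\text{clones per patch}] = \frac{1}{1-p},$$

so the observed mean positive-patch length over-estimates the mean coherent
clone length by that factor. `corrected_mean_patch_length()` divides it out;
the result estimates the clone length itself and is (unlike the raw patch
length) insensitive to $p$. The same correction applied to stripe counts,
`corrected_stripe_number()` $= S/(1-p)$, converts an observed stripe count $S$
into an estimate of the number of *labelled* stem-cell clones: on a ring of
$K$ clones each labelled with probability $p$,

$$\mathbb{E}[S] = K\,p\,(1-p), \qquad
  \mathbb{E}[S]/(1-p) = K\,p .$$

Dividing further by $p$ estimates the total clone number; because that second
step goes beyond the published adjacency correction it is exposed separately
as `total_clone_number()`.

### The ring stripe-counting convention

On a ring we count stripes as (negative → positive) boundaries, so a
monochrome all-positive ring counts 0 stripes. This matches what an observer
can count — a uniform cornea shows no stripe boundaries — and it makes the
identity $\mathbb{E}[S] = K p (1-p)$ *exact* for every $K$ (verified to
$10^{-12}$ by full enumeration in `ring_run_enumeration()`). Had we counted
maximal runs instead, the all-positive labeling would contribute one run and
the expectation would pick up an extra $p^K$ term. `extract_patches()`, by
contrast, keeps the literal run decomposition (an all-positive circular
sequence is one patch), because patch statistics describe the realised
sequence rather than a boundary count; the two conventions are deliberate and
documented. "Clones per patch" is matched to the oracle as a ratio of
expectations, $\mathbb{E}[\#\text{clones}]/\mathbb{E}[\#\text{stripes}]$; the
expectation of the per-labeling ratio is undefined on monochrome rings.

```{r enumeration}
en <- ring_run_enumeration(12, 0.4)
c(expected_stripes = en$e_runs, closed_form = 12 * 0.4 * 0.6,
  clones_per_patch = en$clones_per_patch)
```

### Tie-breaks and degenerate inputs

* The minority population (for the uncorrected median patch length) is the
  one with proportion below 0.5; at exactly $p = 0.5$ we take the population
  with fewer patches, and if that also ties, the negative population. The
  rule is arbitrary but deterministic and recorded with the result.
* $p = 1$ (for patch corrections) and $p \in \{0, 1\}$ (for stripe
  corrections) raise explicit errors instead of returning infinities: a
  monochrome mosaic carries no information about clone boundaries.
* `p` defaults to the observed labelled fraction of the same sequence, as
  patch scoring does in practice; a supplied group-level value is accepted
  and its provenance recorded (`p_source`). For stripe corrections the
  per-eye proportion is the default reading.

## The mosaic generator

`generate_mosaic()` tiles a line or ring with coherent clones whose lengths
are geometric with mean `clone_len_mean` — the simplest one-parameter positive
length law, chosen because it reduces *exactly* to i.i.d. Bernoulli cells at
mean 1 (complete mixing). Each clone is labelled with probability `p`
independently. On rings the final clone is truncated to close the tiling and
remains distinct from the first clone even when both carry the same colour.
The generator returns its internal clone boundaries (`clone_id`), so tests can
recover `clone_len_mean` from the corrected patch statistics and compare
against ground truth rather than against the estimator itself.

The geometric-clone model is a stand-in for developmental cell mixing, not a
mechanistic claim: no published quantitative mixing model exists for this
tissue. What passing recovery tests show is that the *estimators* are
consistent for sequences with geometric clone structure at realistic sizes
($10^5$ cells within 5%); real sections are far shorter (a few hundred basal
cells), where the same estimators are unbiased but noisy, which is why
analyses pool eyes per group.

## Stripe simulation and the two hypotheses

`simulate_ring()` draws rings of `K` clone labels. Reduced mixing is modelled
by `mixing_clusters = m`: the ring is cut into `m` contiguous blocks, each
receiving a single label draw, so adjacent clones within a block are
perfectly correlated — the operative feature of the coarse-mosaic hypothesis
— while `m = K` is full mixing. The radial geometry of the cornea is not
simulated: every reported statistic is a function of the ring sequence.

`hypothesis_experiment()` contrasts a reduced-clone-number scenario with a
reduced-mixing scenario matched for expected stripe count (e.g. $K = 20$ at
full mixing vs $K = 40$ in 20 blocks, both giving $\mathbb{E}[S] = 5$ at
$p = 0.5$). The discriminating statistic is developmental: sections simulated
with `generate_mosaic()` whose clone length is multiplied by the coherence
factor $K/m$ under reduced mixing and untouched under reduced clone number.
At 1000 replicates the two corrected-mean-patch-length distributions are
nearly disjoint (Kolmogorov–Smirnov distance ≈ 0.95), which is the
computational restatement of the argument that equal stripe counts cannot by
themselves distinguish the hypotheses, while pre-stripe patch data can.

Age-related coarsening is modelled by `moran_drift()`: neutral Moran
competition (one random position replaced by a copy of a random neighbour per
step; one generation = `K` steps). Labels coalesce, so the expected corrected
stripe number declines monotonically — clone *number* can fall with age
without any loss of stem-cell function.

## The pulse-chase cohort model

`generate_cohort_timecourse()` is a discrete-time stochastic compartment
model: basal cells divide (both daughters basal, so each division adds one
cell), exit to suprabasal layer 1, advance one layer per `transit_days`, and
shed from the outermost layer. Label is diluted by division and becomes
undetectable after `dilution_limit` divisions. The suprabasal compartment
starts filled with the resident unlabelled population; without it the
suprabasal labelling index would have no meaningful denominator early in the
chase.

Default parameters (all per-day probabilities, chosen once as a
wild-type-like mid-section and documented here):

| parameter | default | rationale |
|---|---|---|
| `n_basal` | 424 | basal cells across a WT mid-section diameter |
| `n_suprabasal` | 669 | resident suprabasal cells in the same section |
| `n_layers` | 4 | WT epithelium has 4–6 suprabasal layers |
| `div_rate` | 0.3/day | equal to the exit rate: near-homeostatic basal layer |
| `transfer_rate` | 0.3/day | gives a day-1 suprabasal labelled fraction ≈ 18% |
| `transit_days` | 1 | label clears the 4 layers within about a week |
| `label_frac0` | 0.12 | acute-pulse basal labelling index ≈ 12% |
| `dilution_limit` | 2 | label undetectable after two divisions |

Setting `div_rate = transfer_rate` makes the basal layer near-homeostatic
(production balances loss, the stem/TAC/loss balance of a stable epithelium);
a small residual drift (< 1%/day) remains because the division and exit draws
are coupled within a step. Under these defaults the labelled suprabasal
cohort rises to a day-3 peak and ≥ 98% of the label is shed by day 14, so the
turnover-time bound of `estimate_turnover_time()` (first post-peak time below
10% of the peak labelled count; the 10% is a documented knob, and a cohort
that never declines is returned as right-censored rather than an error) comes
out at ≤ 14 days. A faster-loss group is modelled by raising `transfer_rate`
alone (0.6/day in the shipped analyses — double the reference, mirroring the
roughly twofold difference in day-1 suprabasal fractions between the
genotypes being emulated).

Time runs in uniform 4-hour steps for every query. One uniform step size
(rather than day-steps for day-scale queries and finer steps only for the 4-h
point) keeps a single bookkeeping path; conservation —
basal + suprabasal + shed = initial + cumulative divisions — is exact at every
step and asserted in the tests.

### Labelling indices

`labelling_indices()` computes, per region and whole-eye:
BLI $= 100\,b^+/b$, SLI $= 100\,s^+/s$, and the adjusted index
ASLI $= 100\,s^+/b$ with the *basal* denominator, which removes the
dependence on how many suprabasal layers an epithelium has. The identity
$\mathrm{ASLI}/\mathrm{SLI} = s/b$ holds exactly on every table and is what
justifies the adjustment when comparing epithelia of different thickness.
The six-region partition splits the ordered cells into six contiguous groups
(outer two → P, next two → I, middle two → C) by largest-remainder
allocation, extra cells going to the outermost groups symmetrically
(order 1, 6, 2, 5, 3, 4). Regional pooling is count-weighted by default
(robust to unequal group sizes); an unweighted mean of the two group indices
is available for strict fidelity to "one mean value per eye", since the
original description does not state whether regional means were
cell-weighted. `suprabasal_fraction()` is $100\,\mathrm{SLI}/(\mathrm{SLI} +
\mathrm{BLI})$ (or with ASLI), the share of labelled cells that have left the
basal layer.

## LRC quantification

`detect_nuclei()` thresholds a calibrated projection image (Otsu by default,
with a manual override since the original ImageJ threshold is unnamed),
labels 8-connected components, and keeps particles of 150–5000 px — the
window that corresponds to 3–15 µm equivalent nucleus diameters at ≈ 0.2
µm/px. "Voxels" in the original size filter are treated as pixels of the
maximum-intensity projection, since counting is done on projected single
images. Components are not split: touching nuclei would be counted once
(no watershed), a documented limitation; the synthetic fixtures place
non-touching nuclei.

Box counting (`count_in_box()`) uses centroid membership with half-open
bounds $[x_0, x_0+340) \times [y_0, y_0+200)$ µm so adjacent sector boxes
never double-count. `per_circumference()` extrapolates the mean per-box count
by circumference/340 µm, with the circumference taken as $\pi$ times the mean
of three diameter measurements; when boxes tile the circumference exactly the
extrapolation returns the true total, which the tests assert.
`lrc_index()` normalises group means within each experiment to percentages of
the four-group sum (rows sum to 100 exactly), which removes per-experiment
staining variability — and, by construction, any information about absolute
counts; experiments missing one of the four groups are excluded with a
warning.

The image generator renders nuclei as soft-edged disks (a hard disk convolved
with a 0.5 µm Gaussian edge) rather than plain Gaussian spots: the
thresholded area of a Gaussian spot varies several-fold with the threshold,
whereas a soft disk keeps the particle area within a few percent of
$\pi(d/2)^2$ for any threshold well inside the dynamic range, so the size
filter behaves predictably. Synthetic fields make no attempt at real
confocal optics, staining variability or 3-D stacks; perfect recall/precision
on them validates the component pipeline and the size filter, not performance
on real immunofluorescence.

## Problem sizes and determinism

All randomness flows from a single integer seed per generator call
(`with_seed()` restores the caller's RNG state, and child streams are derived
arithmetically), so identical seeds give identical outputs. The shipped
analyses and validation use: full enumeration up to $K = 14$ ($2^{14}$
labelings); $10^4$ ring replicates for clone-number recovery; $10^5$-cell
sequences for clone-length recovery; $10^3$ replicates for the hypothesis
contrast; 500 paired cohort runs for the direction test; and 50 synthetic
512×512 fields for detection fidelity. These sizes give Monte-Carlo errors
well below the effect sizes being demonstrated.

## Known limitations

* The geometric-clone mosaic and block-correlated ring are phenomenological;
  they reproduce first-order run statistics, not tissue mechanics.
* Clones are atomic units: the number of stem cells per clone (which the
  ring model deliberately leaves out) cannot be estimated from these
  statistics.
* The cohort model has no circadian structure and treats positions
  independently, so it cannot reproduce regional gradients unless
  parameterised per position.
* Nucleus detection assumes non-touching nuclei and a global threshold;
  dense fields or uneven illumination require segmentation beyond the scope
  here.
* Whether the stripe correction should target labelled clones ($S/(1-p)$) or
  total clones ($S/(p(1-p))$) is ambiguous in the descriptive literature;
  the labelled-clone reading is primary here and the total-clone estimate is
  exposed under its own name.
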