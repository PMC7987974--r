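---
title: "Modeling and quantifying aminoglycoside-induced translation error clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying aminoglycoside-induced translation error clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agaclust)
```

## The problem

Aminoglycoside antibiotics (AGAs) bind the decoding site of the bacterial
ribosome and induce misreading of near-cognate codons. Shotgun and targeted
proteomics can detect the resulting missense peptides and quantify, for each
amino-acid substitution, an *error frequency*

$$E_f = \frac{I_{\mathrm{missense}}}{I_{\mathrm{parent}}},$$

the ratio of the integrated MS intensity of the substituted tryptic peptide
to that of its correct parental peptide. A striking feature of AGA-treated
cells is the appearance of *error clusters*: peptides carrying two or more
substitutions, at frequencies orders of magnitude above the product of the
single-substitution frequencies. The mechanistic interpretation is that a
single drug molecule stays bound to the ribosome over several elongation
cycles, so that once a first misreading event has occurred, subsequent codons
are decoded by a still-perturbed ribosome.

This package provides (i) a generative two-state Markov model of elongation
that produces peptide-level intensity data with exactly this structure, and
(ii) the estimators needed to quantify it: single and cluster error
frequencies, error amplification, the conditional next-error frequency
$E_f^{\mathrm{next}}$, distance-dependence profiles, and the exponential
retention fit. Because raw MS data are not needed to exercise any estimator,
the generator doubles as the package's test bed: every statistic is validated
by parameter recovery against the presets that generated the data.

## The two-state elongation model

A ribosome traversing an mRNA of $L$ codons is in one of two states at each
codon: drug-bound ($B$) or unbound ($U$). Three probabilities govern the
chain:

* $\beta$ — per-codon binding probability. Binding can occur at any codon and
  rebinding after drop-off is allowed. $\beta$ scales linearly with the
  nominal drug concentration ($\beta = \beta_{\mathrm{scale}} \times c$),
  which makes single-error frequencies dose-dependent while leaving
  bound-state properties unchanged.
* $q$ — retention probability: after each translocation the drug stays bound
  with probability $q$. This single number controls how far error clusters
  extend.
* $m_i$ — bound-state misreading probability at codon $i$: the probability
  that a bound ribosome misincorporates the designated substitution at that
  codon. Unbound ribosomes misincorporate it at a baseline rate
  $\varepsilon_0$.

Only a designated set of positions (the substitutions being monitored) can
err; all other codons decode correctly. This keeps the outcome space
enumerable — exactly the situation of a targeted MS assay that monitors a
fixed panel of missense species — and makes the probabilities of all $2^k$
error patterns over $k$ designated positions sum to one.

`pattern_probability()` computes the exact probability of any pattern by a
forward dynamic program over the two states; the unit tests verify it to
$10^{-12}$ against brute-force enumeration of all bound/unbound state paths
on short proteins. `sample_counts()` turns probabilities into per-species
counts, by default drawing from a Poisson law with mean
$N \times p_{\mathrm{pattern}}$ where $N$ is the number of effective
traversals; an explicit per-ribosome Monte Carlo mode cross-validates the
rate mode at small $N$. `emit_intensity_table()` adds log-normal technical
noise and a detection floor and attaches condition metadata, yielding the
long-format intensity tables every estimator consumes.

### What the ratio estimator actually measures

Let $g(d{+}1)$ be the probability that a ribosome bound at the first error
position is still (or again) bound $d{+}1$ translocations later, where $d$
is the number of correct residues between the two errors; with negligible
rebinding $g(d{+}1) = q^{d+1}$. Writing
$c = g(d{+}1)\, m_2$ for the conditional probability of the second error,
the two peptide species that enter the ratio estimator are

$$P(\text{first error only}) \propto m_1 (1 - c), \qquad
  P(\text{cluster}) \propto m_1 c,$$

because the single-first-error species requires the second codon to decode
*correctly*. The measured ratio is therefore

$$E_f^{\mathrm{next}} = \frac{E_f^{\mathrm{cluster}}}{E_f^{\mathrm{1st}}}
  = \frac{c}{1 - c},$$

not $c$ itself. The distinction is negligible for weakly clustering drugs
($c \approx 0.05$) but matters for the strongly clustering ones
($c \approx 0.3$). The preset tables specify the *observable*
$E_f^{\mathrm{next}}$ at a stated anchor distance, and
`efnext_to_misread()` back-solves the microscopic rate by inverting the
full expression,

$$m_2 = \frac{E_f^{\mathrm{next}} / (1 + E_f^{\mathrm{next}})}{q^{d+1}},$$

so that simulations reproduce published observables rather than assumed
microscopic rates. The closed form (including the rebinding correction to
$g$) is verified against the dynamic program to $10^{-12}$ in the test
suite.

### Distance convention

$d$ counts the correct residues between consecutive errors: adjacent
substitutions have $d = 0$, and $d + 1$ translocations separate the two
decoding events. The first error of a cluster is its N-terminal-most
substitution — translation is vectorial, so the first error is decided
before any later one.

## Drug presets

The shipped preset table (`aga_presets()`, stored as JSON under
`inst/extdata/`) anchors each drug to published observables: streptomycin
(Str) with $q = 0.97$ and anchors $E_f^{\mathrm{next}} = 0.08$ at $d = 2$
and $0.05$ at $d = 1$; paromomycin (Par) $q = 0.9$, $0.09$ at $d = 1$;
apramycin (Apr) $q = 0.5$, $0.25$ at $d = 1$; sisomycin (Sis) and
kanamycin A (KanA) $q = 0.5$ with adjacent-cluster anchors $0.40$ and
$0.36$; and a generic `groupII` preset ($q = 0.5$, $0.40$ at $d = 0$). The
$q$ values for the group II drugs sit at the centre of the 0.3–0.7 range
that exponential distance fits return; the near-flat Str ($0.97$) and
weakly decaying Par ($0.9$) values are this package's own choices
consistent with those drugs' flat profiles, and are marked as such in the
preset file.

## Study conditions of the generator

The defaults of `sim_config()` and the titration wrapper define the
conditions every recovery experiment runs under; they were fixed once, on
the following grounds:

* **Titration 0.5–8 µM, 5 points.** Standard working range for
  streptomycin-class drugs in *E. coli*, with maximal misreading around
  8 µM; a 16-fold span gives the ≥ 10-fold range of first-error frequencies
  needed to demonstrate dose invariance of $E_f^{\mathrm{next}}$.
* **Binding scale $10^{-5}$ per µM per codon.** Gives Str-like occupancies
  that put single-error frequencies near $10^{-3}$ at the top dose, the
  upper end of observed substitution frequencies.
* **$N = 10^8$ effective traversals per condition.** The effective copy
  number behind a deep targeted MS measurement of an abundant protein;
  rare-cluster species then carry hundreds to thousands of counts.
* **First-position bound misreading $m_1 = 0.5$.** The first error simply
  marks where bound-state decoding failed; $m_1$ cancels from every
  conditional statistic, so its exact value is immaterial.
* **Baseline error $\varepsilon_0 = 10^{-6}$ per codon** for the designated
  substitution without drug — the order of magnitude of basal missense
  errors at a specific site. Ram-mode (error-prone ribosome mutants)
  simulations raise this to the configured `ram_rate` while keeping errors
  independent.
* **Log-normal noise CV 0.05, 3 technical replicates.** Typical integrated
  peak-area reproducibility of targeted (PRM-style) quantification on
  clean transitions, and the usual technical triplicate design.
* **Detection floor 1** on the arbitrary intensity scale (one traversal
  count): species drawn at zero counts become missing values, as in real
  tables, and missing missense intensities are treated as upper limits at
  the floor — never as zeros.

### Untreated controls and background correction

With $\varepsilon_0 > 0$, baseline errors contribute to the
single-first-error species at every dose; at low doses this measurably
dilutes the cluster/first ratio. Real analyses guard against exactly this
with untreated-cell controls and induction filtering, so the pipeline does
the same: `simulate_cluster_titration()` emits an untreated control table
by default, and `efnext_from_tables()` subtracts each species' control
frequency before forming ratios (`induction_filter()` implements the
two-fold consistency rule for discovery-style tables). Estimates are
clipped at zero rather than allowed to go negative.

## Estimators

* `compute_ef()` — per-replicate intensity ratios, aggregated by the
  median; median-of-correct-peptides fallback when the parental peptide is
  not detected; upper-limit flags for floor-imputed values.
* `stochastic_expectation()`, `amplification()` — the independence
  expectation $\prod_i E_{f,i}$ and the amplification
  $A = E_f^{\mathrm{cluster}} / (E_f^{\mathrm{1st}} E_f^{\mathrm{2nd}})$,
  with the identity $A = E_f^{\mathrm{next}} / E_f^{\mathrm{2nd}}$ checked
  to $10^{-12}$ on every cluster record.
* `efnext_slope()` — across titrations or time courses,
  $E_f^{\mathrm{cluster}}$ is regressed on $E_f^{\mathrm{1st}}$ *through
  the origin*: with no first error there can be no cluster. The intercept
  treatment is a deliberate design choice; a free intercept would absorb
  part of the signal at the few-point sizes typical here.
* `efnext_ratio()`, `efnext_lfq()` — point estimators from absolute
  quantification and from label-free intensities. The LFQ route refuses
  clusters that alter the tryptic cleavage pattern and flags following
  errors that change the charge-state class (gain/loss of K, R or H),
  where intensities stop tracking abundances.
* `build_distance_profile()` — normalizes per-cluster
  $E_f^{\mathrm{next}}$ values to the flat-profile reference drug at the
  matched distance (cancelling peptide-specific ionization and
  detectability), aggregating multiple clusters per distance as mean ± SD.
  Whether curves should additionally be rescaled to 1 at their smallest
  distance is genuinely open; both conventions are implemented
  (`scaling = "reference"`, the default, and `"per_aga"`).
* `fit_retention()` — nonlinear least squares of $N(d) = c\,q^d$ with $q$
  constrained to $[0, 1]$ (Levenberg–Marquardt with box bounds). The
  exponent is $d$, not $d + 1$, because the profile is already a ratio to
  the reference at matched $d$ and the shared offset cancels. Uncertainty
  is a parametric bootstrap over the points' SDs (200 resamples, seeded).
  A perfectly flat profile is reported as $q = 1$ with the CI truncated at
  1 and a degeneracy flag.
* `classify_aga()` — the two-group rule: drugs with high adjacent
  $E_f^{\mathrm{next}}$ (≥ 0.2 by default) are group II (apramycin-like:
  moderate single errors, intense local clusters, steep distance decay);
  drugs below the cutoff with appreciable single-error potency are group I
  (streptomycin-like: strong singles, near-flat profiles). Cutoffs are
  configurable; drugs with neither signal are left unclassified.

## Genetic-code layer

`enumerate_near_cognate()` lists the nine single-nucleotide variants of any
sense codon; `classify_substitution()` assigns a substitution to the 3rd,
1st or 2nd codon position with the priority 3rd > 1st > 2nd when several
positions could produce it (third-position misreading dominates under
AGAs), and labels two-change substitutions non-cognate so they can be
excluded from statistics. Isoleucine and leucine are distinct residues
internally; `collapse_ile = TRUE` provides the mass-degenerate reporting
mode, since standard MS cannot separate them. Stop-codon-producing
mismatches are enumerated but never emitted as substitutions: the model
describes full-length proteins only. Coordinates are 1-based and inclusive
on the sequence as supplied. When no coding sequence is given, parent
codons come from the shipped preferred-codon table and any codon-dependent
result is reported under that assumption.

`tryptic_digest()` implements cleavage C-terminal to K/R except before P,
with missed-cleavage unions; `peptide_for_substitutions()` digests the
mutated sequence and flags spans whose boundaries differ from the
wild-type digest (cleavage sites created or destroyed), which excludes
them from intensity-ratio estimators. `predict_cluster_candidates()` ranks
potential clusters by the retention expectation
$E_f^{\mathrm{1st}} \times (E_f^{\mathrm{next}})^{k-1}$ against the
stochastic product, the screen used to direct targeted enrichment at
plausible cluster peptides.

## Proteotoxicity normalizations

The secondary readouts are small, self-contained normalizations:
`aggregation_enrichment()` (insoluble/soluble ratio over the
correct-peptide cohort median, t-test on log-ratios across replicates);
`thermostability_normalize()` (missense/parent ratio per temperature,
anchored to 1 at 41 °C); `presence_filter()` (≥ 60 % of runs);
`impute_missing()` (per-sample downshifted normal, width 0.3 and downshift
1.8 in sample-SD units — per-sample rather than global imputation is the
standard convention and an explicit assumption here); and
`scale_to_interval()` (min–max scaling with a degeneracy flag). Cluster
analysis, permutation-FDR ANOVA and enrichment tests on proteome responses
are deliberately out of scope.

## A worked example

```{r example}
prot <- example_protein()
subs <- rbind(substitution_spec(prot, 242, "D"),
              substitution_spec(prot, 244, "D"))
subs

sim <- simulate_cluster_titration("Apr", subs, prot,
                                  config = sim_config(seed = 1))
est <- efnext_from_tables(sim$tables, "E242D", "E242D+E244D",
                          baseline = sim$baseline)
est$by_condition
est$efnext
```

The per-condition ratios are flat across a 16-fold dose range — the
signature of a bound-state property — and recover the Apr preset (0.25).

```{r distance}
ef <- simulate_distance_profile("groupII", reference = "Str",
                                d_values = 0:6, clusters_per_d = 3,
                                config = sim_config(seed = 11))
prof <- build_distance_profile(ef, reference = "Str")
fit_retention(prof, aga = "groupII", seed = 12)
```

The exponential fit of the simulated group II profile returns a retention
probability close to the generating $q = 0.5$ (slightly below it, because
the observable $c/(1-c)$ decays marginally faster than $q^d$ at small
distances; the fit is of the observable, as in the underlying analyses).

## What the generator does and does not emulate

It emulates: dose- and time-resolvable single-error frequencies; cluster
species whose frequencies follow bound-state conditional probabilities;
flat versus decaying distance profiles; independent (ram-like) errors;
soluble/insoluble partitioning; replicate noise; censoring at a detection
floor; and parent-peptide dropout. It does not emulate: ionization or
fragmentation physics (beyond an optional per-species multiplier),
retention times or spectral interference, identification errors, premature
termination or drop-off products, multiple drug molecules per ribosome, or
any mechanistic kinetics (no rate constants). Passing recovery tests
therefore validates the estimators and the model algebra — not
instrument-level behavior on real spectra.

Two open model questions are resolved explicitly rather than silently: the
drug is assumed to keep its retention probability $q$ through the
translocation following a misreading event, and a single occupancy state is
assumed (no multi-drug binding). Both are conventions, not measurements.

## Problem sizes and runtime

Recovery experiments use 5-point titrations at $N = 10^8$ effective
traversals per condition with technical triplicates — rates are computed
exactly and counts drawn from Poisson laws, so cost is independent of $N$.
Distance profiles use $d = 0\ldots6$ with three clusters per distance plus
a matched reference and untreated controls (84 simulations), and the
retention bootstrap uses 200 resamples; the complete recovery suite runs
in well under a minute on one CPU. Exhaustive path-enumeration checks are
restricted to proteins of ≤ 8 codons, where $2^L$ state paths are
tractable.
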