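# agaclust

Simulation and quantification of aminoglycoside-induced translation error
clusters.

Aminoglycoside antibiotics (AGAs) bind the decoding site of the bacterial
ribosome and cause misreading of near-cognate codons. Proteomics can measure
the resulting amino-acid substitutions through the *error frequency*

```
E_f = I_missense / I_parent
```

— the intensity ratio of a missense tryptic peptide to its correct parental
peptide. Treated cells additionally accumulate *error clusters*: peptides
with two or more substitutions, at frequencies vastly above the product of
the single-substitution frequencies, because one drug molecule can stay
bound over several elongation cycles. The package is aimed at people who
quantify mistranslation from peptide-level intensity data (targeted or
shotgun) and at people who want a generative null model for such data.

It provides:

* a **two-state Markov model of elongation** (drug bound/unbound per codon:
  binding probability `beta` per codon, retention probability `q` per
  translocation, bound-state misreading probability `m` per monitored
  position) with an exact forward dynamic program for pattern
  probabilities, Poisson-rate and per-ribosome Monte Carlo sampling, and an
  MS-like intensity emitter (log-normal noise, detection floor, replicate
  and condition metadata, soluble/insoluble partitioning);
* the **error-cluster statistics**: `E_f` with parent fallback and
  upper-limit handling, the stochastic expectation `prod(E_f_i)`, error
  amplification `A = E_f_cluster / (E_f_1st * E_f_2nd)`, three estimators
  of the conditional next-error frequency `E_f_next`
  (`E_f_1st * E_f_next = E_f_cluster`): through-origin slope, frequency
  ratio, and label-free intensity ratio with physico-chemical exclusions;
* **distance-dependence analysis**: reference-normalized profiles of
  `E_f_next` versus the inter-error distance `d`, the exponential fit
  `N(d) = c * q^d` recovering the retention probability with a bootstrap
  CI, and the group I / group II drug classification;
* **genetic-code utilities**: near-cognate variant enumeration, mismatch
  position classification (priority 3rd > 1st > 2nd), deterministic reverse
  translation, in-silico tryptic digestion with missed cleavages and
  cleavage-alteration flags, and ranking of candidate cluster peptides for
  targeted follow-up;
* **proteome-table preprocessing**: aggregation enrichment, thermostability
  curves anchored at 41 °C, a ≥ 60 % presence filter, downshifted-normal
  imputation (width 0.3, downshift 1.8), and 0–1 interval scaling.

## Worked example

Simulate an apramycin titration for the E242D–E244D cluster geometry (one
correct residue between the errors) on the packaged model protein and
estimate `E_f_next`:

```r
library(agaclust)

prot <- example_protein()
subs <- rbind(substitution_spec(prot, 242, "D"),
              substitution_spec(prot, 244, "D"))
subs
#>   protein_id position from_aa to_aa parent_codon mismatch_class label
#> 1   EFTU-SYN      242       E     D          GAA            3rd E242D
#> 2   EFTU-SYN      244       E     D          GAA            3rd E244D

sim <- simulate_cluster_titration("Apr", subs, prot,
                                  config = sim_config(seed = 1))
est <- efnext_from_tables(sim$tables, "E242D", "E242D+E244D",
                          baseline = sim$baseline)
est$by_condition
#>       ef_first   ef_cluster    efnext
#> 1 3.953882e-06 1.021124e-06 0.2582586
#> 2 7.933581e-06 2.173365e-06 0.2739450
#> 3 1.697659e-05 4.499567e-06 0.2650455
#> 4 3.289075e-05 8.337483e-06 0.2534902
#> 5 6.618259e-05 1.833634e-05 0.2770568
est$efnext
#> [1] 0.2650455
```

Both substitutions are third-position misreadings of GAA. Across the
16-fold concentration range the first-error frequency rises ~17-fold while
the cluster/first ratio stays flat around the preset value 0.25: the
conditional next-error frequency is a property of the drug-bound ribosome,
not of the dose. The same simulated tables show the amplification over the
independence expectation:

```r
tab <- sim$tables[["8"]]
ef1 <- compute_ef(tab, "E242D")$ef
ef2 <- compute_ef(tab, "E244D")$ef
efc <- compute_ef(tab, "E242D+E244D")$ef
amplification(efc, ef1, ef2)
#> [1] 2315.901
stochastic_expectation(c(ef1, ef2))$value
#> [1] 7.917582e-09
```

The observed cluster frequency (1.8e-05) is more than three orders of
magnitude above the stochastic product — the hallmark of drug retention.
See the vignette (`vignettes/error-clusters.Rmd`) for the model, the
estimator algebra, and the distance-profile / retention-fit workflow.

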