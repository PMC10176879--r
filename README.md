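# npsehr

Classification of neuropsychiatric symptoms (NPS) in free-text clinical
notes, with misclassification-corrected prevalence estimation and
note-vs-questionnaire agreement analysis.

## What problem this solves, and for whom

Memory clinics document apathy, depression, anxiety, agitation and other
neuropsychiatric symptoms of early Alzheimer's disease mostly as free text
in electronic health records (EHRs), not as structured data. Researchers
who want cohort-level NPS prevalence — or want to compare what clinicians
write against what caregivers report on the Neuropsychiatric Inventory
(NPI) — need a text-classification pipeline whose error rates are measured
and then *corrected for*. `npsehr` provides that pipeline end to end:

1. **Annotation I/O** — brat standoff `.txt`/`.ann` pairs for 13 NPS
   categories (the 12 NPI domains + a general category), reduced to
   document-level labels with offset and surface-text verification.
2. **Preprocessing** — tokenization, negation-phrase removal ("no
   depressive symptoms" contributes nothing), stop-word removal, Porter
   stemming, and unigram/bigram count features with a training-frozen
   vocabulary.
3. **Classification** — one elastic-net logistic classifier per category
   (glmnet-backed), stratified tenfold cross-validation over an
   (α, λ) grid selected by out-of-fold AUC, Youden-index cutoff
   `J = sensitivity + specificity − 1` chosen on out-of-fold scores, and
   frozen external validation guarded by a vocabulary hash.
4. **Prevalence** — Rogan–Gladen correction
   `π̂ = (p + Sp − 1)/(Se + Sp − 1)` with adjusted-Wald confidence
   intervals that propagate validation-set uncertainty in Se and Sp
   (intervals are deliberately not clamped: an upper bound of 103% is a
   diagnostic, not a bug), an AUC ≥ 0.80 reporting gate, and FDR-adjusted
   group comparisons.
5. **Agreement** — Cohen's kappa between annotators, and per-category
   EHR-vs-NPI kappa plus discordance proportions (EHR+NPI− / EHR−NPI+) at
   NPI thresholds 1 and 4.
6. **Synthetic corpus generator** — because real memory clinic EHRs are
   protected, a generator with known ground truth (center-specific
   prevalences, planted cue phrases, negated mentions, paired imperfect
   annotators, imperfect NPI reporting) makes every stage testable.

## Worked example

```r
library(npsehr)

cfg <- run_config(
  mode     = "synthetic",
  train    = list(n_patients = 300, negation_rate = 0.1),  # cohort A
  external = list(n_patients = 150, negation_rate = 0.1),  # cohort B
  seed     = 13)
report <- run_experiment(cfg)

subset(report$evaluations, split == "internal_cv",
       c(category, auc, sensitivity, specificity, youden, cutoff))
#>        category auc sensitivity specificity youden cutoff
#>       delusions   1           1           1      1  0.151
#>  hallucinations   1           1           1      1  0.108
#>       agitation   1           1           1      1  0.255
#>      depression   1           1           1      1  0.386
#>         anxiety   1           1           1      1  0.438
#>  ...

report$untrainable
#> [1] "euphoria"
```

On this clean synthetic world the classifiers separate perfectly (AUC 1),
which validates the pipeline rather than flattering it — real notes are
harder. Euphoria is refused outright: at its configured 1% prevalence only
~4 of 300 documents are positive, too few to stratify into ten folds
(mirroring the real-data situation where a classifier could not be trained
on 5 positive documents in 500).

```r
subset(report$prevalence$A, gate_passed,
       c(category, observed, adjusted, ci_low, ci_high))
#>        category observed adjusted ci_low ci_high
#>       delusions   0.1333   0.1333 0.0992   0.177
#>  hallucinations   0.0867   0.0867 0.0594   0.124
#>       agitation   0.2533   0.2533 0.2074   0.306
#>      depression   0.3833   0.3833 0.3301   0.440
#>         anxiety   0.4767   0.4767 0.4208   0.533
#>  ...
```

With perfect classifiers the adjusted prevalence equals the observed one;
with imperfect ones the correction matters. The low-specificity regime
reproduces the characteristic over-100% artifact:

```r
rogan_gladen(0.83, sensitivity = 0.91, specificity = 0.61)
#>       raw   clamped
#> 0.8461538 0.8461538

adjusted_prevalence_ci(830, 1000, sens_tp = 91, sens_fn = 9,
                       spec_tn = 61, spec_fp = 39)
#>    ci_low   ci_high
#> 0.7382890 0.9491616
```

Intra-individual agreement between note-derived labels and simulated NPI
reports shows the expected pattern — modest kappas and many symptoms
present in notes but not endorsed on the questionnaire:

```r
head(report$ehr_npi$threshold_1, 4)
#>        category kappa prop_ehr_pos_npi_neg prop_ehr_neg_npi_pos   n
#>       delusions 0.497                0.348               0.5000 189
#>  hallucinations 0.387                0.500               0.6000 189
#>       agitation 0.564                0.440               0.2000 189
#>      depression 0.461                0.565               0.0909 189
```

`prop_ehr_pos_npi_neg` reads: of patients with delusions in their notes,
35% had no corresponding NPI endorsement; `n = 189` is the subsample with
an available NPI assessment (the generator defaults to 67% coverage).

## Command line

```sh
exec/nps-ehr run      --config run.yaml --out results/
exec/nps-ehr simulate --config synth.yaml --out corpus/
exec/nps-ehr agree    --ann-a raterA/ --ann-b raterB/
```

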