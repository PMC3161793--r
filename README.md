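# avlocnet

Bayesian-network modeling of audiovisual spatial localization: both the
percept and the temporal dynamics of the perception process.

## The scientific problem

When people localize a brief sound that is accompanied by a spatially
discrepant flash, the reported position is captured almost entirely by the
visual stimulus (the ventriloquist effect); when they localize the flash, the
accompanying sound leaves the percept untouched. The two contexts therefore
correspond to *fusion* versus *segregation* of the same multisensory
information. Localization responses alone cannot distinguish a unisensory
percept from a segregated multisensory one — but the *decision time* (the
latency between stimulus onset and pointer-movement onset) can: bisensory
presentations are answered faster than unisensory ones in both tasks.

`avlocnet` implements, end to end, a data-driven pipeline that

1. **simulates** seeded behavioral datasets from the classical protocol
   (2 tasks × 450 trials/subject: 75 unimodal, 75 spatially coincident and
   300 non-coincident audiovisual pairs; primaries at −10…10 deg, secondaries
   at ±5/±10-deg offsets; pointer starting from a 40-deg neutral stop),
2. **extracts** the behavioral variables (movement onset/end at a 1.5 deg/s
   velocity cutoff, decision time, localization normalized by each subject's
   unisensory mean),
3. **elicits the network structure** over the six random variables — task
   `S`, mode of presentation `M`, primary `X_p`, secondary `X_s`, percept
   `X̂`, decision time `T` — using normalized mutual information
   `I(X;Y)/H(X,Y)` against null-calibrated thresholds, conditional-MI
   pruning, and d-separation-based orientation, including
   context-specific-independence **multinets**,
4. **fits** the resulting factorization by maximum likelihood,

   P(S) P(M) P(X_p) P(X_s|M) P(X̂|S,X_p,X_s) P(T|S,X_s),

   with a Gaussian conditional for `X̂` and a log-normal conditional for `T`,
   and answers MAP queries for both outputs,
5. **evaluates** the model by leave-one-subject-out cross-validation,
   reporting coefficients of determination against held-out condition-cell
   means.

## Worked example

```r
library(avlocnet)

params <- sim_params(seed = 101)          # default calibration, 10 subjects
trials <- normalize_localizations(simulate_dataset(params))

# dispersion of the normalized localizations, acoustic task, 0-deg primary
summ <- summarize_conditions(trials)
subset(summ, task == 0 & xp == 0,
       select = c(mode, xs_offset, n, response_mean, response_sd))
#>    mode xs_offset   n response_mean response_sd
#> 3     0        NA 150         0.707        7.45
#> 16    1       -10 150        -8.969        6.13
#> 18    1         0 150         0.156        5.06
#> 20    1        10 150         9.437        6.06   (rows abridged)

set.seed(101)
elicit_structure(trials)
#> PDAG: 6 nodes, 6 edges (1 conflicts reported)
#>   s->xhat
#>   s->t
#>   m -- xs
#>   xp->xhat
#>   xs->xhat
#>   xs->t

cv <- crossvalidate(trials)
unlist(cv_r2(cv))
#>                 r2_percept           r2_decision_time
#>                      0.940                      0.615
#> r2_decision_time_collapsed
#>                      0.894
```

Reading the output: unisensory acoustic responses at the median position
scatter with an SD of ≈7.5 deg; adding a coincident flash tightens them to
≈5–6 deg, while discrepant flashes drag the mean response almost onto the
flash position (−9.0 deg for a −10-deg offset — visual capture with a fusion
weight near 0.95). The elicited graph says the percept depends on the task
and both stimulus positions, the decision time on the task and the secondary
position only, and the secondary position encodes the mode of presentation
(the undirected `m -- xs` edge, resolved as `m -> xs` in the factorization).
Cross-validated MAP predictions explain ≈94% of the variance in held-out
subjects' mean localizations, ≈62% of their mean decision times per stimulus
pair, and ≈89% after regrouping decision times into the three modes of
presentation.

A command-line wrapper over the same pipeline lives at
`inst/scripts/avlocnet.R`:

```sh
Rscript inst/scripts/avlocnet.R all --seed 17 --out run1/
```

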