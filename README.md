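# maskddm

Does a facial mask change how an ambiguous face *looks*, or what we
*expect* of it? When observers judge masked and unmasked ambiguous faces
as friendly or unfriendly, both a **perceptual** bias (the occluded mouth
removes friendly evidence, tilting the stimulus evaluation) and a
**preconceptual** bias (a prior that needs less evidence for one response)
produce more and faster choices for the favored alternative. Choice
proportions alone cannot tell them apart; the joint distribution of
choices and response times can.

`maskddm` implements that decomposition for researchers in decision
neuroscience and cognitive modeling: a drift-diffusion model (DDM) with
exponentially collapsing decision thresholds, fitted per participant to
choice + RT data, with the mask's effect decomposed into a drift-rate
criterion shift (perceptual) and a starting-point shift (preconceptual).

## The model

Evidence accumulates as `dx = v dt + dW` between absorbing thresholds at
`±a·exp(−τt)` (collapse models urgency under the 2.3-s deadline). For
stimulus emotion fraction `k` (morph level, −0.6 … 0.6) and mask
indicator `C`:

    v   = vc0 + C·vcmask + k·(vslope0 + C·vslopemask)
    Ter = Ter0 + C·Termask
    z   = z0 + C·zmask        (starting point, fraction of the bound)

Four nested models — `null` (no mask bias), `reduced_vc` (perceptual),
`reduced_z` (preconceptual), `full_vc_z` (both) — are fitted by maximum
likelihood (first-passage-time densities from a Crank–Nicolson
Fokker–Planck solver, in C++) and compared by AIC/BIC. A logistic
psychometric layer (`p(unfriendly) = 1/(1+exp(−(β0+β1·S)))`) provides
descriptives and deviance-based participant exclusion. Because the
original participant data are not publicly deposited, the package ships a
synthetic-cohort generator that reproduces the experiment's design
exactly (608 trials: 96 per emotion level, half masked; 32 fillers;
8 blocks of 76; 2300-ms deadline).

## Worked example

Simulate one synthetic participant at the group-mean parameters, run the
descriptive layer, and refit the full model:

```r
library(maskddm)
p      <- group_mean_params()
design <- build_design(seed = 1)
trials <- simulate_participant(p, design, seed = 1, participant_id = "s01")
trials <- preprocess_rt(trials)

fit_psychometric(trials, "masked")    # b0 = 0.06, b1 = 5.43
fit_psychometric(trials, "unmasked")  # b0 = 0.39, b1 = 10.26

fit <- fit_mle(trials, model_spec("full_vc_z"), fit_settings(seed = 1))
print(fit)
#> ddm_fit: model full_vc_z, participant s01
#>   logLik 149.49  AIC -278.99  BIC -235.46  (10 free, 574 trials)
#>          a        tau       Ter0    Termask        vc0     vcmask    vslope0
#>     0.9644     0.9905     0.3967     0.0229     0.1418    -0.0478     6.1571
#> vslopemask         z0      zmask
#>    -1.3142    -0.0557     0.0871
```

The masked psychometric slope (5.4) is shallower than the unmasked one
(10.3): the mask removes stimulus information. The fitted DDM attributes
the mask's effect to a flatter drift slope (`vslopemask < 0`), a slower
non-decision time (`Termask > 0`), and the two bias terms: at a single
participant's 574 analyzable trials the bias estimates are noisy (here
`vcmask = −0.05`, `zmask = +0.09` against generating values −0.28 and
+0.10); the recovery harness (`parameter_recovery()`) shows they
concentrate around the truth as trials grow.

A full cohort run (simulate → describe → fit all four models → select) is
one call:

```r
run_pipeline(run_config(seed = 7, n_participants = 2, out_dir = "run"))
```

or from the shell, `Rscript inst/cli/maskddm.R run-all --seed 7 --n 2
--out run` (see `inst/cli/maskddm.R` for the other verbs: `simulate`,
`describe`, `fit`, `select`, `recover`).

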