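# spreadnet

Noradrenaline is thought to loosen the inhibitory control of cortical and
hippocampal memory circuits while new associations are learned, letting the
representations of related items bleed into one another — a *spread of
association* across the cognitive map. `spreadnet` implements the three
computational pieces needed to study that idea at desk scale:

1. **A recurrent spiking network with co-dependent plasticity.** 1000
   excitatory and 250 inhibitory conductance-based leaky integrate-and-fire
   neurons; six stimulus-driven cell assemblies arranged on a ring of
   pairwise associations; excitatory (E→E) plasticity gated by local
   inhibitory currents through `exp[-(I/I*)^γ]` and inhibitory (I→E)
   plasticity driven by `A_ISP·E·(E − αI)` toward an excitatory/inhibitory
   balance. Ring memories are embedded under normal ("placebo") or reduced
   ("atomoxetine") inhibition and probed by driving one assembly; the
   analysis quantifies per-assembly firing, probe-induced weight change and
   the fraction of each assembly recruited, as a function of ring distance.
2. **Behavioural statistics for ring-structured choice data.** The
   overgeneralisation error score
   `100·[Σ prox/Nprox − Σ dist/Ndist]/N_opportunity`, mean rank proximity
   (correct = 1, ring-neighbour = 2, …), topological distance for ring
   reconstructions, and Bang's blinding index, with permutation tests and
   bias-corrected bootstrap effect sizes.
3. **A pupillometry pipeline.** Blink interpolation, 120 ms Gaussian
   smoothing, per-block percent normalisation, epoching with trial/subject
   QC, oddball-minus-regular contrasts, and a two-group cluster-based
   permutation test on the contrast time courses.

Synthetic-data generators (`gen_choices()`, `gen_pupil()`,
`gen_blinding()`, `run_full_protocol()`) provide statistically structured
inputs with known ground truth for every stage, so all inferential
properties (null calibration, power, familywise error control, parameter
recovery) are tested in the package's own suite.

## Worked example: overgeneralisation in a synthetic cohort

```r
library(spreadnet)
set.seed(7)
task   <- ring_task(11)
trials <- gen_choices(behaviour_gen_spec(n_subjects = 22, n_trials = 44))
scores <- score_subjects(trials, task)

dplyr::summarise(dplyr::group_by(scores, group),
                 og = mean(og_errors, na.rm = TRUE),
                 mrp = mean(mean_rank_prox, na.rm = TRUE))
#>   group    og   mrp
#> 1 ATX   9.27   3.69
#> 2 PLC   0.203  3.98

permutation_test(scores$og_errors[scores$group == "ATX"],
                 scores$og_errors[scores$group == "PLC"])
#> Permutation test (10000 permutations, 2-sided)
#>   mean difference = 9.064, p = 0.007699

bootstrap_effect(scores$og_errors[scores$group == "ATX"])
#> Bias-corrected bootstrap (10000 resamples)
#>   effect = 9.267, 95% CI [4.575, 13.48], p = 0.0002287
```

The generator's spread parameter gives the "ATX" group an expected
overgeneralisation score of ~10 percentage points (errors concentrated on
ring-neighbours of the correct context) while the "PLC" group errs
uniformly (expected score 0; chance mean rank proximity on this task is
4.0, computed exactly by `chance_mean_rank()`). The permutation test and
the bootstrap recover the gap and its uncertainty from 22 subjects per arm.

For the network model:

```r
res <- run_full_protocol("atx", seed = 1)   # build, embed, learn, probe
assembly_summary(res)                       # rates, overlap, weight change
spread_gradient(assembly_summary(res))      # distance gradient statistic
autoplot(res)                               # per-assembly rate traces
```

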