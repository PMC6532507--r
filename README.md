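# fbdage

Fossil ages are rarely known exactly: stratigraphy gives an interval
(min, max) in Ma, and Bayesian divergence-time studies that place fossils
directly in the tree under the fossilized birth–death (FBD) process must
decide what to do with that interval. The common shortcuts — fixing each
fossil's age to the interval midpoint or to a random draw — turn out to be
costly. `fbdage` is a self-contained simulation pipeline for measuring that
cost: it simulates birth–death trees with Poisson fossil recovery, dresses
each fossil with a stratigraphic interval, simulates sequence alignments,
runs Bayesian MCMC inference under the FBD tree prior with five different
age-handling rules on identical data, and scores each rule by the relative
error of its posterior medians, 95% highest-posterior-density (HPD)
coverage, relative HPD width and CPU time per effective sample.

## Model

The FBD process describes speciation (λ), extinction (μ), fossil recovery
(ψ) and extant sampling (ρ); inference uses the identifiable
parameterization d = λ−μ (diversification), ν = μ/λ (turnover),
s = ψ/(μ+ψ) (sampling proportion). With q(t) and p₀(t) the standard
per-lineage FBD factors (constants c₁ = √((λ−μ−ψ)² + 4λψ),
c₂ = −(λ−μ−2λρ−ψ)/c₁), the density of a sampled tree with origin x₀,
branching ages xᵢ, fossil-tip ages yⱼ, k sampled ancestors and n extant
tips is

```
ψ^(k+m) ρ^n q(x₀) ∏ᵢ λ q(xᵢ) ∏ⱼ p₀(yⱼ)/q(yⱼ)
```

The five age-handling arms are: **correct** (ages fixed to the truth),
**median** (fixed to the interval midpoint), **random** (fixed to a uniform
draw), **interval** (ages co-sampled by MCMC within the stratigraphic
bounds — the proposed tree has FBD density if all fossil ages are inside
their intervals and zero otherwise), and **symmetric** (co-sampled within
an equally long interval recentred on the truth). Sequence data are
2000 nt of HKY+Γ (κ = 5, shape 0.25, 5 categories) under an uncorrelated
lognormal clock; fossils carry no sequence data. See the vignette
(`vignettes/fossil-age-uncertainty.Rmd`) for the full generative model,
priors, proposal design and limitations.

## Worked example

One small experiment — two handling arms, two replicates, short chains —
to show the moving parts (a real comparison uses ≥ 10 replicates and
longer chains; see below):

```r
library(fbdage)
cfg <- experimentConfig(nReplicates = 2, seed = 7,
                        methods = c("correct", "median"),
                        mcmc = mcmcConfig(chainLength = 20000, thin = 20,
                                          burnin = 0.25),
                        essGate = 100)
ex <- runExperiment(cfg)
subset(ex$results, parameter == "divtime",
       select = c(handling, relError, coverage, relWidth))
```

```
  handling   relError coverage  relWidth
1  correct 0.07433566    0.750 0.2259342
6   median 0.49938355    0.125 0.2180222
```

Each row averages, over the replicates and over every internal node of the
extant species tree, the relative error of the posterior median node age
(|median − truth|/truth), the fraction of nodes whose true age fell inside
the 95% HPD interval, and the HPD width divided by the true age. Already at
this toy scale the pattern of the study is visible: with fossil ages fixed
to interval midpoints the node-age error grows roughly sevenfold
(0.074 → 0.499) and coverage collapses (0.75 → 0.125) at essentially the
same interval width, while the correct-age arm stays accurate. `runMCMC()` exposes the sampler directly (including an
effective-prior mode with the sequence likelihood switched off), and
`runUserAnalysis()` applies the same machinery to a user-supplied
alignment, fossil CSV and clade constraints.

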