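# replicell

An agent-based simulator, with accompanying analytical machinery, for
studying how a division of labour between genetic templates ("genomes")
and catalysts ("enzymes") can arise spontaneously from conflicting
multilevel selection in populations of protocells.

## The problem

Origin-of-life scenarios start from a single kind of replicating
catalytic molecule that is both genome and enzyme. How the two roles
separated — information flowing one way, from non-catalytic templates to
catalysts that are never copied back — is a standing question. This
package implements a minimal model of that transition: protocells, each
containing replicators of two types P and Q, compete for a conserved
substrate S. Every replicator carries eight heritable catalytic values
`k^c_pt ∈ (-∞, k_max]` — the rates at which a catalyst of type `c`
produces type `p` from a template of type `t`, four values for the
molecule itself and four for its transcripts. Replication requires a
catalyst–template complex, so a molecule busy catalysing cannot be
copied: catalysis is costly at the molecular level (within a protocell)
and beneficial at the cellular level (between protocells). When
within-cell relatedness `R = σ²cel / (σ²cel + σ²mol)` is low enough, the
conflict resolves by symmetry breaking — one type loses all catalytic
activity (catalytic asymmetry), reverse transcription disappears
(informatic asymmetry), and templates become a numerical minority —
establishing a genome–enzyme distinction.

The mechanism is a positive feedback between Fisher's reproductive
values and the relative weight of the two selection levels, summarized
by the mean-trait dynamics

    Δk̄P ≈ ω̄P (β σ²cel − γ σ²mol) + ω̄Q β σ²cel     (and P ↔ Q),

whose flow equals `σ²tot ∇[R·B − (1−R)·C]` — the gradient of an
inclusive-fitness potential with benefit `B = k̄P + k̄Q` and cost
`C = −log(e^{−s·k̄P} + e^{−s·k̄Q})`. The package implements both levels:
the stochastic agent-based world (compiled core, exact particle
conservation, online two-level ancestor tracking) and the deterministic
phase plane (nullclines, equilibria, stability, basins of attraction),
plus Price-equation decomposition, variance partition and relatedness,
reproductive values, and an end-state phase classifier.

## Worked example

```r
library(replicell)

p   <- sim_params(V = 100, m = 0.01, t_max = 5000, record_every = 100, seed = 1)
run <- run_simulation(p)
run
#> <replicell_run> 5000 steps, V = 100, m = 0.01
#>   final: 101 cells, 4895 replicators; extinct: FALSE; conservation violations: 0

tail(run$trajectory[, c("step", "cell_count", "freq_S", "kP.PP", "kQ.QQ")], 1)
#>    step cell_count freq_S  kP.PP  kQ.QQ
#> 51 5000        101  0.021 0.9851 0.9813
```

About 100 protocells at `n_tot = 50·V`, a ~2% substrate pool (the decay
probability `d = 0.02` sets the turnover), and catalytic activities
still near their maximum: at this small `V` relatedness is high and no
symmetry breaking occurs.

```r
snap <- run$snapshots[[length(run$snapshots)]]
vd <- variance_decomposition(snap, "P")
c(vd$sigma2_cel, vd$sigma2_mol, vd$R)
#> 0.00009 0.00004 0.696

classify_run(run)
#> <phase_class> none (catalyst Q: A = 0.985; template P: A = 0.983)
```

The deterministic phase plane at low relatedness (`σ²mol = 2.5`,
`σ²cel = 1`): the all-active corner has lost stability and only the
differentiated states (one type catalytic, the other inert) attract:

```r
find_equilibria(pp_params(sigma2_mol = 2.5))
#>          kP        kQ       kind stability boundary
#> 1 0.0000000 0.0000000  symmetric    stable     TRUE
#> 2 0.0000000 1.0000000 asymmetric    stable     TRUE
#> 3 1.0000000 0.0000000 asymmetric    stable     TRUE
#> 4 0.0000000 0.4054651 asymmetric    saddle     TRUE
#> 5 0.4054651 0.0000000 asymmetric    saddle     TRUE
```

The methods vignette (`vignettes/protocell-division-of-labour.Rmd`)
documents the update scheme, the classifier thresholds, the ancestor
tracking, and the problem sizes used by the checks.

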