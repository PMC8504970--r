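# driftcomp

Synaptic connections change continually even in the absence of learning:
spine turnover and efficacy drift persist when activity-dependent
plasticity is suppressed.  A circuit that has stored an input–output
mapping must therefore continually repair the damage — some *compensatory
plasticity* process has to counteract the task-independent *synaptic
fluctuations*.  `driftcomp` is an R package for the quantitative question
this raises: **how strong should compensation be, relative to the
fluctuations, to maintain stored function best?**

It is aimed at computational neuroscientists and anyone studying noisy
optimisation dynamics: the same machinery describes gradient descent with
injected parameter noise on an anisotropic loss surface.

## The theory in brief

Per timestep the weight change decomposes as
`Δw = Δc + Δε`, a compensatory term and a norm-controlled,
gradient-uncorrelated fluctuation.  Writing `Q_w[v] = v̂ᵀ ∇²F[w] v̂` for
the upward curvature of the task-error landscape `F` in direction `v`, the
expected second-order error change of one step is

    E[ΔF] = Δcᵀ∇F + ½‖Δc‖² Q_w[Δc] + ½‖Δε‖² Q_w[Δε].

Minimising over the compensation magnitude and imposing steady state
(`E[ΔF] = 0`) gives the optimal compensation-to-fluctuation ratio

    ‖Δc‖*² / ‖Δε‖² = Q_w[Δε] / Q_w[Δc].

Random directions have average curvature `Tr(∇²F)/N`, while the gradient
direction on a quadratic landscape has curvature
`Σ cᵢ²λᵢ³ / Σ cᵢ²λᵢ²` — an eigenvalue average biased toward large `λ`.
Gradient-like compensation therefore moves in more-curved-than-average
directions, and its optimal rate is *at most* the fluctuation rate
(ratio ≤ 1), dropping further below one the more anisotropic the
landscape.  Zero-order (probe-and-keep) rules and the Newton rule predict
a ratio near one.  The package implements the closed-form side
(`optimal_magnitude()`, `steady_state_ratio()`, `expected_q_random()`,
`q_gradient_quadratic()`, `isotropic_steady_state()`) and the simulation
side that tests it: student–teacher feedforward networks, analytic
quadratic landscapes, four plasticity-rule generators, maintenance
trajectories, ratio sweeps and the staircase protocol.

## Worked example

Build the default 12-20-10 sigmoid teacher, run a maintenance trajectory,
then sweep the compensation:fluctuation ratio:

```r
library(driftcomp)

teacher <- make_layered_network(c(12, 20, 10), "sigmoid", seed = 1)
teacher
#> Layered feedforward network (sigmoid, no biases)
#>   architecture: 12 -> 20 -> 10
#>   parameters:   440

task <- teacher_student_task(teacher, make_input_suite(200, 12, seed = 2))
traj <- run_maintenance(task, compensation_config("exact_gradient"),
                        eps_magnitude = 2, c_magnitude = 1,
                        n_steps = 2000, seed = 3)
traj
#> Maintenance trajectory (task, 440 weights, 2000 steps)
#>   rule exact_gradient | ||dc|| = 1, ||deps|| = 2
#>   error: start 0, final 0.1765
steady_state_error(traj, 500)
#> [1] 0.2328141

sw <- ratio_sweep(nonlinear_task_factory(n_inputs = 200),
                  compensation_config("exact_gradient"), eps_magnitude = 2,
                  ratios = c(0.25, 0.5, 0.75, 1, 1.5, 2),
                  n_steps = 2000, repeats = 4, seed = 4)
summary(sw)
#> Steady-state error vs compensation:fluctuation ratio (argmin 0.25)
#>  ratio mean_steady_error sd_steady_error
#>   0.25         0.1966906     0.006065589
#>   0.50         0.2017671     0.003133167
#>   0.75         0.2554509     0.005997381
#>   1.00         0.3158390     0.016283269
#>   1.50         0.6103669     0.041383017
#>   2.00         0.7176578     0.104442005
```

The student starts at the teacher (error 0), fluctuations of norm 2 push
it uphill, compensation pulls it back, and the error settles around a
steady value.  The sweep shows the signature result: steady-state error is
minimised when compensation is *weaker* than the fluctuations (argmin
ratio 0.25–0.5 here) and grows steeply when compensation outcompetes them.

The closed-form counterpart, on a 2-D quadratic with eigenvalues (1, 4)
and equal eigen-projections:

```r
steady_state_ratio(q_eps = expected_q_random(5, 2),
                   q_c = q_gradient_quadratic(c(1, 4), c(1, 1)))
#> [1] 0.8086075
```

`plot(sw)` draws the sweep curve with ±1 sd shading; `staircase()` runs
the increasing-magnitude protocol and reports the sweet-spot magnitude;
`run_experiment()` drives the full config-based protocols
(`"staircase_run"`, `"sweep_grid"`, `"linear_sweep_grid"`,
`"theory_check"`) and writes CSV/JSON/PNG outputs.

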