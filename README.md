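# runopt3d

Predictive trajectory optimization for three-dimensional running —
including running with a continuous change of direction — with a
musculoskeletal model whose dynamics are kept in implicit form.

## The problem

Predicting how a person runs, and how they would run a movement that was
never measured (here: running on a circle), is an optimal control problem
over a musculoskeletal model. runopt3d implements that pipeline end to
end in R:

- a reduced 3D runner: 21 degrees of freedom (6-DOF pelvis with heading
  about the vertical axis outermost, ball torso, per leg a ball hip and
  revolute knee/ankle/subtalar), 18 Hill-type muscle–tendon units with
  polynomial muscle-tendon length paths, 3 torso torque actuators
  (normalized by 10 N·m), and a smooth penetration-based foot-ground
  contact model (heel and toe points per foot);
- implicit full-body dynamics `f(x, ẋ, u) = 0` with state
  `x = (q, q̇, s, a)` — coordinates, rates, projected CE lengths and
  activations — and controls `u = (n_e, m)`, evaluated by recursive
  Newton–Euler over the kinematic tree with forward-mode algorithmic
  differentiation for machine-precision Jacobians;
- backward-Euler direct collocation: N nodes, dynamics as defect
  constraints `f(x_k, (x_k − x_{k−1})/h, u_k) = 0`, free cycle duration
  `T_sim`, and a periodicity constraint
  `x(T_sim) = R_per x(0) + t_per` whose rotation `R_per` (about the
  vertical axis, by the central angle `θ = 2 asin(v T_sim / 2r)`) turns a
  straight-running tracking problem into a curved-running prediction;
- the objective
  `J = W_Track J_track + W_mus J_mus + W_tor J_tor + W_reg J_reg`:
  variance-normalized tracking of joint angles and ground reaction
  forces, volume-weighted cubed excitations divided by the cubed speed,
  squared torque controls, and a small derivative regularization;
- an augmented-Lagrangian solver with projected-Newton inner iterations
  on sparse Gauss-Newton Hessians, Gauss-Newton feasibility restoration,
  and a contact-stiffness / grid warm-start cascade.

Three chained simulations reproduce the study design: predict **standing**
(single node, 50 random multistarts), track **straight running** at
`v_x = 4 m/s` against reference data, and predict **curved running** on a
circle of radius 3.7 m at 2.7 m/s — tracking only straight-running joint
angles and vertical GRFs, with the circle imposed purely through the
rotational periodicity constraint (counterclockwise, left leg inside).

Since no motion-capture data ships with the package, a synthetic
reference generator emulates cycle-extracted running data (12 noisy gait
cycles, stance duty factor 0.35, vertical GRF impulse balancing body
weight) and the cycle-averaging step (resampling to the 50 collocation
samples, mean and SD per sample).

## Worked example

```r
library(runopt3d)

model <- build_reduced_runner(92, 1.95)   # the study subject
validate_model(model)                      # character(0) = usable

# synthetic reference: 12 cycles at 4 m/s, averaged onto 50 samples
cycles <- synth_reference(model, speed = 4, n_cycles = 12, seed = 1)
ref <- cycles_to_reference(cycles, N = 50)

stand <- standing_task(model, n_starts = 12, seed = 1)
print(stand)
#> <runopt_solution> task 'standing': J = 0.0060645, T_sim = 1.000 s
#>   max constraint violation 0.000232 (converged)

f <- full_dynamics_residual(model, stand$X[, 1],
                            rep(0, state_control_layout(model)$n_x),
                            stand$U[, 1])
sum(f$grf[c(2, 5)])    # total vertical GRF equals the 902.5 N body weight
#> [1] 902.5194

straight <- straight_running_task(model, ref, v_x = 4, init = stand)
curved <- curved_running_task(model, ref, v_norm = 2.7, r = 3.7,
                              init = straight)
write_solution_motion(model, curved, "curved.sto")
```

`standing_task()` reports the per-start objectives in `$multistart`; the
running solutions carry the optimized trajectories (`$X`, `$U`), cycle
duration `$T_sim`, the objective breakdown `$terms`, and
`$max_violation` with a `converged` flag (take it seriously: the
running solves plateau above the feasibility tolerance within the
default budgets and are then flagged, not silently accepted). The
average forward speed of the straight solution equals the prescribed
4 m/s because the periodicity constraint enforces it, and the curved
solution starts on the 3.7 m circle with its cycle chord equal to
`2 r sin(θ/2)`.

A thin command-line driver over the same functions lives at
`inst/cli/runopt3d.R`
(`stand | track-straight | predict-curved | synth-ref |
check-derivatives`).

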