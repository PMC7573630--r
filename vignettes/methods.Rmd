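---
title: "Predictive trajectory optimization for 3D running: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive trajectory optimization for 3D running: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

runopt3d predicts and reconstructs three-dimensional running — including
running on a circle, i.e. with a continuous change of direction — by
trajectory optimization of a musculoskeletal model whose dynamics are kept
in implicit form. This vignette documents the model, the transcription, the
solver, the synthetic reference data, and the design decisions a user
should know before trusting (or modifying) results.

## The musculoskeletal model

`build_reduced_runner()` constructs a desk-scale 3D runner: 10 segments,
21 degrees of freedom (DOFs), 18 Hill-type muscle-tendon units (MTUs) and
3 torque actuators. The pelvis is the floating base with three translations
and three rotations; the rotation order places **heading** (rotation about
the vertical y axis) outermost, so that rotating the whole body about the
vertical axis changes exactly one coordinate, `pelvis_rot`. This is what
makes the rotational periodicity constraint of curved running a sparse,
linear-in-the-state map. The torso sits on a 3-DOF ball joint driven by
three torque actuators whose controls are normalized by 10 N m — the
reduced model's stand-in for arm action. Each leg has a ball hip, revolute
knee, revolute ankle and revolute subtalar joint.

The coordinate convention is x forward, y vertical up, z to the subject's
right; all internal units are SI with radians (degrees only at motion-file
edges, flagged in the header).

Segment masses are standard anthropometric fractions of subject mass, with
the torso fraction defined as the remainder so the total equals the
subject mass exactly; lengths are fractions of stature. Inertia tensors
use box/rod approximations. These are deliberately generic: the framework
represents the full-complexity layout (more DOFs, more MTUs, polynomial
paths of higher order) through the same model-definition structures, which
serialize to YAML via `write_model_yaml()`.

### Muscles

Each MTU is a three-element Hill model: contractile element (CE) with
activation and contraction dynamics, parallel elastic element (PEE), and
series elastic element (SEE, the tendon). The contraction state is not the
CE length but its projection `s` on the line of action; with the
constant-height pennation model `l_CE sin(phi) = l_CE_opt sin(phi_opt)`,
the CE length is `sqrt(s^2 + h^2)` and every quantity in the force balance
stays finite as the pennation angle approaches 90 degrees. The implicit
contraction residual (per muscle, in N)

```
residual = F_SEE - (a F_ISO f_L f_V + F_PEE + d_CE v_CE) cos(phi)
```

uses a Gaussian active force-length curve (`W = 0.56`), a hyperbolic
force-velocity curve with `A_hill = 0.25`, `v_max = 10 l_CE_opt/s` and an
eccentric branch that continues slope-continuously and saturates at 1.5
`F_ISO`; the SEE is quadratic with strain `eps0_SEE = 0.04` at `F_ISO`,
and the PEE is quadratic engaging at optimal CE length with stiffness
`1/W^2` (so it reaches `F_ISO` at `l_CE_opt (1 + W)`). A small CE damping
`d_CE = 0.01 F_ISO/(l_CE_opt/s)` makes the residual strictly monotone in
`sdot`, guaranteeing a unique implicit contraction rate and bounded
Jacobians. Activation dynamics use the smooth excitation-weighted rate
blend

```
adot = (n_e - a) (n_e / T_act + (1 - n_e) / T_deact)
```

with `T_act = 10 ms`, `T_deact = 40 ms` — differentiable everywhere,
unlike an if/else on `n_e > a`. All parameters are per-muscle entries in
the model file and can be overridden.

Muscle-tendon lengths are polynomials in the spanned joint angles
(`mtu_geometry()`, `fit_path_polynomial()`); moment arms are the negated
partial derivatives (virtual work). Polynomials have well-defined
derivatives of any order, which the implicit-dynamics Jacobians need. The
reduced runner uses constant moment arms (degree-1 paths) of 2–6 cm chosen
in the physiological range; the fitting routine recovers arbitrary
coefficients up to degree 4 from length samples and is the intended route
for calibrating against measured moment-arm data.

### Ground contact

Contact is penetration-based and C1-smooth so that it can sit inside a
derivative-based optimizer: smoothed penetration
`p = (sqrt(y^2 + eps_p^2) - y)/2`, cubic normal force
`F_y = k_n p^3 (1 - c_n ydot)` softly clamped nonnegative, and Coulomb
friction smoothed by a regularization velocity,
`F_t = -mu F_y v_t / sqrt(|v_t|^2 + v_c^2)`. Defaults:
`k_n = 2.5e8 N/m^3`, `c_n = 1 s/m`, `mu = 1`, `v_c = 0.01 m/s`,
`eps_p = 1 mm`. Under static body weight this yields about 1 cm of
penetration — the price of a stiffness the optimizer can differentiate
through. Two contact points per foot (heel, toe); their summed force is
the simulated ground reaction force (GRF) signal.

## Implicit dynamics

The full model dynamics are a residual `f(x, xdot, u) = 0` with
`x = (q, qdot, s, a)` and `u = (n_e, m)`:

1. kinematic identity rows `xdot_q - qdot`,
2. multibody rows `RNE(q, qdot, qddot) - tau_ext`, evaluated by a
   recursive Newton-Euler pass over the kinematic tree (gravity via the
   base acceleration; no mass matrix is ever formed), with muscle forces,
   actuator torques and contact forces entering as generalized forces
   through moment arms and point Jacobians,
3. per-muscle contraction residuals,
4. per-muscle activation residuals.

The rows are nondimensionalized — multibody rows by subject weight `m g`,
contraction rows by `F_ISO`, activation rows by `T_act` — so that a single
feasibility tolerance (`1e-3`) is meaningful across rows whose natural
units span five orders of magnitude. The module-surface functions
(`multibody_residual()`, `contraction_residual()`, ...) keep natural units.

Derivatives are algorithmic: the whole evaluation chain is templated on
the scalar type in C++ and instantiated with a forward-mode dual number,
giving machine-precision directional derivatives. The collocation
Jacobian assembles per-node blocks from (i) dual sweeps over the node
state and the cycle duration, (ii) the backward-Euler chain rule for the
previous-node columns, and (iii) analytic control columns. Every Jacobian
and gradient is tested against central finite differences at `1e-5`
relative tolerance, and `check_derivatives()` exposes the same check to
users.

## Transcription and tasks

Backward-Euler direct collocation on N nodes at `t_k = k T_sim / N`,
`k = 0..N-1`: the defect constraints are
`f(x_k, (x_k - x_{k-1})/h, u_k) = 0` for `k = 1..N-1` plus a wrap defect
in which the state at `T_sim` is not a decision variable but the
periodicity image `P(x_0, T_sim)` of the first node and the controls wrap
to `u_0` — exactly N defect blocks, no duplicated variables. For straight
running `P` adds `(v_x T, 0, v_z T)` to the pelvis position; for curved
running it rotates the pelvis horizontal position and global velocity pair
about the vertical axis by the central angle
`theta = 2 asin(v T / (2 r))` and adds `theta` to the heading. Rotating
the velocity pair is physically required for a consistent circular cycle
and is applied even though the positional map alone would formally suffice
to pin the geometry. The decision vector is
`(x_0..x_{N-1}, u_0..u_{N-1}, T_sim)` with bounds from the model file and
`T_sim` in `[0.3, 1.5] s`.

The objective is the weighted sum of four dimensionless terms (all
discretized with the same rectangle rule as the dynamics, so the `1/T_sim`
normalization cancels into `1/N`):

- **tracking**: variance-normalized squared deviation from the reference
  mean, with variances floored at 10% of each signal's mean variance
  (`adjust_variance()`) and per-signal weights balancing the angle and GRF
  groups (`W_ang = 1`, `W_GRF = 5`);
- **muscular effort**: volume-weighted cubed excitations divided by the
  cubed norm of the horizontal speed (divisor 1 for standing, where the
  speed is zero — the divisor exists to compensate for different running
  speeds and has no meaning at zero speed);
- **torque**: mean squared normalized torso-actuator controls;
- **regularization**: mean squared backward-difference derivatives of all
  states and controls, wrap interval through `P`.

Task presets (`task_spec()`): standing uses one node, `xdot = 0`, no
periodicity, `W_mus = W_tor = 1`; straight running tracks all joint
angles, pelvis orientation and all six GRF components with `W_track = 1`,
`W_mus = 1e3`, `W_tor = 1`, anchors the first-node pelvis at the origin
and is warm-started from the standing solution tiled along the prescribed
forward progression; curved running tracks joint angles and vertical GRFs
only, multiplies `W_mus` and `W_tor` by 10, anchors the first node at
`(-r, 0)` — counterclockwise around the origin, left leg inside — and is
warm-started from the straight solution rotated onto the circle. The
regularization weight defaults to `W_reg = 1e-3`: with SI states the
acceleration entries of `xdot` make the raw regularization term of order
10–100 for a running motion, so a weight of order 0.1 would dominate the
tracking term instead of being the intended small convergence aid.

## Solver

The transcribed problem is a sparse NLP with bound constraints and
equality defects. `solve_nlp()` implements an augmented-Lagrangian
method. Inner subproblems are minimized by a projected Newton iteration:
the Gauss-Newton Hessian of the augmented Lagrangian (objective
curvature plus `rho J'J` from the defect Jacobian) is factorized with a
sparse Cholesky after clamping variables that press against their
bounds, and steps are globalized by Levenberg-Marquardt damping that
tracks the accepted step length. Multipliers are updated between inner
solves whenever feasibility progresses; the penalty parameter grows only
on genuine stalls and is kept moderate, since very large penalties
merely degrade the conditioning. A damped Gauss-Newton **feasibility
restoration** — minimum-norm steps from the defect normal equations,
with the (dense-coupling) cycle-duration column split off by a
Sherman-Morrison update so the normal matrix stays banded, accepted only
when the defect 2-norm decreases — runs between outer iterations and as
a final polish.

Because the defect system is violently nonlinear through the cubic
contact law, the running tasks solve through a warm-start cascade:
a coarse 10-node grid on a 1000-fold softened ground finds the basin
cheaply, the solution is interpolated (states wrapping through the
periodicity image) to 25 and then the task's node count, and the ground
stiffness is tightened in stages (`k_n` times 1e-3, 1e-1, 1); the final
stage solves the unmodified problem. Convergence requires the maximum
nondimensionalized defect to be at most `1e-3`; a solve that does not
reach feasibility is returned flagged `converged = FALSE`, never
silently accepted. In practice the standing problem converges well below
the tolerance, while the running solves typically plateau one to two
orders of magnitude above it within the packaged iteration budgets (a
worst defect of order 1e-2, i.e. a few newton-metres of torque
imbalance at isolated foot-strike nodes) — see the limitations section. The standing task solves its single-node problem from
`n_starts` random initial guesses drawn uniformly within the variable
bounds (pelvis translations within a standing-sized box, coordinate
rates near zero) and returns the converged solution with the lowest
objective.

## Synthetic reference data

`synth_reference()` emulates the structure of cycle-extracted running
data: 12 cycles by default, right heel strike at phase 0, left leg shifted
half a cycle, stance duty factor 0.35. Joint-angle templates are low-order
harmonics with running-like ranges (hip flexion about -10 to +40 degrees,
knee flexion peaking in swing, ankle dorsi/plantarflexion of +-15
degrees); the vertical GRF is a smooth single hump per stance scaled so
the two legs' cycle-averaged vertical force equals body weight (2.9 body
weights peak at duty 0.35), the fore-aft GRF is a braking/propulsion
biphasic wave, and the mediolateral component is small. Cycle-to-cycle
variation is seeded smooth noise with about 2 degrees SD on angles and 5%
on GRF amplitude; cycle lengths vary slightly so the resampling path is
exercised. `cycles_to_reference()` resamples every cycle to the N
collocation phases `k/N` and takes the per-sample mean and SD (n-1
denominator).

What the generator does **not** emulate: measured data's soft-tissue
artifact, filter transients, inter-subject anthropometric mismatch between
model and data, and — most importantly — dynamical consistency: the
templates are kinematic shapes, not solutions of this model's equations.
A tracking solve therefore has irreducible deviation from the reference,
exactly as tracking of real motion-capture data does. Passing tests on
synthetic references demonstrate the machinery (transcription, solver,
constraint enforcement, signal bookkeeping), not fidelity of the reduced
model to human running.

## Numerical choices and degenerate inputs

- Feasibility tolerance `1e-3` on the nondimensionalized defect rows;
  solver inner tolerance `1e-5`; derivative checks at `1e-5` relative.
- The contact softening constants (`eps_p`, `f_eps`, `v_c`) leave
  sub-Newton residual forces away from the ground; tests assert against
  that scale rather than machine zero.
- An all-zero SD for a tracked signal is an error (the variance
  normalization is undefined), not a silent floor.
- `central_angle()` refuses chords longer than the circle diameter.
- Problem sizes used in the packaged studies: N = 50 nodes for running
  (matching the reference resampling), 1 node for standing; the
  node-count consistency property is checked at N = 25 vs N = 50.
  Standing uses a multistart of configurable size; the packaged
  reproduction study uses a reduced multistart (8 starts; the per-start
  solve is deterministic given the seed) and running-solve budgets of a
  few outer iterations per continuation stage — enough to pin the
  constraint-implied quantities, not to exhaust the feasibility plateau
  discussed under limitations. Budgets are ordinary `solver_settings()`
  arguments.

## Known limitations

- The reduced runner's 21 DOFs and 18 lumped MTUs are a desk-scale
  instance; absolute joint-angle and GRF waveforms should not be read as
  subject-specific predictions.
- No segment-segment collision avoidance: in curved running the swing leg
  may pass through the stance leg's space, a known artifact reproduced
  deliberately (a minimum-distance constraint would remove it).
- The solver is the package's weakest link. The standing problem
  converges far below the `1e-3` feasibility tolerance, but on the
  running problems the augmented-Lagrangian iteration plateaus at a
  worst nondimensionalized defect of order `1e-2` within the packaged
  budgets: the cubic contact law makes the defect system so nonlinear
  through the foot-strike nodes that full Gauss-Newton steps are only
  accepted heavily damped, and progress per multiplier update saturates.
  The constraint-implied quantities (average speed, circle radius, chord
  speed, periodicity geometry) are enforced by the transcription itself
  and are insensitive to this plateau, but running solutions should be
  treated as approximate dynamic consistency, the `converged` flag taken
  seriously, and tracking-quality numbers read with that caveat. An
  interior-point solver with exact second-order information (the class
  of tool this problem was designed for) closes the remaining gap;
  within this package, raising `max_outer`/`max_inner` buys feasibility
  roughly linearly in time.
- Contact parameters are not calibrated to a specific shoe/surface; the
  ~1 cm static penetration trades realism for smoothness.
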