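---
title: "Methods: switched AVPD heart model and intra-cycle pump-speed optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: switched AVPD heart model and intra-cycle pump-speed optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`lvadopt` models the left heart and systemic circulation as a lumped
nine-state ODE system in which ventricular pumping is driven by the
longitudinal motion of the atrioventricular plane (AVP) rather than a
time-varying elastance. The states are the pressures of left atrium,
left ventricle, aorta, systemic artery and venous compartment (mmHg),
the aortic and pump flows (mL/s), and the AVP velocity (cm/s) and
position `s` (cm):

\[
x = [P_{LA}, P_{LV}, P_A, P_S, P_V, Q_A, Q_{LVAD}, v, s]^\top .
\]

The AVP behaves as a piston of cross sections \(A_{LA}\) and \(A_{LV}\)
between atrium and ventricle. Its force balance
\(L_{AVP}\dot v = -R_{AVP} v - A_{LV}P_{LV} + A_{LA}P_{LA} + F_C\)
carries a piecewise-constant contraction force \(F_C\): during atrial
contraction the effective force is \(-|F_{AC}|\), pulling the plane
towards the basal threshold \(-S_D\); during ventricular contraction it
is \(+|F_{VC}|\), driving the plane to \(+S_D\); in relaxation it is
zero. (The sign convention is a package decision: the source model
writes a single \(F_C\) term while describing the two phases as acting
in opposite directions; the chosen signs are the only ones that make
both switching events reachable.) Radial squeezing of the ventricle
amplifies the piston's volume displacement by \(1 + k_{RAD}\).

The valves are ideal diodes, \(Q = \Delta P / R\) when the forward
pressure difference is positive and zero otherwise. The rotary pump
obeys
\(L_{LVAD}\dot Q_{LVAD} = P_{LV} - P_A - R_{LVAD} Q_{LVAD} - \beta u^2\)
with speed \(u\) in rpm; \(\beta\) is stored negative
(\(-1.02\times 10^{-6}\) mmHg/rpm\(^2\)) so that raising the speed adds
forward head. For a subject without an implanted pump
(`lvad_present = FALSE`, the personalisation setting) the pump branch is
removed and \(Q_{LVAD}\equiv 0\); running the pump equation at
\(u = 0\) instead would act as an open shunt from aorta to ventricle.

### The cycle as a switched system

One heart beat is a fixed sequence of seven phases: atrial contraction
(mitral open), ventricular contraction with the mitral valve still open,
isovolumic contraction, ejection, relaxation with continuing ejection,
isovolumic relaxation, and filling. The six phase boundaries are implicit
switches: the roots of \(s = -S_D\), \(P_{LA} = P_{LV}\) (closure),
\(P_{LV} = P_A\) (opening), \(s = +S_D\), \(P_{LV} = P_A\) (closure) and
\(P_{LA} = P_{LV}\) (opening). The full mode product (three contraction
settings, two states per valve) has twelve subsystems; the canonical
schedule visits seven of them. If an event does not occur before the end
of the cycle — for instance the aortic valve never re-closing at a
constant speed beyond the partial-support range — the simulation fails
with an error naming the missing event rather than silently reordering
phases, because the phase order is an assumption of the method.

### Conserved volume

Summing the five compartment volume derivatives \(C_i \dot P_i\) gives
exactly \((A_{LA} + (1 + k_{RAD}) A_{LV})\, v\): every inter-compartment
flow cancels pairwise, so the quantity
\(\sum_i C_i P_i - (A_{LA} + (1+k_{RAD})A_{LV})\, s\) is a first
integral — the stressed blood volume. Two consequences shape the
implementation. First, the periodic cycle map has a unit eigenvalue
along this direction, so the Newton search for the periodic orbit solves
a bordered system that pins the iterate to its volume level set. Second,
the periodic state reached depends on the volume implied by the search
seed; the personalisation therefore projects every warm start back onto
the volume of the fixed reference state, making the forward model a pure
function of the parameters.

## Simulation

The integrator is an adaptive Dormand–Prince 5(4) scheme (compiled, with
cubic-Hermite dense output) with absolute and relative tolerances of
1e-8. Events are located on the dense output by bisection to machine
precision in time; explicit control switches (the pwc profile's
`t1, t2, t3` and the zero-order-hold grid edges) are step boundaries.
The periodic start state is found by a Newton iteration on the cycle map
(finite-difference map Jacobian, nine extra cycle integrations per
step), falling back to plain fixed-point cycling when the Newton path
fails; tolerance 1e-6 in a scaled max-norm, which makes the periodicity
constraint residuals of order 1e-4 or below — far inside the tolerance
`eps_per = 0.5` used for reporting.

Objective and constraint functionals are evaluated by trapezoidal
quadrature on the 1 ms output grid with event times included as nodes.
This deviates from the design suggestion of reusing the collocation
quadrature; the difference is at the 1e-6 relative level (bounded by the
simulator-versus-collocation test) and the trapezoid keeps the
functionals independent of the transcription module.

## Collocation transcription

The multiphase transcription rescales each phase onto \([0,1]\)
(`transform_time`), turning the six switching times — nine for the pwc
scenario, where phases 3, 6 and 7 are split at the speed switches — into
continuous variables. States are approximated by degree-3 Radau IIA
collocation polynomials on a nominal 1 ms grid; per-phase interval
counts are frozen integers derived from the initialisation durations
(grid nodes deform with the durations, the standard switching-time
practice). `build_nlp` materialises the structure — phase table,
variable and constraint counts, switching-residual and dwell-time
blocks — and `solve_collocation_ivp` solves the collocation equations
sequentially (equivalent to implicit Radau time stepping), which serves
as an independent cross-check of the adaptive simulator.

The environment provides no large-scale interior-point NLP solver, so
the optimal control problems are *not* solved as the simultaneous
collocation NLP. Instead the package uses the reduced (single-shooting)
formulation: for any candidate control the periodic state is eliminated
by the cycle-map fixed point, and the remaining low-dimensional problem
is solved with a quasi-Newton box-constrained method
(`stats::nlminb`) using explicit central-difference gradients (step
2e-4 relative, matched to the 1e-6 simulation noise floor). Physiological
constraints enter as quadratic penalties on the residual beyond 90% of
each tolerance, so returned optima sit strictly inside the feasible set;
feasibility is re-checked against the true tolerances afterwards.
Switching residuals are satisfied to event-location accuracy by
construction and verified post hoc. The minimum-dwell condition on the
ventricular-contraction *phase* mentioned in the source's results is not
imposed: phase durations are outcomes of the event-driven dynamics here,
not decision variables.

## Personalisation

Nine parameters
\(p = [R_{AVP}, C_{LV}, L_{AVP}, F_{VC}, F_{AC}, A_{LV}, A_{LA},
k_{RAD}, S_D]\) are estimated from sampled LV pressure by weighted
nonlinear least squares with the phase durations fixed (taken from the
realised events of a simulation, following the stated initialisation
strategy) and the pump absent. Because the phase-fixed dynamics do not
contain \(S_D\), the six phase-boundary switching residuals are appended
to the residual vector with weight \(1/\sigma_{sw}\)
(\(\sigma_{sw} = 0.05\)); they are the penalised counterparts of the
transcription's boundary constraints and restore identifiability of
\(S_D\). The solver is a damped Gauss–Newton iteration with adaptive
Levenberg–Marquardt regularisation scaled by the Jacobian column norms,
central-difference Jacobians (relative step 1e-4) and projection onto
box bounds. The reported `objective` is the data misfit
\(\tfrac12\sum_i (\hat P_{LV}(t_i) - P_{LV}(t_i;p))^2/\sigma_i^2 +
\phi(p)\) (the prior \(\phi\) defaults to zero); the solver's monotone
merit additionally contains the switching penalty.

Uncertainty is summarised by Fisher-information relative standard
deviations from the Gauss–Newton approximation,
\(\%SD_i = 100\sqrt{[(J^\top J)^{-1}]_{ii}}/|p_i|\), computed in
relative parameter scaling for conditioning. The design is genuinely
ill-conditioned along a direction mixing the AVP drag, inertance, forces
and areas — relative SDs of several hundred percent, consistent with the
published observation that two of the nine parameters are weakly
identified — and the Gauss–Newton valley is correspondingly slow: exact
recovery on noise-free data needs on the order of a hundred iterations.

## Synthetic data

No clinical series is deposited, so the package generates its own stated
world. The `paper_subject` reference patient combines the published
nine-parameter estimate with placeholder circulation constants (the
supplement holding the originals is not part of the source text). The
placeholders were calibrated once, before the acceptance tests were
written, against the stated haemodynamic targets — left-atrial pressure
inside 10–20 mmHg, cardiac output near 3.5 L/min without a pump, partial
support preserved around 8000–9000 rpm — and then frozen. The pump-free
periodic cycle yields CO ≈ 3.3 L/min, \(P_{LA}\in[10.9, 14.3]\) mmHg and
an AVPD amplitude of 10.3 mm. The end-systolic LV pressure reaches only
about 103 mmHg against the 120 mmHg of the measured subject: with the
published \(R_{AVP} = 324.2\), the velocity drag during ejection caps
the peak; the target therefore carries a 20% tolerance rather than a
retuned \(R_{AVP}\). Measurements are \(P_{LV}\) samples at
\(n_m = 27\) evenly spaced times (a systole-dense layout is available;
the true clinical layout is unknown) with independent Gaussian noise,
\(\sigma_i = \max(\text{noise SD}, 1)\) mirroring the unit weighting of
the estimation problem.

What a green test does *not* establish: the synthetic world has exact
model structure (no model error), stationary noise, and a conserved
volume convention; recovery results say nothing about structural
misspecification against real pressure data.

## Scenario comparison

`compare_scenarios` solves the constant scenario first, warm-starts the
pwc scenario from the constant optimum (plus a deterministic
counterpulsative second start, since the equal-levels point is a known
weak local minimum), and warm-starts the continuous scenario from the
pwc optimum with the pwc switch times inserted into the zero-order-hold
grid so the pwc solution is exactly representable. Each enlargement of
the feasible control set therefore can only improve the objective, and
the ordering \(J_{cont} \le J_{pwc} \le J_{const}\) holds by descent —
the property the acceptance suite asserts. With the package defaults
(\(\rho_1 = 0.5\), \(\rho_2 = 1.333\times10^{-4}\) J/(mmHg·mL),
\(\rho_3 = 0.004\) J/mL, target CO 4 L/min ± 200 mL/min) the optimal
modulated profiles are counterpulsative and shorten the atrial
contraction phase relative to constant speed, reproducing the
qualitative published findings; the published objective values
themselves depend on the undeposited supplement configuration and are
not reproduction targets.

Solutions are local. `solve_ocp(multi_start = n)` adds seeded
perturbations of the warm start; the default is off for determinism.
The copulsative/counterpulsative label correlates the applied speed with
the ventricular-contraction phase indicator; |r| > 0.2 is the documented
classification threshold.

## Numerical choices at a glance

| Quantity | Value | Why |
|---|---|---|
| integrator tolerances | 1e-8 abs/rel | event location and FD Jacobians need a quiet floor |
| event residual at boundaries | < 1e-6 | bisection on dense output |
| steady-state tolerance | 1e-6 (OCP), 1e-9 (PE) | PE Jacobians difference through the fixed point |
| collocation | Radau IIA, degree 3, 1 ms | stiff accuracy; matches the stated discretisation |
| `eps_sw` | 1e-3 | switching-residual reporting tolerance |
| FD gradient step (OCP) | 2e-4 relative | above the simulation noise floor |
| LM damping | adaptive, column-scaled | ill-conditioned Gauss–Newton valley |
| pulsatility threshold | |r| = 0.2 | classifier is descriptive, not part of the optimisation |

## Known limitations

Right heart, pulmonary circulation, baroreflex, valve regurgitation,
blood rheology and rotor inertia are out of scope by design. The reduced
OCP solve finds local optima of a penalised problem, not KKT points of
the full collocation NLP; dwell times on contraction phases are not
enforceable in this formulation. The personalisation identifies a
nine-parameter vector from a single pressure signal only up to a
strongly ill-conditioned direction, and the Fisher SDs quantify exactly
that.
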