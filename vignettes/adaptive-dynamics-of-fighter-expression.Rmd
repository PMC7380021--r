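---
title: "Adaptive dynamics of fighter expression in a two-sex, two-tactic mite model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive dynamics of fighter expression in a two-sex, two-tactic mite model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artevol)
```

## The biological question

Male bulb mites (*Rhizoglyphus robini*) come in two discrete reproductive
tactics. *Fighters* carry a thickened, weaponized third leg pair that they use
in contests over females -- and to kill conspecifics. *Scramblers* are
unarmed; they mature faster, live slightly longer, and sneak matings. The
proportion of male zygotes that develops into fighters, written $\beta$, is a
heritable threshold trait and can evolve.

Fighter expression feeds back on the population itself: more fighters means
more contests, and -- where fighters kill conspecifics -- more mortality in
whichever life stage they target. That mortality changes population size and
structure, which changes the payoff of being a fighter, which moves the
selection gradient on $\beta$. This package implements that eco-evolutionary
feedback loop end to end: a density-dependent stage-structured projection
model, a hawk--dove mating game between the male morphs, stage-targeted
killing by fighters, and the adaptive-dynamics machinery (resident
equilibration, mutant invasion fitness, pairwise invasibility plots, singular
strategies, parameter sweeps) that locates the evolutionarily stable fighter
fraction $\beta_{\mathrm{ESS}}$.

## The demographic model

Four stages: zygotes ($z$, all juvenile stages pooled), adult females ($x$),
adult fighters ($f$) and adult scramblers ($s$), with densities
$n_i$. One projection step is one day. Zygotes mature into stage
$i \in \{x, f, s\}$ at rate $G_i = \sigma_{zz} / t_i$, where $t_i$ is the
maturation time; a fraction $\rho$ of zygotes is male, and a fraction $\beta$
of the males becomes a fighter. Zygote stasis is

$$P_z = \sigma_{zz}\left(1 - \left[(1-\rho)G_x + \beta\rho G_f +
(1-\beta)\rho G_s\right]\right),$$

and adults remain in their stage with their daily survival
$P_j = \sigma_{jj}$.

Reproduction couples the sexes. Encounters are mass-action,
$e_{i,j} = e_0 n_i n_j / \sum_k n_k$ (an `adults_only` denominator variant is
available as an option). A female--male encounter yields a clutch
$k = k_0/(1 + n_x)$ -- clutch size falls with female density -- provided the
male secures the mating. With probability $1 - c_m$ he is unopposed; with
probability $c_m$ he faces a competitor drawn at random from the male pool,
and the outcome follows a hawk--dove payoff matrix

$$M = \begin{pmatrix} m_{ff} & m_{fs} \\ m_{sf} & m_{ss} \end{pmatrix}
 = \begin{pmatrix} (V - C)/2 & V - \varepsilon \\
 \varepsilon & V/2 \end{pmatrix},$$

where $V$ is the value of uncontested access, $C$ the fighter's cost of
escalated fights, and $\varepsilon < V$ the scrambler's sneaking success. The
mating probability of a morph-$j$ male is the frequency-weighted mixture

$$p_{x,j} = 1 - c_m + c_m\left[\tfrac{n_f}{n_f + n_s} m_{jf} +
\tfrac{n_s}{n_f + n_s} m_{js}\right],$$

clamped to $[0,1]$ because $m_{ff} < 0$ is possible when $C > V$. Births from
morph $j$ are $B_{x,j} = k\, e_{x,j}\, p_{x,j}$; each birth is credited half
to the mother and half to the father, giving the fertility entries
$F_x = (B_{x,f} + B_{x,s}) / (2 n_x)$ and, per male of morph $j$,
$F_j = B_{x,j} / (2 n_j)$ (see *Design choices* for this bookkeeping and its
alternative).

Fighters kill encountered conspecifics of stage $i$ with probability $u_i$
(the *killing success*). The number killed per day is $q_i = e_{i,f} u_i$, so
the killed proportion of stage $i$ is

$$Q_i = q_i / n_i = e_0\, u_i\, n_f \Big/ \sum_k n_k,$$

and killing discounts each stasis entry by $(1 - Q_i)$. Maturing zygotes are
not exposed (the quiescent moulting stage is hidden from fighters). The full
projection matrix over $(z, x, f, s)$ is

$$N(n) = \begin{pmatrix}
(1-Q_z)P_z & F_x & F_f & F_s\\
(1-\rho)G_x & (1-Q_x)P_x & 0 & 0\\
\rho\beta G_f & 0 & (1-Q_f)P_f & 0\\
\rho(1-\beta)G_s & 0 & 0 & (1-Q_s)P_s
\end{pmatrix},$$

and the population dynamics are the nonlinear map $n_{t+1} = N(n_t)\, n_t$.
With all $u_i = 0$ the model reduces entrywise to the baseline two-sex,
two-tactic model.

## Parameters

Defaults are the bulb-mite parameterization (`demographic_params()`); the
"range" column is the interval over which sweeps vary a parameter.

| symbol | meaning | default | range | unit |
|---|---|---|---|---|
| `e0` | encounters per individual | 1 | -- | ind/day |
| `rho` | male fraction of zygotes | 0.5 | -- | -- |
| `beta` | fighter fraction of males (trait) | free | 0--1 | -- |
| `t_x`,`t_f`,`t_s` | maturation times | 13.7, 14.4, 12.6 | -- | days |
| `c_m` | male--male competition strength | 0.9 | 0--1 | -- |
| `C` | fighter cost | 0.7 | 0.5--1 | -- |
| `V` | uncontested access probability | 1 | 0.5--1 | -- |
| `eps` | sneaking success | 0.2 | 0--0.4 | -- |
| `k0` | density-free clutch size | 26.1 | -- | ind/mating |
| `sigma_zz`,`sigma_xx` | zygote, female survival | 1, 0.95 | -- | /day |
| `sigma_ff`,`sigma_ss` | fighter, scrambler survival | 0.95, 0.96 | 0.9--1 | /day |
| `u_z`,`u_x`,`u_f`,`u_s` | killing success per stage | 0 | 0--1 | -- |

Scramblers out-survive and out-pace fighters (`sigma_ss > sigma_ff`,
`t_s < t_f`); fighters out-compete scramblers in contests
(`m_fs = 0.8` vs `m_sf = 0.2` at the defaults). The evolutionary tension
between these is what sustains the dimorphism.

## The adaptive-dynamics pipeline

1. **Resident equilibration** (`run_to_equilibrium()`). The map is iterated
   until the relative state change per step falls below `tol_state` (default
   `1e-8` for exploratory use; the invasion machinery uses `1e-10`), then the
   dominant eigenvalue of $N$ at the final state is required to be 1 within
   `tol_lambda = 1e-6`. Both criteria together define convergence; a run that
   has not settled after `max_steps = 1000` continues to ten times that with
   a warning rather than failing, which keeps sweeps robust near
   bifurcations. Extinction (total density below $10^{-12}$) and boundary
   equilibria (a stage below $10^{-12}$) are flagged.
2. **Invasion fitness** (`invasion_fitness()`). A rare mutant with trait
   $\beta'$ experiences the resident's equilibrium environment: the mutant
   matrix $N'$ substitutes $\beta'$ everywhere the trait appears -- the two
   maturation entries *and* inside $P_z$ -- while every density-dependent
   quantity ($F_i$, $Q_i$, all densities) stays frozen at the resident
   equilibrium. $W(\beta', \beta)$ is the dominant eigenvalue of $N'$; the
   mutant invades iff $W > 1$. At a converged equilibrium
   $W(\beta, \beta) = 1$ by construction, which doubles as an internal
   consistency check.
3. **Selection gradient and singular points**
   (`selection_gradient()`, `find_singular_strategies()`). The gradient is a
   central finite difference of $W$ in $\beta'$ with step `h = 0.01`
   (one-sided at the trait boundaries). The scan over $[0,1]$ uses the same
   0.01 grid; sign changes are bracketed and refined by bisection to
   `refine_tol = 1e-4`. A $+\to-$ change is convergence-stable (an
   attractor), $-\to+$ a repeller. Boundaries are attractors when the
   one-sided gradient points into them.
4. **Classification** uses the three pairwise-invasibility criteria made
   programmatic: (a) the vertical-line test (can any mutant invade the
   singular resident? tolerance `neutral_tol = 1e-6` on $|W-1|$), (b)
   convergence stability from the gradient, (c) the horizontal-line test (can
   the singular strategy spread when rare against every viable resident?).
   Interior attractors of this model are *evolutionarily neutral*: a mutant
   adopting the singular strategy has exactly resident fitness, the limit
   case between a strict ESS and a branching point. The classifier labels
   them `neutral_attractor` whenever the curvature of $W(\beta')$ at the
   singular point is within `curvature_tol = 1e-5`, and reserves
   `strict_attractor`/`branching_point` for definite curvature.
5. **Sweeps** (`sweep_1d()`, `sweep_2d()`, `extract_isoclines()`). Each cell
   runs the full pipeline; failures are recorded per cell. The desk default
   is 21 cells per axis (against 100 in full-resolution runs -- resolution is
   a knob, not a constant) and contour extraction uses marching squares at
   0.1 increments, with bistable cells reported separately.

Resident equilibria are warm-started from the neighbouring trait value
during scans, which cuts equilibration to a few hundred steps per column
without changing results (the equilibrium is independent of the start, a
property the test suite checks over random initial conditions).

## Design choices

**Male fertility bookkeeping.** Crediting each birth half to the mother and
half to the father forces $F_f n_f + F_s n_s = F_x n_x$, which yields the
per-male form $F_j = B_{x,j}/(2 n_j) = k\, e_0\, n_x\, p_{x,j} / (2\sum_k
n_k)$ -- well-defined even as a morph becomes rare, which is exactly the
regime invasion analysis cares about. The package defaults to this
convention. The alternative sometimes written down, $F_j = B_{x,j}/(2 n_x)$,
credits a male with births proportional to his morph's own density; it
breaks the father/mother balance and builds a spurious positive frequency
dependence into the mating market (each fighter appears more fertile merely
because fighters are common), which destroys the interior singular point
entirely -- the baseline model then has only a repeller between two boundary
attractors. It is retained as `fertility = "per_female"` for comparison, and
the test suite pins the numeric behaviour of both.

**Encounter denominator.** Killing of zygotes requires zygotes in the
encounter pool, so all four stages enter the mass-action denominator by
default; `encounter_denominator = "adults_only"` restores the adults-only
variant for the baseline model. Equilibrium densities shift between the two,
but the location of singular strategies is insensitive to the choice.

**Killed proportion.** $Q_i = e_0 u_i n_f / \sum_k n_k$ follows from
$q_i = e_{i,f} u_i$ and $Q_i = q_i/n_i$; the target stage's density cancels,
so every stage faces the same fighter-pressure factor scaled by its $u_i$.
$Q_i$ is clamped to $[0,1]$ (reachable only when $e_0 > 1$), with a warning.
A consequence worth knowing: because the per-capita kill rate of a stage
does not increase as that stage becomes rare, killing pressure on a
vanishing morph stays bounded -- rare scramblers are *not* disproportionately
suppressed, and the scrambler-killing feedback is correspondingly gentle at
low $u_s$ (see *Behaviour*).

**Initial conditions.** No canonical initial population vector exists;
equilibration starts from $(10, 10, 10, 10)$ and the suite verifies that any
strictly positive start reaches the same equilibrium to $10^{-6}$ relative.

**Degenerate inputs.** Fertilities are defined as 0 when females or males
are absent; an all-zero population is reported as extinct rather than
raising during matrix assembly; `sigma = 1` for a morph with no mortality
source leaves the map without a fixed point, and such sweep cells are
flagged `no_attractor` instead of being assigned an ESS.

## Behaviour of the model

At the default parameterization the trait has a single interior attractor
near $\beta^* \approx 0.62$: fighters and scramblers coexist, and the
attractor is neutral in the limit-case sense above. Killing females
(`u_x`) does not move the singular point at all -- female deaths are exactly
compensated through the density dependence of clutch size. Killing zygotes
(`u_z`) or fighters (`u_f`) lowers $\beta_{\mathrm{ESS}}$ monotonically but
never to zero: a fighter that kills competitors or offspring taxes its own
tactic, yet coexistence survives the whole $u \in [0,1]$ range. Killing
scramblers (`u_s`) pushes the attractor upward (at `u_s = 0.002` the
singular point sits near 0.64, at `u_s = 0.02` near 0.75). Fighter survival
raises, and scrambler survival lowers, the attractor, each over a narrow
band of survival values; at low fighter survival combined with substantial
scrambler killing the interior attractor is replaced by *evolutionary
bistability* between the two boundary strategies ($\beta = 0$ and
$\beta = 1$, separated by a repeller that slides down as `u_s` grows) -- the
population ends up all-scrambler or all-fighter depending on where it
starts. All of these statements are computed by the test suite and the
acceptance script; the numbers quoted are those they print.

Two caveats belong here rather than in fine print. First, the fitness
landscape of this model is extremely shallow: away from the diagonal,
$|W - 1|$ is of order $10^{-3}$ or less across the whole trait plane, so
classifications inherit the tolerances above, and any reimplementation that
equilibrates less tightly can shuffle near-threshold outcomes. Second, under
the mass-action killing term the collapse to an all-fighter ESS requires
substantially stronger scrambler killing than the very low thresholds
sometimes quoted for models of this type; with saturating (per-capita)
killing the collapse happens at far smaller `u_s` but fighter--fighter
killing then extinguishes fighter expression outright. The mass-action form
is the one consistent with the encounter model, and it is what this package
implements.

## What the scenario generator does and does not emulate

`generate_scenarios()` enumerates the study conditions as fixtures: the
default parameterization, each killing probability at representative values,
the very-low-`u_s` regime, survival extremes and competition extremes, each
tagged with the qualitative outcome expected for that regime where one is
asserted. The model these scenarios feed is deterministic and unstructured
beyond its four stages: no demographic stochasticity, no environmental
variation, no individual condition distribution behind the threshold trait
(the liability mechanism is abstracted into $\beta$ directly), no genetics
beyond clonal trait substitution, and no energetic return from cannibalism
(a fertility-bonus hook is a documented extension point, not implemented).
Passing tests therefore certify the demographic and game-theoretic
machinery, not the behaviour of finite, noisy mite populations.

## Numerical footnotes

Eigenvalues come from dense `eigen()` on the 4x4 matrix; the dominant
eigenvalue of these non-negative matrices is real (Perron--Frobenius), and a
complex dominant pair raises an error rather than returning a real part
silently. The independent test oracle recomputes every matrix entry from the
scalar definitions and extracts eigenvalues from the characteristic
polynomial (Faddeev--LeVerrier plus `polyroot`), keeping the two routes
genuinely separate; they agree to $10^{-10}$ on random in-range draws.
Gradient steps halve cleanly (the Richardson check in the suite), bisection
stops at $10^{-4}$ in the trait, and all tabular output is written with
fixed 10-significant-digit formatting so repeated runs are byte-identical.
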