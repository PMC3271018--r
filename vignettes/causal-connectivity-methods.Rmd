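---
title: "Methods: causal connectivity estimation in causalconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal connectivity estimation in causalconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalconn)
```

# The problem

Given fMRI time series from a small set of brain regions recorded while
subjects perform a task, we want to know which regions causally drive which
others, whether a group of children differs from a group of adults in
specific directed connections, and whether those connection strengths carry
behavioral and anatomical signatures. `causalconn` implements a complete
analysis chain for this question — two complementary causal estimators with
a shared surrogate-null inference layer, onset-latency analysis, graph-level
hub quantification, functional-connectivity and structure-function
comparisons, and sparse behavior regression — together with a synthetic
cohort generator that produces data from the same generative model with
known ground truth, so every stage can be validated by parameter recovery.

# The generative model

The core model is a bilinear state-space system. Latent "neuronal" signals
$s(t) \in \mathbb{R}^M$ for $M$ regions evolve as

$$ s(t) = \sum_{j=1}^{J} v_j(t)\, C_j\, s(t-1) + D\,u(t) + w(t),
   \qquad w(t) \sim N(0, Q), $$

where $v_j(t)$ are modulatory task inputs (by default the single task on/off
regressor), $C_j$ is the $M \times M$ coupling matrix active under input
$j$ — entry $(m, n)$ is the strength of the directed influence of region
$n$ on region $m$ — $D$ is a diagonal external-input strength matrix and
$u(t)$ the binary stimulus vector. The observed BOLD signal is a linear
convolution of each region's latent signal with a region-specific
hemodynamic response:

$$ y_m(t) = b_m^\top \Phi\, x_m(t) + e_m(t),
   \qquad e_m(t) \sim N(0, \sigma_m^2), $$

with $x_m(t)$ the $L$ past values of $s_m$, $\Phi$ a fixed $2 \times L$
basis (canonical HRF and its temporal derivative) and $b_m$ per-region
weights, so inter-regional HRF variation is explicit in the model rather
than a confound for causality.

The canonical HRF is a double-gamma with response peak at 6 s, undershoot
peak at 16 s and peak-to-undershoot ratio 6, scaled to unit peak; the
derivative basis is its 1 s backward finite difference. These values are
conventional for task fMRI; all are configurable through
`build_hrf_basis()`.

# Estimation

`fit_mds()` estimates $\{C_j, D, b_m, Q, \sigma_m^2\}$ by penalized
expectation-maximization:

* **E-step.** Exact Kalman forward-backward smoothing on the lag-embedded
  state $z(t) = (s(t), \ldots, s(t-L+1))$. The shift structure of the
  embedded transition keeps the predict step at $O(p^2 M)$ for
  $p = ML$; the smoother is implemented in C++ (RcppArmadillo) because it
  runs thousands of times per analysis (every EM iteration, every subject,
  every surrogate fit).
* **M-step.** Conjugate closed-form updates: ridge-penalized regression for
  each region's coupling row and input strength (Gaussian prior, precision
  `ridge = 1e-3`), a ridge regression on the smoothed embedded latents for
  the HRF weights, residual-moment updates for the noise variances, and a
  baseline term per region that absorbs the session mean removed in
  preprocessing.

The objective recorded per iteration is the exact marginal log-likelihood
(prediction-error decomposition of the Kalman filter) plus the log prior at
the current point estimates; EM theory guarantees it is monotone
non-decreasing, and the package asserts this up to a relative tolerance of
$10^{-6}$ (the spectral-radius stability guard, which rescales a coupling
update whose spectral radius reaches 0.97, is the one step that can break
strict monotonicity; it essentially never triggers on realistic data).
Posterior covariances of the coupling rows are reported as uncertainty
summaries. Noise variances are point estimates (MAP under flat priors)
rather than full conjugate posteriors; for the edge-level inference the
package performs, only the coupling posterior means and their surrogate
distribution matter.

Identifiability deserves care in this model class:

* *Scale.* The likelihood is invariant under $s_m \to \gamma s_m$,
  $b_m \to b_m/\gamma$, $q_m \to \gamma^2 q_m$. The default `q_mode =
  "shared"` (one state-noise variance for all regions) anchors relative
  region scales while letting the overall scale adapt; `"fixed"` and
  `"free"` are available.
* *Sign.* $\gamma = -1$ is also invariant; after convergence each region is
  canonicalized so its estimated HRF correlates positively with the
  canonical basis.
* *Baseline.* Preprocessing removes each region's temporal mean, but the
  model's predicted BOLD has a task-locked mean. The external-input
  regressor is therefore mean-centered inside the estimator (the modulatory
  input keeps its on/off meaning), and a per-region baseline parameter
  absorbs the remainder. Without these terms the input strength $D$ is
  systematically underestimated and the HRF weights drift toward the
  derivative basis; with them, simulation recovery of the coupling matrix
  reaches correlations above 0.9 at realistic sizes.
* *Initialization.* EM is initialized by Wiener deconvolution of each
  region with the canonical HRF followed by a least-squares fit of the
  latent regression. This starts the optimization close to its optimum —
  useful both for full fits and for the shortened fits used as edge
  statistics in surrogate testing (below).

`fit_var()` / `influence_terms()` implement the complementary estimator:
conditional multivariate Granger causality on the observed series. For a
VAR($p$) fit (default order 1, BIC-free; the sampling interval makes higher
orders data-hungry), the influence of $x$ on $y$ conditional on all other
regions is $F_{x \to y} = \ln(\hat\sigma^2_{y|\text{no } x} /
\hat\sigma^2_{y|\text{full}}) \ge 0$, and the difference-of-influence
$\mathrm{doi}(x,y) = F_{x \to y} - F_{y \to x}$ is exactly antisymmetric;
its sign assigns net direction.

# Inference: surrogate nulls, FDR, group differences

Both estimators share one inference layer. Surrogate cohorts are built by
per-region phase randomization: each region's Fourier amplitudes are kept
(preserving its autocorrelation and variance exactly) while phases are
replaced by independent uniform draws, destroying all cross-region temporal
dependence — the null hypothesis of no causal interaction. The full
estimation procedure is re-run on each surrogate cohort, so the null
distribution is of *the same statistic* computed by *the same protocol* as
the observed value. For this reason the fitting configuration used for the
statistic and for its surrogates must match; when many surrogate fits are
needed, a shortened EM (deconvolution initialization plus a few iterations)
is used consistently on data and surrogates.

Edge p-values come either from the add-one empirical rule
$p = (r+1)/(n+1)$ (exact, but resolution-limited to $1/(n+1)$) or from a
Gaussian tail fitted to the surrogate null's mean and standard deviation
(`p_method = "normal"`), which matches the parametric flavor of testing a
statistic against a null distribution's location and provides the
resolution FDR control needs when the surrogate count is limited by the
cost of state-space fits. Benjamini-Hochberg FDR is applied across the
$M(M-1)$ off-diagonal edges (diagonals never enter inference).

Group differences use the difference of group statistics per edge; the
null pairs the two groups' surrogate draws (independent across groups, so
all $n_A \times n_B$ cross differences are valid null samples), again with
either empirical or Gaussian tails, and BH-FDR across edges.

# Onset latency

`fit_event_response()` regresses each region's series on the stimulus
boxcar convolved with the canonical HRF and its temporal derivative (plus
intercept and linear drift), and evaluates the fitted evoked response on a
grid upsampled tenfold relative to the TR. `onset_latency()` computes the
slope by central finite differences and returns the earliest time at which
the slope reaches 10% of its maximum within the initial rising segment
(from stimulus onset to the first local extremum of the fitted curve — a
definition that stays well-posed on noisy fits); descending responses use
the mirrored criterion. The estimator is invariant to positive rescaling
and equivariant to time shifts, which the test suite asserts directly.
Latency comparisons are paired t-tests across regions within group and
two-sample t-tests per region across groups, BH-corrected within each
family; a sign-flip permutation option is provided.

The two-basis expansion is a first-order model of timing: it represents
shifts of roughly a second faithfully and compresses larger shifts, so
latency *orderings* are trustworthy while absolute differences beyond
~1 TR are attenuated. Duration matters too: regressors are built from the
stimulus boxcar (5 s events), not onset impulses; with impulse regressors
the sustained responses of a task design are badly approximated and onset
estimates destabilize.

# Graph metrics

On the binarized significant graph, `degree_metrics()` counts out-degree,
in-degree and net causal outflow (out minus in; positive for outflow hubs),
and `node_path_length()` computes each node's mean shortest directed path
to every other node normalized by $M - 1$. Unreachable targets contribute a
finite penalty of $M$ steps — one more than the longest realizable path —
so means stay defined on sparse graphs (`unreachable = "exclude"` averages
over reachable targets instead). Hub status is tested per node by a
two-sample t-test of its per-subject metric values against the pooled
values of all other nodes, BH-corrected across nodes. Shortest paths are
delegated to igraph; the test suite checks them against an independent
Floyd-Warshall implementation on random graphs.

# Functional connectivity, structure-function, behavior

Instantaneous functional connectivity is the Pearson correlation between
region pairs after regressing out an intercept, a linear drift and any
user-supplied confound columns (the package does not prescribe a
physiological-noise model; confounds arrive as a matrix). Group comparisons
are two-sample t-tests on Fisher-z transformed correlations with BH-FDR
over pairs. Structure-function coupling is the across-subject Pearson
correlation between a per-subject functional measure on an edge and the
fiber density (or mean FA) of the corresponding region pair from a
tractography table.

Behavior prediction uses the lasso (glmnet; `alpha` exposes elastic-net
mixing, pure lasso by default since nothing selects a mixing value) on the
10 directed connection strengths, with the response standardized
internally, penalty chosen by seeded 5-fold cross-validation at the
minimum-CV-error rule, and the selected connections reported in decreasing
order of standardized coefficient magnitude. Both in-sample and
cross-validated $R^2$/MSE are reported because either could be the
headline number; per-subject connection strengths come from subject-mode
state-space fits or per-subject doi matrices.

# The synthetic cohort generator

`default_cohort_spec()` encodes the study conditions the package ships
with: five regions named for the salience-network and central-executive
nodes (rAI, rVLPFC, ACC, rDLPFC, rPPC); the right anterior insula as causal
outflow hub (edges rAI → each of the other four at strength 0.5, self-decay
0.35, spectral radius well below 1); a jittered event-related design of
52 five-second trials with a 1 s fixed gap plus uniform 0-3.5 s jitter at
TR 2 s (the jitter distribution is a modeling choice — only its range and
mean are conventionally reported — and uniform on the stated range gives
mean 1.75 s); unit state-noise and unit observation-noise variances (an
SNR-1 regime); an "adult" and a "child" group with the child rAI → rPPC
edge weakened by 0.3; subject-level Gaussian perturbation (sd 0.1) of the
nonzero coupling entries, resampled if stability is threatened; reaction
time and accuracy coupled linearly to the within-group-centered rAI
out-edge strengths with smaller behavior noise in adults (so adult behavior
is better predicted by connectivity, and group-mean RT/accuracy are set by
intercepts: children slower and less accurate); and a structural table in
which rAI-rPPC fiber density tracks that edge's functional strength in
adults only, with lower fiber density and FA means in children. Behavior
couples to *centered* strengths so that accuracy, a bounded proportion,
does not saturate at its ceiling.

What the generator does *not* emulate: spatially correlated or
physiological (cardiac/respiratory) noise, scanner drift beyond what
preprocessing removes, HRF variability across subjects, head motion,
region-size effects, or nonstationarity of coupling within a run. Passing
recovery tests on these cohorts therefore demonstrates correctness of the
estimation machinery under the model's own assumptions, not robustness to
every artifact of real fMRI.

# Numerical choices and scaled problem sizes

Defaults: EM convergence at relative objective change below $10^{-6}$ or
500 iterations; ridge precision $10^{-3}$ on couplings and HRF weights;
initial augmented-state variance 1; stability cap 0.97; embedding
$L = \lceil 32\,\mathrm{s} / TR \rceil$ so the full HRF support is covered.
TR defaults to 2 s everywhere and is configurable.

The validation suite runs the full chain many times (multi-replicate
recovery, calibration and topology studies), so it uses deliberately
scaled-down problem sizes chosen once as the smallest that keep the
scientific properties visible: cohorts of 6-10 subjects per group,
36-52 trials (≈150-240 scans), embedding lengths of 4-8 lags with the
generator and estimator sharing the same truncated HRF support, shortened
deconvolution-initialized EM protocols (applied identically to data and
surrogates) for edge statistics, and 100-999 surrogates depending on the
cost of one refit. Where a threshold interacts with surrogate-count
resolution (FDR at $q < 0.01$ needs p-values below $0.01 \cdot k/20$), the
Gaussian-tail p-method carries the resolution instead of brute surrogate
count.

# Known limitations

* The external-input strength $D$ is only weakly identified when the task
  regressor is also the modulatory input (their effects overlap during
  task blocks); couplings — the quantities inference is about — recover
  well, but $D$ estimates should not be interpreted quantitatively.
* Shortened-EM edge statistics are attenuated toward zero relative to
  converged estimates; this is harmless for hypothesis testing (the
  surrogate null is built with the identical protocol) but means reported
  strengths from short protocols are conservative.
* The state-noise covariance is modeled as diagonal (shared variance by
  default) in estimation even though the simulator accepts a general PSD
  matrix.
* Granger causality on BOLD is vulnerable to regional hemodynamic delay
  differences; the state-space model addresses this explicitly, which is
  why the package treats agreement of the two methods as the meaningful
  result.
* Conditional Granger influence is much less sensitive than the
  state-space model to weak couplings: in the validation studies, a
  0.2-strength edge observed through the HRF (the weakened hub-parietal
  edge of the child group) is recovered by the Granger route in roughly
  70% of replicate cohorts at study-size groups, while the state-space
  route recovers it essentially always. Group *differences* on that edge
  are detected reliably by both. The topology-recovery study reports both
  rates rather than hiding the gap.
* With a single modulatory input equal to the task regressor, rest periods
  carry no coupling information by construction.
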