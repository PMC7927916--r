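---
title: "Inferring cortical On-Off states from multichannel spiking activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cortical On-Off states from multichannel spiking activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onoffstate)
```

## The model

Population spiking in sensory cortex alternates between episodes of vigorous
("On") and faint ("Off") firing that are synchronous across the cortical
depth. `onoffstate` treats these episodes as the two values of a hidden
Markov chain and the multichannel spike counts as doubly stochastic
observations of it: in 10 ms bins (`w_bin`, configurable), the count on
channel $j$ in bin $t$ is Poisson with mean $\lambda_{j,s_t}$, where
$s_t \in \{\text{Off}, \text{On}\}$ is the latent phase shared by all
channels. The model is fully described by the emission matrix $\Lambda$
(channels $\times$ phases, stored internally as expected counts per bin;
multiply by $1000/w_\mathrm{bin}$ for spikes/s), the row-stochastic
transition matrix $P$, and the initial distribution $\pi_0$.

Fitting is by Baum-Welch EM (`em_fit()`), with exact log-domain forward-
backward recursions (no underflow up to at least $10^4$ bins) and Viterbi
decoding of the single most probable phase sequence per trial
(`viterbi()`). Because EM can stall in local maxima, each fit is restarted
10 times from random initializations --- $\pi_0$ and the rows of $P$ from
flat Dirichlet distributions, emission rates uniform on
$(0, 2 \times \text{channel mean})$ --- and the restart with the highest
final log-likelihood is kept. EM terminates when the relative
log-likelihood change falls below $10^{-3}$ *and* the largest absolute
entry change of $P$ and $\Lambda$ falls below $10^{-5}$, or after 500
iterations (flagged, not an error). Trials are independent sequences that
share $\pi_0$, $P$ and $\Lambda$; sharing $\pi_0$ across trials is the
standard Baum-Welch treatment and is the convention adopted here. After
fitting, phases are relabeled so that the population-mean rate increases
with the state index (state 1 = Off, state 2 = On); labels are otherwise
arbitrary under the likelihood.

Attention conditions are fitted independently (`fit_all()`): every
condition gets its own $P$, $\Lambda$, $\pi_0$ and decoded paths. Condition
differences in any statistic therefore reflect separately estimated models,
not a shared model with covariates.

## The joint two-area model

Interareal coordination is modeled with a single 4-state chain over both
areas' phase combinations, in the fixed order 1 = V1off-V4off,
2 = V1on-V4off, 3 = V1off-V4on, 4 = V1on-V4on (`em_fit_tied()`). Each
channel's emission rate is tied across the two states in which its own
area is in the same phase, so a V1 channel has one Off rate (states 1, 3)
and one On rate (states 2, 4). The tied M-step pools expected counts and
occupancies across tied states --- the exact maximizer under the equality
constraints --- so tied rates are equal to machine precision, and
initialization draws one rate per tied group. EM labels are mapped back to
the canonical order by identifying each area's On phase with its
higher-rate tied pair (`canonicalize_states()`); exact rate ties are
broken by state index and flagged.

Two scenario contrasts summarize who leads (`scenario_contrasts()`): from
both-Off, $P(1\!\to\!3) - P(1\!\to\!2)$ is positive when V4 switches On
first; from both-On, $P(4\!\to\!2) - P(4\!\to\!3)$ is positive when V4
switches Off first. Attention differences are attend-RF minus the mean of
the away conditions.

## Model validation

**Model order.** `cv_sweep()` runs 4-fold cross-validation for 1--8
phases: the model is fit on 3/4 of the trials, and on each held-out trial
the path is decoded from all channels except the scored one
(leave-one-channel-out, transitions unchanged --- removing the channel's
row from the emission likelihood only), accumulating
$\sum_t (n_{tj} - \lambda_{j,s_t})^2$. Errors are normalized to the
1-phase model and averaged over channels, folds and conditions. The elbow
rule (`select_k()`) classifies a recording as two-phase iff adding the
second phase reduces the normalized error by at least 10% and no later
phase adds another 10%; recordings with 3-/4-phase patterns are flagged
for exclusion. Incremental drops are measured on the curve normalized to
the 1-phase error (differences of consecutive values); measuring each drop
relative to the previous order is available via `relative_to =
"previous"`. Within the sweep, per-fold fits may use fewer restarts and
capped iterations (arguments pass through); the classification rests on
error drops an order of magnitude larger than the threshold.

**Variance explained.** `r2_explained()` uses two-fold cross-validation:
$R^2 = 1 - \sum_t (n_t - \lambda_{s_t})^2 / \sum_t (n_t - \bar n)^2$ on
held-out trials, per channel, across integration windows of 50--500 ms
(predicted count in a window = sum of the per-bin predicted rates). For
single units the On/Off rates are not fitted: they are the unit's mean
rates during the On and Off phases decoded from the multiunit activity on
training trials. The ceiling is $R^2_{max} = 1 - 1/FF$ (Fano factor from
the unbiased variance estimator; chosen because the timescale sweep works
with few pooled bins per window): with a perfectly known two-level rate,
the residual variance cannot fall below the Poisson variance. $R^2_{max}$
is a population-average quantity --- per channel it coincides with $R^2$
up to sampling noise on well-separated data, so ceiling comparisons should
be made on population means.

## Phase-level dynamics

Decoded paths become epoch tables (`epochs_from_path()`): maximal constant
runs with start/end times. Epochs touching a window edge are censored ---
their true duration is unknown --- and are excluded from mean-duration
statistics but retained for occupancy, which therefore equals the
duration-weighted epoch fractions exactly. Attention effects on any
nonnegative quantity use the modulation index
$\mathrm{attMI} = (A_{RF} - A_{out}) / (A_{RF} + A_{out})$.

Transition timing relative to task events uses `transition_pdf()`:
transition counts in 100 ms bins, normalized per trial and per second so
conditions with different trial counts are comparable. Rate confounds are
controlled by `rate_match()`: binomial thinning of bin counts toward the
minimum condition mean per channel, which preserves the Poisson character
and never increases any bin. Pupil-linked state is summarized per
recording as the Pearson correlation between baseline pupil (mean over a
configurable pre-stimulus window; fixation-to-stimulus by default, since
the defining window is a free choice) and the trial's mean uncensored
On-epoch duration. Behavioral linkage tables (`rt_by_state()`) pair each
qualifying trial's reaction time with the decoded state of the bin
containing its target dimming (half-open bins: an event on a bin edge
belongs to the bin starting there); the mixed-model fit itself
(`RT ~ attention * state` with recording as a random intercept) is left to
standard tools such as `lme4`/`lmerTest` on the exported table.

## Interareal coordination

`cc_hmm()` correlates the two areas' decoded series: per trial, both are
mean-subtracted and normalized so each series' zero-lag autocorrelation is
1 (denominators are per-trial, following the defining formula; a pooled
variant is not provided because the per-trial reading is the literal one),
then averaged across trials. Sign convention: with $x$ = V1 and $y$ = V4,
$CC(\tau) = \langle x(t)\, y(t+\tau)\rangle$, so mass at $\tau < 0$ means
V4 transitions lead. The trial-shuffle predictor (`shuffle_predictor()`,
100 random derangements by default --- a single shuffle is one draw of the
same estimator) removes event-locked structure; `auc_split()` integrates
the corrected curve on each side of zero (trapezoid, $\tau = 0$ excluded
from both halves so neither side claims the symmetric point).

`tta()` averages one area's mean-subtracted rates around isolated latent
transitions of the other (no neighboring transition within 100 ms),
normalized per transition, with the same shuffle predictor. The timing of
the rate change is the crossing point of two straight lines fit by least
squares (`two_line_crossing()`). The default fit is a broken stick: the
two lines are constrained to meet at a candidate crossing, scanned over a
fine grid, and the best-SSE candidate is returned. An unconstrained
variant (independent left/right lines intersected at the best breakpoint)
is available via `method = "independent"`; it is noticeably less stable on
shallow traces because near-parallel line pairs throw the intersection far
from the kink, which is why the constrained fit is the default.

## Field potentials and spectra

Preprocessing follows the standard laminar pipeline: common average
reference, bipolar derivation (superficial minus deep neighbors), MUA
envelope (rectified spiking band, 5th-order Butterworth low-pass below
300 Hz), stimulus-onset SNR over eight 50 ms windows against a
[-200, -50] ms baseline with strict $>3$ inclusion, finite-difference CSD
$(\phi(x+h) - 2\phi(x) + \phi(x-h))/h^2$ at 150 um spacing (exact on
quadratic depth profiles; no conductivity factor), and response latency
from an exponentially-modified-Gaussian plus cumulative-Gaussian fit,
with latency at 33% of the sustained (cumulative-Gaussian) component's
maximum --- the sustained term is used because the dissipating term has no
stable "peak" to reference when both are present.

State-conditioned spectra (`state_spectra()`) use epochs longer than
250 ms, zero-padded to 1024 samples so every segment shares one frequency
grid (4--200 Hz at 1 kHz); epochs longer than 1024 samples are cut into
non-overlapping 1024-sample pieces, keeping a remainder that still
qualifies. Tapers are DPSS sequences computed from the symmetric
tridiagonal eigenproblem, with $K = 7$ tapers and time-bandwidth product
$NW = 4$ --- inferred from $K = 2NW - 1$, since only the taper count is a
fixed choice. Percent change is $100 (On - Off)/Off$ per frequency.
Population receptive-field maps combine per-channel z-maps with Stouffer's
method; the standard $\sum Z_i/\sqrt{k}$ is the default and the
$\sum Z_i/k$ variant is available (`mode = "mean"`), since both appear in
practice and they differ only by a map-wide scale factor relative to the
threshold.

## Microsaccades

Eye velocity is the central difference of position, low-passed at 20 Hz
with a 2nd-order zero-phase Butterworth filter (zero-phase so onsets are
not biased late). Each trial gets a robust scale per component,
$\sigma = \sqrt{\mathrm{median}(v^2) - \mathrm{median}(v)^2}$, applied to
*velocity* --- the standard practice for this detector --- with a
position-channel variant behind `mode = "position"`. An event requires the
elliptical criterion $(v_x/6\sigma_x)^2 + (v_y/6\sigma_y)^2 > 1$ for at
least 3 consecutive samples (the two components are combined elliptically
rather than thresholded independently; at 220 Hz the rectangular variant
differs only for strongly oblique saccades); events closer than 20 ms are
merged to prevent double counting at this sampling rate. Amplitude and
direction come from the onset-to-offset displacement.
`microsaccade_free_mask()` flags trials whose analysis window contains no
event, so every analysis can be rerun on clean trials.

## The synthetic generator

`simulate_session()` produces a two-area session with known ground truth,
so every estimator above can be scored without any data download. It
emulates: two areas $\times$ 16 channels of Poisson counts driven by one
joint 4-state chain (simulated directly as the 4-state process, which
makes the joint-model quantities well-defined ground truth); a V4-lead
asymmetry encoded as $P(1\!\to\!3) > P(1\!\to\!2)$ and
$P(4\!\to\!2) > P(4\!\to\!3)$ (`make_joint_P()`); per-condition transition
matrices, with attend-RF trials leaving On more slowly and Off more
quickly; task delays drawn uniformly from the fixed monkey-1 ranges
(fixation to stimulus 614 ms; stimulus to cue 618--1131 ms; cue to first
dimming 1162--2133 ms; between dimmings 792--1331 ms), discretized to the
10 ms bin grid so ground-truth states align exactly with count bins;
reaction times $\mathrm{base} + \mathrm{offset}(s_{\mathrm{dim}}) +
\mathcal{N}(0, \sigma)$ truncated at zero; baseline pupil linear in the
trial's mean On-epoch duration plus noise; 220 Hz eye traces with
raised-cosine microsaccades (20 ms duration --- only detection, not
saccade shape, is at stake) at Poisson times, optionally coupled to
Off-to-On transitions at a fixed lead; and a laminar LFP surrogate of pink
noise plus a 5 Hz component gated to the Off phase, a 60 Hz component
gated On, and a stimulus-evoked mid-layer dipole giving the CSD a known
sink.

Default generative parameters --- Off 20 spikes/s, On 100 spikes/s,
per-bin stay probabilities around 0.95--0.97 --- echo the ~100 Hz
multiunit regime the model targets; they are testing conventions, not
claims about any dataset, since generative values are never reported for
real recordings (all are fitted). Every draw flows from the master seed
through named substreams, so a configuration reproduces bit-identically
and each component (paths, counts, delays, eye, LFP) can be regenerated
independently.

What the generator does *not* emulate --- and what passing tests therefore
do not establish about real data: stimulus drive and adaptation
(emission rates are constant within a phase), non-Poisson dispersion,
laminar rate gradients and connectivity, gradual (non-Markov) state
drift, and eye-position artifacts in the spike counts. Tests on this
generator validate the estimators under the model's own assumptions; they
cannot certify those assumptions for any recording.

## Numerical choices and conventions

- Bins are half-open $[t, t + w)$; a spike exactly on an edge belongs to
  the bin starting there. The trailing partial bin is dropped (the HMM
  needs equal-width bins). Binning conserves in-window spike counts
  exactly and is independent of spike ordering.
- Viterbi ties break toward the lower state index, making decodes
  deterministic; random tie-breaking would make paths irreproducible.
- Zero emission rates are handled exactly: probability 1 for a zero
  count, $-\infty$ log-likelihood otherwise.
- Degenerate inputs reported as missing rather than guessed: zero test
  variance in $R^2$, zero mean in the Fano factor, constant pupil,
  parallel lines in the crossing fit, empty supra-threshold RF regions.
- Fold assignment in cross-validation is a seeded random partition
  without stratification.
- The test suite and the acceptance script run at desk scale: recovery
  uses 100 trials x 300 bins x 16 channels; the model-selection study 50
  recordings of 12 trials x 100 bins per class; coordination batches 30
  sessions of 36 trials; the TTA timing check 10 sessions with a fixed
  80 ms interareal lag. These sizes were chosen so each check is decided
  by its effect size rather than by simulation noise.

## Limitations

Phases are discrete by construction; slow continuous excitability drift
is approximated by two levels. The per-condition fits cannot separate
attention effects on dynamics from attention effects on rates except
through the rate-matching control. Censored epochs make mean durations
conditional on epoch completion within the window, which shortens
apparent durations when windows are short relative to epochs. The
microsaccade detector's threshold adapts per trial, so extremely quiet
trials can produce false positives from drift alone; the merge window
and minimum-duration rule mitigate but do not eliminate this.
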