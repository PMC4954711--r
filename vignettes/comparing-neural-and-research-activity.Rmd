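---
title: "Comparing neural calcium fluorescence with research-topic activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing neural calcium fluorescence with research-topic activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FluorNet)
```

## What the package computes

FluorNet builds two kinds of "activity movies" — time-ordered frames of
spatially placed node intensities — and quantifies their resemblance.

The first kind is biological: a cultured network of excitatory neurons in
a 1 mm² dish is simulated as leaky integrate-and-fire (LIF) units with
short-term synaptic depression; spikes are converted to intracellular
calcium, read out through a saturating fluorescent indicator with noise,
and blurred by light scattering, giving a frames × neurons fluorescence
matrix sampled every 20 ms.

The second kind is bibliometric: publication or patent records carry a
year and a keyword list; yearly keyword counts form a keywords × years
matrix; keyword pairs that ever co-occur on a record are correlated over
the full time axis; the top-ranked keywords are placed at neuron
positions and their yearly counts rendered as frames, one per year.

Both movies go through the same comparison machinery: per-frame Earth
Mover's Distance (EMD) against a no-activity baseline, frame-pair EMD
between movies under an explicit alignment, and plug-in transfer entropy
for directed dependence between node series.

## The network model

The membrane potential of neuron $i$ obeys
$$\tau_m \frac{dV_i}{dt} = -V_i + \frac{I_{syn,i}(t)}{g_l},$$
with $g_l = 50$ pS, $\tau_m = 20$ ms. Crossing $V_{thr} = 20$ mV emits a
spike, resets $V$ to zero and clamps it for $t_{ref} = 2$ ms. The
synaptic current decays with $\tau_s = 2$ ms and receives delta inputs:
recurrent spikes of presynaptic neuron $j$ arrive after a delay
$t_d = 2$ ms with amplitude $\alpha_{int} A_{ji} E_{ji}(t)$, and an
independent external Poisson process per neuron arrives with amplitude
$\alpha_{ext}$.

Short-term depression follows the three-pool resource scheme: each
synapse's resources split into effective ($E$), recovered ($R$) and
inactive ($I = 1 - E - R$) fractions. A presynaptic spike moves a
fraction $U = 0.3$ of $R$ into $E$; $E$ inactivates with
$\tau_{inact} = 3$ ms and $R$ recovers with $\tau_{rec} = 500$ ms. With
homogeneous weights these per-synapse equations depend only on the
presynaptic spike history, so the state is stored once per presynaptic
neuron — an exact reduction, not an approximation.

### Unit convention

The printed constants put $I_{syn}$ in pA and $g_l$ in pS, and pA/pS is
volts; the drive term $I_{syn}/g_l$ is therefore multiplied by 1000 to
express it in mV, the unit of $V_{thr}$. Under this convention a single
recurrent spike at $\alpha_{int} = 5$ pA with $E \approx 0.3$ produces a
$\approx 2$ mV EPSP, i.e. roughly ten coincident inputs reach threshold —
the physiologically sensible regime in which 5 pA is a meaningful
starting value for the weight calibration. Any residual scale ambiguity
is absorbed by that calibration, which is the model's own mechanism for
fixing the absolute synaptic scale.

### Integration

The step updates are per-term exponential (exact for each linear decay,
with the coupling terms held over one step): this makes the pure-leak
solution $V(t) = V(0)e^{-t/\tau_m}$ exact for any step size, and leaves a
first-order coupling error of order $V \cdot dt/\tau_s$. The default
$dt = 0.1$ ms keeps that error below ~1% of threshold; the test suite
verifies a coarse run against a $dt = 0.01$ ms reference. An R-level
stepper (`stepNetwork`) states the same update in plain code and is
checked for exact agreement with the compiled loop.

### Parameters the model does not pin down

The external drive and wiring are not specified by the printed constants;
they are package design choices, fixed once:

* **External drive** — `extRate = 5` Hz, `alphaExt = 10` pA per neuron.
  One external event alone depolarizes to ~15 mV, so isolated events
  occasionally fire a neuron; background spiking stays sparse (~0.6 Hz
  per neuron) and network bursts are triggered collectively, the
  all-or-none regime described for cultured networks.
* **Topology** — neurons uniform in the unit square; directed edges drawn
  with probability $\propto e^{-(d/\lambda)^2}$, $\lambda = 0.3$ mm,
  scaled to a mean degree of 15. Short-range wiring yields clustering
  above a degree-matched uniform random graph, mimicking spatial clustering
  in dissociated cultures. An explicit adjacency matrix can be loaded
  instead.
* **Burst detection** — a network burst is $\ge$ 20% of neurons spiking
  within a 50 ms sliding window; onsets closer than 100 ms merge. Burst
  *rate* then equals count / duration. These defaults make the 0.1 Hz
  target operational; they are exposed in `BurstParams()`.

### Weight calibration

`calibrateBursting()` reproduces the two-phase scheme: every evaluation
simulates 200 s and measures the burst rate; while the 0.1 Hz target is
not bracketed the weight moves by multiplicative ±10% steps (down when
too fast, up when too slow); after bracketing, linear interpolation
between the closest bracketing (weight, rate) pairs continues until a
measurement lands strictly within 0.01 Hz of the target. Burst counts
are discrete (one burst per 200 s run = 0.005 Hz), so the accepted rates
are 0.095–0.105 Hz; a tiny numerical guard keeps floating-point rounding
from accepting a deviation exactly equal to the tolerance. Per-iteration
simulation seeds fan out from the master seed, making the whole loop
reproducible. With the defaults the loop converges from 5 pA to
$\alpha_{int} \approx 12$ pA in ~10–30 iterations.

At these constants 0.1 Hz bursting is noise-triggered (mean inter-burst
interval 10 s far exceeds $\tau_{rec}$), so repeated 200 s measurements
at a fixed weight scatter with a standard deviation near 0.02 Hz. The
converged calibration measurement — itself a full 200 s simulation — is
therefore the quantity to report as "the rate after calibration";
a single further re-run estimates the same rate with that 0.02 Hz noise.

## Calcium, fluorescence, scattering

Calcium is updated per 20 ms frame exactly as the discrete rule
$$[Ca]_t - [Ca]_{t-1} = -\frac{\Delta t}{\tau_{Ca}}[Ca]_{t-1} + A_{Ca} n_t$$
with $\tau_{Ca} = 1$ s and $A_{Ca} = 50$ μM per spike (the printed unit
is truncated; μM is the dimensionally consistent reading against
$K_d = 300$ μM). Fluorescence applies the saturating non-linearity
$F = [Ca]/([Ca]+K_d) + \eta_t$ with Gaussian $\eta_t$ of SD 0.03. Noise
is added before scattering, because the scattering formula consumes the
noisy $F_{i,t}$; noisy values are not clipped to [0, 1]. Scattering adds
$A_{sc}\sum_{j\ne i} F_{j,t} e^{-(d_{ij}/\lambda_{sc})^2}$ with
$\lambda_{sc} = 0.15$ mm, $A_{sc} = 0.15$.

## Publication activity

Record parsing supports MEDLINE tagged fields (MH/OT), WoS-style
tab-delimited exports (WC/SC) and patent classification tables
(CPC/ICL). Keywords are case-folded, trimmed of surrounding punctuation
and whitespace-collapsed — but not stemmed, which would merge controlled
vocabulary terms unpredictably. Within one record a keyword counts once
(incidence): the field tags list distinct descriptors. Duplicate records
are removed; records without a year are skipped and counted.

Correlation uses the sample Pearson formula, computed only for pairs
that co-occur on at least one record; constant series make the
coefficient undefined and such pairs are excluded. Ranking is by
descending $r$, then descending appearance count, then lexicographic
pair order — the third key is added so the order is total and reruns are
identical. "Appearance count" is read as the pair co-occurrence count
(configurable to total keyword appearances). When articles and patents
are both analyzed they are ranked separately per source.

The movie assigns each selected keyword a position drawn without
replacement from the supplied neuron-position set, and by default paints
the yearly count min–max normalized over the whole movie, so the global
minimum maps to 0 and the maximum to 1 ("similar shades" across movies).
A windowed-correlation mode (default window 5 years) paints sliding-pair
correlations onto both endpoint nodes instead; it exists because the
per-frame formula for "imaging changing correlations" is otherwise
underdetermined.

## Earth Mover's Distance

A frame becomes a *signature*: each active node is a cluster at its
position with weight proportional to intensity, normalized to total 1 —
equal totals are the condition under which EMD with a metric ground
distance is a metric. Frames with more active nodes than `maxClusters`
(default 256) are aggregated onto a coarser grid, conserving weight. The
transportation problem
$$\min_F \sum_{ij} d_{ij} f_{ij}, \quad f_{ij} \ge 0,\;
\textstyle\sum_j f_{ij} \le w_{p_i},\; \sum_i f_{ij} \le w_{q_j},\;
\sum_{ij} f_{ij} = \min(\sum w_p, \sum w_q)$$
is solved exactly by a transportation simplex (northwest-corner start,
MODI potentials, Bland's rule as anti-cycling fallback) written for this
package, since no LP solver in the dependency stack provides it; the
test suite checks it against an independent dense-simplex LP on all
small instances and verifies the metric axioms on random signature
triples. EMD is the optimal work divided by the total flow. Unequal
totals are balanced internally with a zero-cost dummy cluster, which
realizes the inequality constraints exactly.

Two conventions deserve emphasis:

* **Baseline.** An all-zero image has no unit-mass signature, so "no
  activity" is represented by the uniform signature over the node
  positions. This preserves equal total weights but shifts the absolute
  level of EMD-versus-baseline curves; their shape and argmax are
  unaffected.
* **Normalization.** Before signature construction a movie is min–max
  normalized globally (not per frame), the formalization chosen for the
  shade calibration between movies.

Frame alignment between a 20 ms-resolution neural movie and a yearly
publication movie is never inferred silently: `compareMovies()` takes an
explicit index mapping, `"identity"`, or `"peak"` (shift so the frames
of maximum total activity coincide).

## Transfer entropy

Fluorescence series are first differenced ($x_n = F_{n+1} - F_{n}$) to
suppress the slow calcium decay, then discretized — default three
quantile bins, Markov order $k = 1$, chosen for small-sample stability
since nothing in the source pins them down; both are configurable. The
plug-in estimator evaluates
$$TE_{Y \to X} = \sum P(x_{n+1}, x_n^{(k)}, y_n^{(k)})
\log \frac{P(x_{n+1} \mid x_n^{(k)}, y_n^{(k)})}
{P(x_{n+1} \mid x_n^{(k)})}$$
from empirical joint frequencies (base-2 by default, reported in bits);
`transferEntropyExact()` evaluates the same sum from a known joint
distribution. No bias correction is applied — the estimator is the bare
definition — so short series overestimate small TE values; the
convergence test quantifies this at lengths 10³ vs 10⁵.

## Synthetic corpora

`generateCorpus()` produces the record streams the analysis assumes:
log-normal latent yearly intensities (SD 0.5 in log space around a
baseline of 3 appearances/year), planted pairs sharing a latent channel
mixed as $\sqrt{\rho}\,u + \sqrt{1-\rho}\,v_k$ so the log-latent
correlation is exactly $\rho$, optional burst epochs multiplying the
shared channel by 8, Poisson counts around the intensities, and
co-occurrence placement (planted members share a record with probability
0.8; background records draw two keywords). Poisson noise attenuates the
realized count correlation — approximately by
$\sigma^2_{latent}/(\sigma^2_{latent} + \mu)$ — and the generator warns
when a requested $\rho$ exceeds that bound; a noise-free mode
(`countNoise = "none"`) exists for exact-correlation fixtures. The
defaults (45 years, ~60 background records/year, 30 keywords) mirror the
scale of a mid-sized topic export while keeping runs fast.

What the generator does *not* emulate: citation structure, vocabulary
drift, author effects, heavy-tailed keyword popularity, or the
1000-fold larger corpora of real databases. Passing recovery tests shows
the pipeline's statistics behave as designed under the stated model, not
that real corpora satisfy that model.

## Problem sizes used in the checks

The packaged tests simulate networks of 5–100 neurons for 0.2–10 s for
dynamical properties, and run the full calibration (100 neurons, 200 s
evaluations) once; corpus-recovery checks use 20 seeded corpora of ~45
years. These sizes were chosen so the whole suite completes in a few
minutes while each check still exercises the regime it is about
(collective bursting, rank recovery, LP exactness).

## Known limitations

* Excitatory-only dynamics by default; inhibitory edges are representable
  in the adjacency matrix but carry the same weight sign.
* The plug-in TE estimator is biased upward on short series.
* The transportation simplex is exact but dense; frames are capped at
  256 clusters by grid aggregation.
* Burst-rate measurements at the calibrated point carry ~0.02 Hz
  run-to-run noise; conclusions about the rate should quote the
  converged calibration measurement or average several runs.
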