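---
title: "Models and methods behind thetabeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thetabeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetabeat)
```

## What the package models

`thetabeat` implements the stimulus-design and analysis pipeline of a
two-session sleep-induction paradigm. A 6 Hz binaural beat — a 250 Hz carrier
in the left ear against a 256 Hz offset tone in the right — is mixed with an
ambient natural sound (an ASMR-style trigger) at fixed decibel ratios, and the
electroencephalographic response is summarized as band-power changes over a
seven-region 10-10 montage, a midline 6 Hz peak, a frontal alpha laterality
index, and 32-item Brunel Mood Scale (BRUMS-32) factor changes. Because no
recorded human data ship with the package, a synthetic-EEG module generates
cohorts with the statistical structure the analysis assumes, so every stage is
testable end to end.

## Stimulus synthesis

`synthesize_binaural()` renders the two tones dichotically. The beat is a
property of the *summed* channels: the envelope of the mono sum is modulated
at $|f_\mathrm{offset} - f_\mathrm{carrier}|$, which
`envelope_peak_frequency()` measures as the periodogram maximum of the
analytic-signal envelope. That measurement, not the construction, is what the
package's contract tests assert, so an error in either tone would surface as
a shifted peak.

Printed stimulus levels (45, 30, 20 dB against a fixed 60 dB natural sound)
are sound-pressure levels that cannot be realized in a digital file. The
package therefore treats them as *relative* levels on a dBFS-anchored scale:
`calibrate_rms_level()` maps a level $L$ to RMS
$r_0 \cdot 10^{L/20}$ with the anchor $r_0 = 2\times10^{-4}$ by default
(placing 60 dB at RMS 0.2, safely inside full scale). Every printed level
*difference* — the quantity the design actually varies — is preserved
exactly; `mix_combined()` verifies this by construction and rescales both
components jointly (recording the gain) if the sum would clip, so the mixing
ratio survives headroom normalization. Level is defined as whole-file RMS
averaged across channels, the simplest measurable convention.

The five natural-sound triggers (rain, waves, waterfall, forest, river) are
surrogates: seeded $1/f^\chi$ noise with per-kind spectral tilt and amplitude
modulation (`generate_surrogate_asmr()`). Real ASMR recordings are copyrighted
streams whose choice was arbitrary across subjects in the original design; a
documented filtered-noise family keeps the pipeline self-contained and
reproducible while preserving the one property the mixing stage consumes —
a broadband, roughly pink spectrum. WAV output is 32-bit float at 44.1 kHz.

## Synthetic EEG cohorts

`simulate_subject()` builds each channel as

$$x(t) = \sigma_b \, n_\chi(t) + A_\alpha \, g \, s(t)\sin(2\pi f_\alpha t +
\phi) + a \, \mathbb{1}_\mathrm{stim}(t) \sin(2\pi f_0 t + \phi_e),$$

where $n_\chi$ is unit-variance $1/f^\chi$ noise (default $\chi = 1$,
i.e. −10 dB/decade; the spectral floor is 0.5 Hz), $\sigma_b = 10\,\mu V$ is
the broadband background scale, the alpha oscillator has amplitude
$A_\alpha = 6\,\mu V$ with a per-channel gain $g \sim U(0.8, 1.2)$, a
subject-specific frequency $f_\alpha \sim U(9, 11)$ Hz and an optional
fractional suppression $s(t)$ during stimulation. The entrainment response is
a sinusoid at the target frequency $f_0$ (default 6 Hz) added to every
channel of the affected regions during stimulation, with `post_carryover`
(default 1) of the amplitude persisting into the post-stimulus rest — the
paradigm's pre/post topography comparison only makes sense if the induced
rhythm outlasts the stimulus for the two-minute rest.

The single per-subject amplitude draw $a \sim \mathrm{LogNormal}$ is the
random effect that produces the paired-design correlation structure: the
measured theta-power change scales with $a^2/2$, so the between-subject
log-scale SD $\sigma$ fixes the noise-free standardized paired effect at
$d = 1/\sqrt{e^{4\sigma^2} - 1}$. `calibrate_effect()` inverts this:
$d = 0.9$ gives $\sigma = 0.448$, and with a 7 µV mean amplitude the
spectral-estimation noise of short records is subdominant, so the measured
effect sits slightly below 0.9 (the analytic prediction for the 16 s epochs
used in the calibration tests is $d \approx 0.87$, i.e. about 85–90% paired-t
power at $n = 15$, against the ≥ 70% bound the tests assert).

Deliberately absent: volume conduction and leadfields (the analysis consumes
only channel band powers), ocular/muscle artifacts, sleep-stage dynamics, and
re-referencing (data are generated as if already referenced). Passing tests
therefore demonstrate that the *pipeline* recovers what was injected under
its own assumptions — not that real scalp EEG satisfies those assumptions.

Units are microvolts throughout; powers are reported in µV² (a log10 option
exists downstream) because the source tables' power units are unstated and
standardized effects, not absolute powers, are the calibration target.

## Preprocessing

The chain is downsample 500→250 Hz (anti-alias FIR at 0.4× the target rate),
band-pass 0.5–50 Hz, then a 58–62 Hz band-stop. All filters are
windowed-sinc (Hamming) FIR designs from `signal::fir1`, with the order set
by the ≤ 0.5 Hz transition requirement at the low edge (≈ 3.3·fs/Δf taps).
Since a symmetric FIR is linear phase, each filter is applied once by FFT
convolution with edge reflection and its integer group delay removed — this
is *exactly* zero phase (the tests assert a 0-sample cross-correlation lag)
at half the cost of a forward–backward pass, and the magnitude response is
the designed one rather than its square. Whether the notch precedes or
follows the band-pass is immaterial here because the 50 Hz upper edge already
removes the 60 Hz line; the package runs the notch last.

## Spectral summaries

Band power is the Welch PSD (4 s Hann segments, 50% overlap, density
scaling) integrated over half-open bands: delta 0.5–4, theta 4–8, alpha
8–13, beta 13–30, gamma 30–50 Hz. Half-open edges make the five bands
partition 0.5–50 Hz, so band powers sum to the total (a tested invariant).
The 4 s window gives 0.25 Hz resolution, which places a bin exactly at 6 Hz.
Regional power is the arithmetic mean of member-channel powers over the
seven regions (prefrontal, frontal, central, temporal, parietal, occipital,
midline; midline channels belong to both their lobe and the midline set).

The midline 6 Hz peak is reported as the stimulation/baseline ratio of the
mean midline PSD at the bin nearest 6 Hz. The source analysis does not state
a normalization; the ratio form was chosen because it is unitless, equals 1
under the null, and is invariant to the unknown absolute power scale.

The alpha laterality index is $LI = (L - R)/(L + R)$ with $L$ and $R$ the
mean alpha powers of the lateral prefrontal+frontal channels (Fp1, F7, F3
vs. Fp2, F8, F4); midline channels are excluded since they belong to neither
hemisphere. $LI \in [-1, 1]$, positive for left dominance.

## The statistical battery

Paired t-tests (two-sided throughout; sidedness is unstated in the source)
are computed by `stats::t.test` on the within-subject differences, with the
paired Cohen's $d = |\bar{x}_d|/s_d$, which satisfies $d = |t|/\sqrt{n}$ to
machine precision (a tested identity). Partial eta squared is
$F\,\mathrm{df}_1/(F\,\mathrm{df}_1 + \mathrm{df}_2)$, cross-checked against
the sums-of-squares route inside `one_way_anova()`.

Two design decisions deserve flagging. First, the published one-way ANOVA
dfs — (2, 42) and (3, 56) for 15 subjects — imply conditions were treated as
independent groups despite the repeated-measures design. `one_way_anova()`
replicates that layout by default for fidelity and offers
`repeated = TRUE` for the within-subject decomposition (df
$(k-1, (k-1)(n-1))$). Second, the channel × stimulation two-way ANOVA's
error term is unstated; subjects are treated as replicates within cells,
giving effect dfs (18, 1, 18) and 532 error df for the full design.
Bonferroni families are explicit by design: 3 pairwise contrasts among three
conditions, 6 among four, 19 channels for the electrode-wise tests; both raw
and adjusted p-values are always emitted because some published post hoc
p-values appear uncorrected.

`check_printed_consistency()` recomputes, for each published summary row,
the interval of $|t|$ compatible with the two-decimal rounding of its mean
and SD at $n = 15$. Fifty-seven of the sixty rows bracket their printed t;
three rows (two band rows and one mood row of the comparison session) are
internally inconsistent as printed — the adjacent p-values suggest
typesetting errors in the t cells — and the package flags them rather than
fitting to them. Similarly, the published Cohen's d values agree with
$|t|/\sqrt{15}$ to ~0.001 except one outlier (t = −3.704 printed with
d = 0.887 where the identity gives 0.957); the implementation always reports
the formula value.

## Session orchestration

`run_session1()` emits the screening-session tables (per-band change,
regional theta, across-condition ANOVAs with paired post hocs, BRUMS
changes) and a selected condition. The original selection combined
per-subject 6 Hz midline peaks with psychological stability in an
unformalized way; the codified rule — majority vote of per-subject peak
winners, ties broken by the mean calmness change, otherwise indeterminate —
is a reconstruction and is labeled as such in the output. Identical null
conditions yield no strict per-subject winners and an indeterminate
selection rather than an arbitrary pick.

`run_session2()` adds the pre/post channel topography (two-way ANOVA plus
per-channel Bonferroni-corrected paired tests), the laterality table and the
four-condition comparisons. Sub-sessions are simulated independently — the
5–10 min washout of the real protocol is not modeled because the analysis
assumes independence anyway. Session-2 "baseline" is each sub-session's own
pre-stimulus rest.

## Numerical choices and problem sizes

Degenerate inputs are rejected rather than coerced: silent audio cannot be
calibrated, zero-variance samples are degenerate for t statistics, $L + R =
0$ leaves the laterality undefined, incomplete factorial cells reject the
two-way ANOVA. Epoch bounds are half-open in samples; band edges are
half-open in frequency; the 6 Hz peak uses the nearest bin and warns if the
grid is coarser than 1 Hz.

The test suite runs the full-scale epoch layout only where it is cheap and
otherwise uses scaled designs chosen so the asserted property is far from
its decision boundary: 16 s epochs at 250 Hz for calibration loops (seven
Welch segments per epoch), 60/120/60 s at 500 Hz with all 19 channels for
the end-to-end recovery run, and a midline-only montage where only midline
statistics enter. The recovery run injects an 8 µV midline effect
(between-subject SD 2 µV), sized analytically so each midline electrode's
standardized change is ≈ 1.8 and clears the Bonferroni threshold with
probability ≈ 0.999 while the 16 unaffected electrodes stay null.

## Known limitations

The BRUMS-32 item wording is not redistributable, so the default
item-to-factor mapping assigns items in labeled blocks of four; supply the
instrument's real mapping for field use. The surrogate sounds share only
coarse spectral statistics with real recordings. No EDF I/O is provided —
recordings exchange as delimited matrices with a YAML sidecar — and the
synthetic generator makes no claim of physiological realism beyond the
features listed above.
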