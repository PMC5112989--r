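---
title: "Methods: song synthesis, feature extraction and delimitation statistics"
author: "songdelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: song synthesis, feature extraction and delimitation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
conventions behind `songdelim`, in the order the pipeline runs them. The
package targets the *Cicadetta brevipennis* group of small European
cicadas, whose calling song is a repeated binary unit (phrase 1): a long
echeme `E_L` that swells in power over several seconds, a pause of a few
tens of milliseconds (`IED_L_S`), a short echeme `E_S` built from a
handful of syllables (complete timbal cycles), and a longer pause
(`IED_S_L`) before the next unit. Some lineages insert a second phrase
(`PH2`) of fast alternating short and longer echemes; whether that phrase
is a rare courtship element or a regular part of the calling song is
itself a diagnostic character.

## The synthetic-data model

`generate_song()` renders a sine carrier (13.3–14.7 kHz depending on OTU)
amplitude-modulated by piecewise envelopes, which is sufficient because
every downstream statistic is computed from the amplitude envelope, event
timing or the power spectrum — none depends on the fine phase structure
of real timbal pulses.

**Duration model.** Each of the four phrase-1 durations is drawn
independently per group from a truncated normal with the OTU's published
cohort mean and SD (`taxon_presets()`); `E_L` durations are truncated to
the observed 0.7–60 s extremes, the short pause to the 0.03–0.14 s window
that defines a short-echeme gap, and the other durations to small
positive floors. Treating every group draw as independent, with each
recording standing for one individual, ignores the partition into
within- versus between-individual variance, which the source measurements
do not report; the consequence is that per-individual statistics built
from extremes (notably the minimum `IED_S_L` over 20 groups) are somewhat
more dispersed and lower-shifted than in real cohorts. This is a known,
accepted bias of the generator (see *Limitations*).

**Temperature.** Song tempo accelerates with perch temperature. All
drawn durations are scaled by `1 + s·(T − 25)` with a common fractional
slope `s = −0.004/°C` for every OTU, consistent with the observation
that slopes do not differ detectably between lineages and with the
magnitude of the fitted linear temperature coefficients (about
−0.002 s/°C on a ~0.5 s pause). The reference temperature of 25 °C sits
at the centre of the 17–33 °C recording range, which the generator
enforces as its valid domain.

**The long-echeme envelope.** The published shape information for `E_L`
is the standardized power staircase: average power in the six predefined
segments (0–0.05, 0.05–0.15, 0.15–0.30, 0.30–0.60, 0.60–1.50, 1.50 s–end)
rescaled to 0 at the baseline segment and 1 at the final one. A single
power-law amplitude rise cannot reproduce the four interior values to
better than ~0.09 (we verified this by least squares over the full
parameter range), so the envelope is instead piecewise linear in dB with
knots at the segment boundaries, and the knot levels are solved — segment
by segment, in closed form plus a one-dimensional root find — so that the
six segment-average powers reproduce the OTU's staircase exactly. The
overall rise is fixed at 16 dB: large enough to read as a marked swell,
small enough that the echeme onset (−16 dB re full power) stays above the
−20 dB detection threshold, which is what makes sub-millisecond onset
recovery possible. Echemes shorter than the 1.55 s needed for the full
staircase fall back to a linear-in-dB swell.

**Short echemes and chirps.** `E_S` carries a raised-cosine syllable
modulation with depth 0.8, giving `k` envelope peaks for `k` syllables
(drawn from the OTU's syllable-count distribution) while keeping the
troughs at 20 % of the echeme's amplitude — well above the segmentation
hysteresis, so a short echeme is detected as one event, yet deep enough
for unambiguous syllable counting at half-maximum. Introductory chirps
(`E_IN`) are 15–20 ms flat bursts at half amplitude; their count is
Poisson with the OTU's mean and their pauses (25–40 ms) always satisfy
the ≥ 0.015 s criterion used by the chirp-rate variable. Phrase-2 blocks
are inserted after a group with the OTU's insertion probability; each
block holds six echeme/inter-echeme groups `G2` (an `E_L2` plus the
drawn number of `E_S2`, internal gaps < 0.2 s), and the phrase-2
amplitude sits the OTU's published offset (10.6–16.4 dB) below the
average power of the long echeme's final segment, so the power-contrast
statistic is recoverable to within a fraction of a dB.

All randomness flows through one integer seed; identical arguments give
bit-identical waveforms and annotations. A background noise floor at
−80 dB re full scale keeps logarithms finite and survives 16-bit
quantization in WAV export.

**What the generator does not emulate.** Real field recordings carry
wind, heterospecific song, amplitude fading with distance and moving
singers; the carrier is a frequency-modulated pulse train, not a pure
tone, so the quartile spread of real spectra (roughly 13.4–15.8 kHz) is
not reproduced — a pure carrier concentrates the spectrum near the
centre frequency. Chirp counts are independent Poisson draws, so the
per-OTU chirp-rate percentages emerge from `P(k ≥ 2)` rather than being
matched to the published rates (e.g. petr's emergent rate is ~34 % where
real petr show 10 %: real chirp production is clustered within
individuals, ours is not). Passing tests therefore demonstrate that the
measurement and statistics machinery is correct under the published
parameter values and clean signal conditions — not that it is robust to
degraded field audio, which would need real recordings.

## Segmentation

Detection runs on a block-averaged rectified envelope at ~4 kHz
(0.25 ms resolution) smoothed over 2 ms, with a relative Schmitt
trigger: events are runs above −23 dB (re the 99th-percentile envelope
level) containing at least one sample above −20 dB; runs closer than
3 ms are merged and runs shorter than 5 ms dropped. The defaults were
chosen against the generator's amplitude plan (chirps at −6 dB, phrase-2
down to −16.4 dB, echeme onsets at −16 dB, all above threshold; syllable
troughs below −20 dB never occur because the modulation rides on the
short echeme's 0.2 amplitude floor) and are exposed in
`segmentation_config()` for tuning on other material.

Kinds are assigned by context, phrase-2 first: a maximal run of events
no longer than 0.5 s with internal gaps < 0.2 s containing at least two
0.1–0.5 s echemes is a phrase-2 block (`E_L2`/`E_S2` split at 0.1 s);
outside blocks, events over 0.3 s are `E_L`; a short event 0.02–0.15 s
after an `E_L` is its `E_S`; short events chained in front of an `E_L`
with gaps < 0.5 s are `E_IN`; a leftover short event attaches forward as
a chirp (the tie rule). The 0.3 s long/short boundary sits midway
between real short echemes (≤ ~0.1 s) and the shortest long echemes
(≥ 0.7 s); classifying phrase-2 runs before applying it prevents the
occasional 0.3–0.45 s `E_L2` from being promoted to a long echeme.

## Feature extraction

`compute_features()` aggregates the first 20 detected groups (all groups
when 10–19 are present; fewer than 10 is a minimum-sample violation, as
in the field protocol). First-20 is our convention; no selection rule is
stated for the original measurements. The phrase-2 occurrence rate uses
*all* groups of the recording, and phrase-2 structure statistics follow
their own rule: when two blocks with at least four `G2` are available,
the fourth-, third- and second-last `G2` of each of two blocks (six
total) enter the power contrast, otherwise all available ones.

Average power is `10·log10` of the mean squared amplitude — a
program-agnostic definition equivalent to RMS up to the factor that
cancels in standardization. The staircase is measured from the detected
`E_L` onset (leading chirps are separate events and never included);
echemes shorter than 1.6 s, or with a total rise under 0.5 dB, are
marked invalid and skipped. For groups followed by phrase 2 the
`IED_S_L` is undefined (the block occupies the pause) and excluded from
means and minima. Carrier-frequency quartiles come from the cumulative
periodogram (Hann window, first second of the event) restricted to the
10–20 kHz band of these songs.

## Delimitation statistics

The ANCOVA interaction screen (`value ~ temperature × taxon`) licenses
the common-slope model; the temperature GLM is then
`variable = a + b·temperature + c·OTU` with the reference pair coded
0/1 — ordinary least squares for continuous variables, log-link Poisson
for chirp counts, logit binomial (per-individual group counts as
denominators) for the chirp rate. Temperature enters in raw °C, matching
the scale on which the published intercepts live.

Classification removes only the temperature term: the partial residual
is `value − b·temperature` (on the link scale for non-Gaussian
families), keeping the OTU effect that carries the signal. The
"variance" of a reference OTU is summarized as the observed min–max
interval of its members' partial residuals — reading the original
procedure as a range criterion — with `mean ± k·SD` available as an
alternative; a reference individual inside the opposite interval is an
overlap (failure), and individuals of further OTUs are labelled by the
interval(s) containing them, falling back to the nearest interval
outside both. Putative hybrids are individuals with at least two of the
three diagnostic song characters (EP_L/1, minimum IED_S_L, chirp
number) in the overlap, or characters split between the taxa.

The PCA is a correlation PCA (`prcomp`, `scale. = TRUE`) over those
three characters, with a deterministic sign convention (dominant loading
positive). The rank-sum statistic counts pairs `x_i > y_j` plus half
ties; p-values are exact (via the null distribution) for tie-free
samples up to 20 per group and tie-corrected normal with continuity
correction beyond. No multiple-testing correction is applied — variables
are reported one by one, as in the source analysis.

## Trait matrix and diagnosis

The ten-row matrix encodes per-taxon expectations as +/− symbols with
double symbols for characters that were flawless in the reference data;
we weight single symbols 1 and double symbols 2 in a weighted
pass-proportion score (no combination rule is published; proportions
keep records with different numbers of evaluable traits comparable, and
ties are reported as ambiguous rather than broken). The altitude row's
"700–800 m" band is a single 750 m threshold (configurable); the
unstated lito expectation for EP_L/1 and the mixed petr altitude cell
are not evaluable and never count for or against. The genetic row is
evaluated only when a distance to *C. cerdaniensis* is supplied.
`simulate_trait_records()` draws matrix inputs directly from the preset
distributions (the per-individual minimum pause as a minimum over 20
group draws, mirroring measurement) so diagnosis can be exercised at
cohort scale without audio.

## p-distances

Uncorrected distances use pairwise deletion: a column counts only when
both characters are unambiguous bases, which matches common
alignment-viewer defaults; complete deletion is available as a
sensitivity switch, and the two coincide exactly on gap-free
alignments. Group means average all cross pairs (between) or unordered
intra pairs (within); undefined pairs are excluded and counted.
Percentages are rounded to one decimal only at report time. The split
of one OTU into haplogroups is driven by a user-supplied sublabel
column, never inferred. The deposited study sequences are not bundled;
`simulate_alignment()` provides clade-structured synthetic stand-ins
whose divergence is set by substitution counts, and the analysis script
scales them to the 2–3 % between-clade magnitudes typical of these
genes.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on synthetic
material at sizes chosen to make sampling error small relative to each
check: 500 groups for distribution recovery, 20 seeds × 5 groups for
segmentation boundaries (< 5 ms for ≥ 95 % of events), composite
individuals of 117 (lito) and 746 (hipp) groups for the phrase-2 rates,
100 replicates of n = 200 for GLM contrast recovery, 72 specimens for
the colouration share, and cohorts of 100 for trait-matrix accuracy.
Waveforms are double precision at 44.1 kHz; event times are derived from
integer sample counts, so annotations are exact; envelope decimation
uses integer block means to avoid resampling artefacts; truncated
normals are drawn by inverse-CDF (no rejection, fully seed-stable).

## Limitations

Beyond the field-audio caveats above: the generator's independent group
draws overstate within-individual variance, so range-based overlap
intervals are wider than real cohorts would give (a conservative bias
for delimitation claims); `bulg` carries attribute fields only, since no
usable song data exist for that lineage; the phrase-2 block length is
fixed at six groups (real phrases vary, but only blocks of at least two
groups matter to any statistic); and hybrid flagging applied to lito
correctly reports its known intermediate character (short pauses with
petr, everything else with brev) — when screening for petr × brev
contact-zone hybrids, restrict the flags to individuals of the reference
pair.
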