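---
title: "Models and methods behind oriscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oriscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriscope)
```

oriscope studies how haloarchaea use several replication origins across
several replicons. This vignette is the package's account of the models it
implements, the defaults it ships, and what its synthetic data can and
cannot stand in for.

## The population model behind marker-frequency analysis

Marker-frequency analysis (MFA) compares the abundance of each genomic
locus in a replicating (exponential) culture against a non-replicating
(stationary) one. Loci near active origins are over-represented in the
exponential sample because more cells have already duplicated them, so
origins appear as peaks in the exponential:stationary ratio along the
replicon.

`simulate_marker_frequency()` makes this quantitative with a deliberately
minimal steady-state model:

* **Cell ages.** In an asynchronous exponential culture the age density is
  $f(a) = \frac{2\ln 2}{\tau}\, 2^{-a/\tau}$ on $[0, \tau]$, where $\tau$
  is the doubling time in minutes. Division-time variance is ignored: ages
  are truncated at exactly one doubling time. This is sufficient to produce
  the characteristic MFA shapes; it slightly sharpens the profile relative
  to a culture with age dispersion.
* **Firing.** Each origin $o$ fires independently with probability $p_o$
  per cell, at time $s_o$ after birth ($s_o = 0$ by default). Origins that
  do not fire are replicated passively by incoming forks; if no origin
  fires, that cell simply remains unreplicated for the cycle. This is the
  simplest treatment consistent with $p_o < 1$.
* **Forks.** Bidirectional forks advance at $v$ bp/min and stop where they
  meet an opposing fork. On a circle this collision arithmetic is exactly
  first-arrival: the replication time of locus $x$ under a realized firing
  set $S$ is $t(x) = \min_{o \in S}\left(s_o + d(x, o)/v\right)$ with $d$
  the shorter-arc distance.
* **Copy number.** A locus has copy number 2 in a cell of age $a$ iff
  $t(x) \le a$. For a single origin certain to fire, the expected
  exponential-phase copy number has the closed form
  $M(x) = 2^{\,1 - t(x)/\tau}$, which the simulator's mean converges to;
  the test suite checks this at 500, 2 000 and 8 000 cells and at 20 000
  cells against a 3-standard-error band.
* **Noise.** Each probe and channel receives independent multiplicative
  lognormal noise with unit mean and a coefficient of variation
  `noise_cv` (default 0.1). Multiplicative noise keeps signals positive
  and scale-free, which is the dominant behaviour of two-colour array
  intensities after normalisation. The stationary channel is the same
  noise applied to a flat copy number of 1.

Profiles (`make_profile()`) scale each replicate by its stationary-channel
median before forming ratios — a robust, scale-free normalisation; the
ratio is in any case invariant to a common rescaling of one replicate's two
channels — and then average replicate ratios per probe.

### Peak calling and strain comparison

`call_peaks()` works on the circular log2 profile: local maxima with
topographic prominence at least `min_prominence` (default 0.1 log2 units)
are accepted greedily in order of decreasing prominence subject to
`min_separation` (default 50 kb). The defaults separate two origin peaks on
a chromosome-scale replicon while rejecting noise bumps at the simulated
noise level; both are tunable.

`compare_strains()` re-measures each reference peak in the mutant as
*apex over saddle*: the mutant's log2 value at the reference apex minus
the higher of its values at the two reference trough positions. A region
replicated passively by a remaining origin gives a monotone profile across
the span and therefore a height near zero, whereas a simple max-minus-min
range over the span would mistake the passive gradient for a peak. A peak
is "lost" when this height is below half the reference prominence and
below `min_prominence`.

### Origin-usage fitting

`fit_origin_usage()` inverts the forward model by grid search: per-origin
firing probabilities on a 0.05 grid and the fork time scale
$t_{ter}/\tau$ (terminus replication time over doubling time) on a 0.1
grid, minimising squared log2 error against the closed-form mixture over
firing subsets. Firing delays are fixed at zero; with desk-scale data the
delay is not identifiable separately from the firing probability, and the
simplification is stated here deliberately. Origin positions are inputs
(from peak calling or annotation), snapped to the nearest probe.

## Sequence architecture: what the scanner looks for

Characterised archaeal chromosomal origins are an AT-rich duplex-unwinding
core flanked by origin recognition boxes (ORBs) bound by the Orc1/Cdc6
initiator, next to the initiator's own gene. In halophiles the boxes carry
an extended run of guanines (the "G-string") at one end, and the conserved
chromosomal origin additionally contains a perfect G-rich inverted repeat
just inside the two boxes that acts as an initiation enhancer.

Design choices, in scanning order:

* **ORB consensus.** The packaged default (`default_orb_consensus()`,
  `TTCCAGTGGAAACGAAAGGG`) is the package's own composition: the classic
  archaeal ORB core extended with a G-rich 3' end. It is a configuration
  value, not a claim about any particular species; for real genomes supply
  a lineage-specific IUPAC consensus.
* **Mismatch tolerance.** `max_mismatch = 3` over a 20-nt consensus finds
  degenerate cluster boxes planted with up to 2 mutations while keeping the
  random-hit rate per position around $3 \times 10^{-8}$, i.e. effectively
  zero spurious hits on a 100-kb replicon (checked empirically on seeded
  genomes). Genome `N`s never match any consensus position.
* **G-strings are part of the box.** `has_gstring` inspects the hit's
  strand-aware 3' flank for at least `gstring_min = 6` consecutive G.
  Consequently the *inter-ORB interval* handed to `find_enhancer()`
  excludes each box's G-string: without that exclusion the two G-strings
  themselves (8 bp each, G fraction 1.0) would always qualify as a G-rich
  inverted repeat and enhancer-arm mutations could never abolish the call.
* **Pairing specificity.** `pair_inverted_orbs()` pairs a plus-strand box
  left of a minus-strand box (boxes facing inward, the orientation the
  planted geometry defines) with an inner gap of 20-500 bp. Two further
  requirements keep ORB-rich titration clusters from masquerading as
  origins, both discovered to be necessary on synthetic genomes: the gap
  must contain no other ORB hit (a genuine core is ORB-free), and an
  AT-rich region must overlap the gap by at least `min_at_overlap = 100`
  bp — one full AT-window's worth of core, not a marginal window grazing
  the gap.
* **AT-richness is relative.** `find_at_rich()` slides 100-bp windows
  every 10 bp and thresholds at the replicon's background AT fraction plus
  0.10 (capped at 1). Haloarchaeal genomes are strongly GC-rich, so an
  absolute threshold would misfire; conversely, at this margin isolated
  background windows do occasionally qualify on large replicons, which is
  why pairing demands substantial overlap rather than mere existence.
* **Enhancer search.** The longest perfect inverted repeat with arm length
  at least 8 bp and arm G fraction (on the G-rich strand) at least 0.8,
  found by scanning complementary-match runs along anti-diagonals of the
  pairing matrix. A G-rich sub-arm of a longer but less G-rich repeat also
  counts; ties break to the leftmost arms. Emitted arms always satisfy
  `right == revcomp(left)` exactly.
* **Titration clusters.** Groups of at least `cluster_min = 3` hits whose
  consecutive gaps are at most `max_span / cluster_min` (default 333 bp),
  not overlapping any origin candidate. A gap heuristic rather than a
  fixed window: the exemplar cluster (11 boxes in 722 bp) motivates the
  scale but does not define a rule.
* **Classification.** A candidate within 2 kb (edge-to-edge, circular) of
  an initiator gene is `ori_cdc6`, else `orphan`. Annotation pipelines
  differ in how orc1/cdc6 homologs are labelled, so `load_genome()` takes
  the tag that marks them as a required argument.

## What the synthetic genomes emulate — and what they do not

`build_genome()` plants, per origin locus: a plus-strand ORB instance with
an 8-bp G-string, a 5-bp spacer, the optional enhancer arm
(`GGGGAGGGGG` in the packaged chromosomal-origin mimic), a 150-bp AT core
at 85% AT, the reverse-complement arm, and the mirrored minus-strand box;
then a cdc6 gene (1 200 bp) 100 bp downstream, and optionally an
intergenic titration region of an exact length containing a chosen number
of non-overlapping ORB instances on random strands with 0-2 mutations
each. Background sequence is i.i.d. at 60% GC (typical haloarchaeal
composition), optionally with a leading-strand G excess switching at an
origin/terminus pair so that cumulative GC-skew analysis has a planted
signal. The three packaged configurations differ in enhancer presence and
cluster size (11 boxes / 722 bp; 3 boxes / 400 bp — the 400 is this
package's choice of a comparable intergenic span, as no length is
documented for the second species).

Synthetic data of this kind deliberately omits: dye bias and spatial array
artifacts, probe cross-hybridisation, replication-transcription conflicts,
cell-cycle structure beyond a single truncated age distribution, real
intergenic composition, and any sequence homology between loci. Passing
tests therefore demonstrate that the algorithms are correct against their
stated models, not that the defaults are optimal for any real array or
genome.

## Genetic logic and the titration model

`predict_knockout()` encodes three rules: an origin is functional iff
active with both locus and cognate initiator intact; a genotype is lethal
iff some replicon has no functional origin, or a titration region is
deleted while its regulated origin locus is retained (a deregulated,
over-initiating origin); and a viable genotype is "sick" when it removes
an initiator that is essential outside initiation. Origin activity flags
and the extra-essential set are curated data, not inferences. One
consequence is worth stating: lethality is *not* monotone under further
deletion — removing the regulated origin rescues a titration-region
deletion — so the package's monotonicity property holds for origin and
initiator deletions only.

`predict_ars()` grants a plasmid-borne origin autonomous replication iff
its cognate initiator is available from plasmid or host genome (initiators
act in trans; non-cognate initiators never substitute).
`predict_compatibility()` marks an ARS-positive plasmid integrative iff
its origin is titration-controlled and the host retains that origin locus.
This compatibility rule is hypothesis-derived — maintenance mode is
attributed to the strict regulation of the origin, not to homology length
— and is labelled as such here.

`initiation_efficiency()` is an equilibrium mass balance: total initiator
$T$ distributes over $k$ origin sites and $n_c$ competitor sites, all
independent with identical dissociation scale $K_d$ and single occupancy:
$T = F + (k + n_c)\,\frac{F}{K_d + F}$, solved for free initiator $F$ by
bisection on $[0, T]$ to a relative tolerance of $10^{-10}$; the origin
fires when all $k$ of its sites are occupied, so efficiency is
$\left(F/(K_d+F)\right)^k$. Defaults $T = 20\,K_d$, $k = 2$ put the origin
in the regime where competition matters but does not extinguish firing;
the model's job is the qualitative dose response (efficiency strictly
decreasing in $n_c$, increasing in $T$), not fitted constants.

## Numerical and scale choices

* Coordinates are 0-based half-open internally; GFF3 is converted at the
  boundary; BED/bedGraph outputs are 0-based half-open.
* Circularity is honoured everywhere: motif scanning appends a
  (consensus-length − 1) seam window, smoothing and peak logic wrap,
  skew windows wrap, and distances are shorter-arc. Candidate *pairing*
  does not pair across the seam; place the coordinate origin away from a
  suspected replication origin, or rotate the record.
* The cumulative skew track sums per-step (G−C) blocks so its final value
  equals the replicon total; because the sum is anchored at coordinate 0,
  only extrema positions are meaningful on a circle.
* Peak ties break to the lowest coordinate; skew extrema ties likewise.
* Test and demonstration problem sizes are desk-scale by choice:
  replicons of 60-160 kb, arrays of one probe per kb, 500-20 000 cells
  per replicate, 1-3 replicates. The statistical checks state their
  expected Monte-Carlo error explicitly (binomial for copy numbers,
  lognormal for probe noise) so the sizes can be scaled up without
  changing the assertions.

## Known limitations

* The simulator has no division-time variance, no B/D cell-cycle periods,
  and no fork stalling; profiles are therefore slightly sharper than real
  MFA data.
* Usage fitting assumes origins fire at birth ($s_o = 0$) and requires
  origin positions as input.
* The scanner's consensus is positionally unweighted (Hamming distance,
  IUPAC degeneracy); no PWM scoring is attempted.
* The genetic predictors are deliberately boolean; they reproduce outcome
  tables, not growth rates or transformation efficiencies.
* Plasmid maintenance mode rests on the titration hypothesis stated
  above; alternative explanations (e.g. homology-length effects) are not
  modelled.
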