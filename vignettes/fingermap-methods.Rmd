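---
title: "Methods: fingerprint physical mapping with fingermap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint physical mapping with fingermap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`fingermap` reconstructs the analysis chain of a BAC-based physical map of
a single chromosome arm: HICF fingerprints → Sulston-score overlap net →
linear contigs → minimum tiling path (MTP) → 3D pool screening →
deletion-bin map with gene-space statistics. This vignette explains the
models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the method left genuine latitude. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The fingerprint model

A clone's fingerprint is the multiset of sized restriction fragments
("bands") of its insert. SNaPshot-style HICF labels fragments in several
dye channels and sizes each within 50–500 bp, so a band is identified by
its *(dye, size)* pair. `fingermap` codes this as the integer
`(dye - 1) * 1000 + size`; sizes stay on the integer 50–500 grid within a
channel, and cross-channel bands can never fall within a small matching
tolerance of each other. With `n_dyes = 4` (default) the number of
distinguishable band positions is `gellen = 4 × 451 = 1804`.

This multi-channel grid is load-bearing. On a flat single-channel 451-value
grid, two unrelated ~70-band clones already match ~27 % of their bands by
chance, so a Sulston probability of 1e-15 requires ~74 % of bands shared —
while realistic band noise (5 % missing bands, ±1 size jitter against a
±1 matching tolerance) retains only ~70 % of truly shared bands. Every
noisy assembly would fail its own net cutoff. Multi-dye coding is both
what the laboratory method actually does and what makes the standard
cutoff ladder (1e-15 … 1e-33) meaningful.

**Noise model** (`noise_model`): each true band is dropped with
`band_miss_rate` (default 0.05), jittered by a uniform integer in
±`size_jitter` (default 1), and `Poisson(spurious_rate)` (default 2)
random bands are added. Contaminant clones — `ceiling((1-purity)·n)` of
the library, default purity 0.88 — draw all bands from a random decoy
pool: sufficient to exercise the purity handling without simulating a
second genome.

## 2. Overlap significance

For profiles with `n_low ≤ n_high` bands sharing `m` matched bands
(maximum one-to-one matching within tolerance, computed by a two-pointer
sweep in C++), the Sulston score is the upper binomial tail with
per-band match probability `x = 1 − (1 − 2·tol/gellen)^n_high`. Note the
event this models: for each band of the smaller profile, "some band of the
larger profile lies within tolerance", counted with multiplicity. A
Monte-Carlo oracle must count that event — the acceptance suite throws
continuous uniform bands on a circular axis of `gellen` positions and
counts query bands with any partner in range; a one-to-one-matching oracle
sits measurably below the formula (the score is, by design, conservative
in that respect).

Matching tolerance defaults to 1 grid unit. On an integer grid the match
window is really `2·tol + 1` values, slightly wider than the `2·tol/gellen`
the formula assumes; the score is therefore mildly anti-conservative for
random pairs, which the net cutoff of 1e-15 absorbs with orders of
magnitude to spare.

## 3. Net cleaning: questionable overlaps and clones

*Q-overlaps.* Edges weaker than 1e-25 are suspects. A weak edge is removed
when its endpoints share at least one common neighbour (so corroboration
was possible) yet no two-hop path through edges *stronger than the edge
itself* exists. Pairs with no common neighbour at all sit at
coverage-thin junctions where absence of corroboration is not evidence of
falsehood; they are kept.

*Q-clones.* A clone whose neighbourhood graph (the subgraph induced on its
net neighbours) splits into two or more components of at least
`q_clone_min_side = 2` clones bridges otherwise-separate clusters. That
pattern has two causes the topology cannot distinguish — a chimeric insert,
or a genuine clone in a low-coverage gap — so `fingermap` adds a band-level
test: the net retains sub-threshold pair evidence down to
`support_cutoff = 1e-10`, and if any clone pair *across* the two sides
shows such direct similarity, the bridge is genuine and kept; otherwise the
clone is removed and reported. Planted-chimera recall of this rule is
measured by the acceptance suite. The neighbourhood-component formulation
(rather than graph articulation points) matters: two chimeras whose
regions form a cycle protect each other from articulation analysis but
not from neighbourhood splitting.

## 4. Adaptive clustering and linearity

Connected components at 1e-15 are candidate contigs. A component is
*linear* when no clone has three pairwise-separated neighbours, where two
neighbours are separated only if they have **no edge and no other common
neighbour**. The corroboration clause is essential under band noise:
borderline edges drop out stochastically, but a dropped edge inside a
linear run leaves many common neighbours, whereas a true third branch
direction leaves none. (A bare "no edge" criterion misclassifies noisy
linear contigs as branched and shatters them down the cutoff ladder.)

Non-linear components are re-clustered at the next cutoff of the geometric
ladder 1e-15, 1e-18, …, 1e-33 (`n_steps = 6`); components still non-linear
at 1e-33 have their branching clones excluded and are re-checked. Main
contigs have ≥ 6 clones; 2–5-clone groups are short contigs.

### Layout coordinates

Each edge implies a physical distance
`insert · (1 − f)`, where `f` is the matched fraction of the smaller
profile, corrected in two ways:

* **Coincidence correction**: subtract the expected chance matches
  (`x` with the `2·tol+1` window) before forming the fraction — otherwise
  distant pairs look systematically closer than they are.
* **Retention calibration**: divide by the band-retention factor
  `r ≈ (1−miss)² · P(|jitter difference| ≤ tol)`, estimated from the data
  as the 99th percentile of corrected matched fractions (near-identical
  clone pairs attain it). Without this, noisy maps inflate ~3-fold in
  length and their depths deflate correspondingly.

Provisional ends come from a double Dijkstra sweep; clones are then placed
by a least-squares 1-d embedding: minimise `Σ (p_b − p_a − s·d_ab)²` over
all edges, signs from the seriation order, iterating sign assignment to a
fixed point. Averaging over every edge avoids the zigzag accumulation a
predecessor-offset walk suffers when nearly coincident clones are locally
permuted. Two refinements address known failure modes:

* **Containment edges** (a band set inside a distinctly longer clone's, at
  fully-matched corrected fraction and `n_low ≤ 0.8·n_high`) carry no
  distance information — the short clone could sit anywhere inside the long
  one — and are dropped from the fit, the classic buried-clone treatment.
* **Anchor votes**: for order-adjacent clones, the *difference* of their
  shared counts against a flanking anchor clone cancels the bands the pair
  has in common, leaving a nearly noise-free relative-position signal;
  a few bubble sweeps of magnitude-weighted votes fix residual local
  inversions.

Orientation remains free (layouts are reported up to reversal); the bin
map fixes it later where at least two ranked markers allow.

Contig length is `span + insert`; depth is `clones · insert / length`.

## 5. MTP, reinforcement, pools

MTP selection is a greedy end-to-end interval cover on layout coordinates
(per-clone spans estimated as `n_bands · insert / mean(n_bands)`), which
is provably minimal for interval covers and never selects buried clones.
Consecutive MTP clones whose overlap is significant only above 1e-15 risk
a sequence-level gap; one clone spanning the junction with stronger
overlaps to both flanks is added as a reinforcement when available,
otherwise the junction is flagged. Questionable clones may be appended,
labelled, excluded from coverage guarantees. Categories are disjoint, so
totals add.

3D pooling re-arrays clones plate-major into `rows × cols` plates and
forms one pool per row, per column and per plate (16/24/7 at production
scale — 47 pools for 2,528 clones). The desk-scale configuration uses
8 × 12 plates so that each pool type keeps enough pools for robust
scoring statistics at a few hundred MTP clones.

## 6. Pool-screen simulation and deconvolution

PCR screens are binary per pool: carrier pools positive (missed at
`fn_rate = 0.05`), others positive at `fp_rate = 0.01`. Array screens give
per-pool log-intensities `baseline + shift·carrier + N(0, sd)` per
replicate; the default replicate count is 10, reflecting five probes per
target hybridised in a dye-swap pair. (A literal 2 dye-swap replicates
makes a t-test at α = 0.01 unusable — df = 1 requires |t| > 63.7 — so the
probe dimension must be counted among the replicates for the published
thresholds to be operable.)

Scoring is per pool type: robust z = (pool mean − type median) / type MAD,
with a fallback chain type-MAD → global MAD → global sd because a carrier
contaminates the scale of small pool sets; positives at a confidence tier
need `z ≥ C(tier, type)` — C defaults: column 2.8/2.6/2.4, plate
1.6/1.6/1.4, row 2.6/2.4/2.2 for high/medium/low — *and* a replicate
t-test against the type median at p < 0.01 in the positive direction.
Zero-variance replicates skip the t-test and are flagged. Tiers nest by
construction.

Deconvolution intersects positive rows × columns × plates over occupied
wells. Single candidates are assigned; multi-candidate sets are resolved
by overlap consistency: candidates grouped by "same contig, spans within a
window", and a unique group of ≥ 2 mutually overlapping clones is the real
location (the remaining candidates are address ghosts — with two carrier
clones, the address intersection necessarily contains spurious
combinations). No unique group → ambiguous; PCR reports these as needing
colony PCR, arrays discard them (cross-hybridisation). An optional prior
(contigs already known to bear the marker) can restrict candidates first.

## 7. Bin map, ordering, supercontigs, gene space

A deletion line retaining fraction FL of the arm keeps `[0, FL)`:
absent/absent places a marker distal to the larger FL, present-only-in-the-
larger between the FLs, present/present proximal (refined only with
genetic evidence); present only in the smaller-FL line is impossible and
flagged. Contigs take the majority bin of their markers, conflicts
preserved, never resolved silently. Corrected bin size divides mapped bin
length by map coverage; with the default total (the sum of the bin
lengths) corrected sizes sum to the arm length *exactly* — an algebraic
identity the suite asserts.

Within bins, contigs sort by median primary-reference ortholog rank;
contigs with only secondary-reference (synteny-zipper) ranks are
interleaved after rescaling the secondary scale onto the primary by a
linear fit over contigs carrying both (falling back to raw ranks when no
such contigs exist). Ties break by minimum rank then contig id. Flags:
orthologs hit by non-adjacent contigs (duplication candidates), and
contigs whose ranks split into clusters separated by more than 5 % of the
reference rank range (split locations). Supercontig elongation merges
contigs whose *end clones* (window 2) overlap at 1e-15 — such edges exist
because adaptive splitting and Q-removal are more stringent than the net —
provided the merged layout stays linear; member bookkeeping is preserved
and merges form a partition. The ordered map exports as AGP v2.1, one
object per bin, contigs as W components, 100-bp U gaps, `?` orientation
for unorientable contigs.

Genes on the same or overlapping clones form islands (graph components of
size ≥ 2); the per-bin table reports syntenic/non-syntenic and
island/isolated counts and densities per Mb of mapped length, whose row
identities hold by construction. `pearson_with_p` is the plain Pearson
r with the t-distributed two-sided p on n−2 df.

## 8. The stated desk-scale world

The production-scale inputs (a 258 Mb arm, 26,112 fingerprinted clones)
are not reproducible at desk scale, so the recovery criteria run on a
1,000-clone world that preserves the statistical regime:

* **standard**: 12,250 kb arm, 15 unclonable zones of 150 kb → 10,000 kb
  clonable; 1,000 clones of 143 ± 25 kb at 88 % purity = 12.6× clonable
  coverage, the production figure; default band noise.
* **ample** (for the noise-free recovery check): 6,834 kb arm, 12 zones →
  25× coverage.

Unclonable zones wider than one insert make the true coverage islands
well-defined independently of any detection threshold — they are also why
real maps come out in dozens of contigs rather than one. The ground-truth
partition links clones overlapping by at least the calibrated minimal
detectable overlap (`detectable_overlap_kb`), computed from the scoring
model alone. These worlds were frozen from feasibility arithmetic before
any recovery test was run.

What the generator does *not* emulate: sequence-level structure (no
nucleotides, no restriction-site realism), vector/host band
contamination, partial digests, cross-well contamination, probe design
(probe behaviour is planted directly), and hybridisation physics. A green
recovery test therefore establishes the statistical machinery — matching,
scoring, cleaning, clustering, layout, deconvolution — not robustness to
laboratory artefacts upstream of band calling.

## 9. Numerical choices and degenerate inputs

* All generators are pure functions of (parameters, seed); RNG state is
  restored after each call.
* Sulston tails are evaluated with `pbinom(..., lower.tail = FALSE)`
  (accurate far below 1e-300 is not needed; p values bottom out around
  1e-90 here and remain representable).
* Pair pre-filtering: only pairs that could possibly reach the laxest
  retained cutoff (shared ≥ `log(cutoff)/log(x_max)`) are scored.
* Empty fingerprints are legal and flagged; single-clone layouts are
  trivially linear with length one insert; zero-MAD scales fall back as
  described; a zero mapped length is an error for bin-size estimation.
* The least-squares embedding anchors its translation null space with a
  tiny diagonal regulariser; component connectivity is asserted upstream.

## 10. Known limitations

* Clones a few kb apart are genuinely interchangeable at HICF resolution;
  layout orders are exact only up to such local ties (the noise-free
  50-clone criterion, Spearman |ρ| ≥ 0.99, is the resolution limit, not a
  convention).
* The Q-clone rule cannot rescue a genuine bridge whose flanks share no
  sub-threshold similarity at all; such clones are removed, as the
  laboratory protocol also removed them, and the contigs end there.
* Within-bin order for contigs lacking ranked markers is undefined
  (`unplaced`), mirroring the unresolved residue of real maps.
* The pool-scoring C statistic is a robust z operationalisation; the
  original normalisation lives in unpublished scripts, so only the
  threshold-plus-t-test contract is reproduced.
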