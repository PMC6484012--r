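---
title: "pioneerscan: methods and design notes"
author: "pioneerscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pioneerscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pioneerscan` implements the statistical core of a multi-omic analysis of
how a transcription factor shapes open chromatin across developmental
time: overlap statistics between peak sets, known-motif enrichment and
PWM clustering, ATAC footprint and nucleosome-occupancy analysis,
per-factor chromatin-opening ("pioneer potential") indexes, and
peak-to-gene integration with cell-type gene-set enrichment. A
synthetic-data generator with planted ground truth makes every stage
testable end to end without external data.

This vignette records the models, the tunable parameters and the design
choices that were genuinely open, so a maintainer can see why each knob
sits where it does.

# Coordinate and data conventions

All intervals are 0-based half-open (BED convention) internally; 1-based
formats are converted at the I/O boundary only. The core containers are
plain data frames with light S3 classes (`peak_set`, `cut_track`,
`fragment_set`, `pwm`); interval algebra is delegated to IRanges,
sequence I/O to Biostrings.

# Interval statistics

**Jaccard.** Base-pair mode is intersected over union bases of the
merged sets. Count mode pools and merges both sets into union regions
and reports the fraction of union regions overlapping peaks of both
inputs, counting each union region once, which keeps the statistic
symmetric and bounded by 1.

**Summit-confocal co-occurrence.** Two peak sets are compared over a
universe of candidate regions. A universe region is confocal with a
summit when the summit falls within a 3 kb window centered on the region
midpoint; two summits co-localize when additionally they lie within
20 bp of each other. The count of doubly-matched regions is tested
against Hypergeometric(N, K, n) and reported as ln P(X >= k). The
universe is deliberately explicit: the natural default is the merged
open-chromatin set of the matching timepoint (ChIP peaks are tested
against open chromatin), but any region set can be passed, and the
minimum-overlap rule is a parameter. Both choices materially affect N
and therefore the tail, which is why they are arguments rather than
constants.

**Feature enrichment.** Overlapping annotation categories are resolved
by the precedence promoter > 5'UTR > 3'UTR > exon > intron > ncRNA
(standard annotator behaviour); uncovered bases are intergenic. Each
peak is assigned one category by its summit, and enrichment is
log2((peak fraction + eps)/(genome fraction + eps)) with eps = 1e-9 so a
zero genome fraction reports NA rather than an infinity. The promoter
default is TSS +/- 1 kb, exposed as an argument.

**Knockout region loss.** A control region is lost when it overlaps no
perturbed region by >= 1 bp. A coverage-ratio mode (perturbed coverage
< 0.5x control after per-million scaling) is provided because
"lost by overlap absence" and "lost by coverage drop" are different
operational definitions and the choice is not neutral; overlap absence
is the default.

# PWM machinery

PWMs are column-stochastic 4 x width matrices with a background model.
JASPAR count matrices are smoothed with one total pseudocount per
column, split by the background frequencies, before normalization
(Laplace-style smoothing; keeps all log-odds finite).

**Scanning.** The match score is the log2 odds sum over columns; both
strands are scanned and windows containing N are skipped. P-values come
from the exact distribution of the score under the background model,
computed by dynamic programming over columns with distinct partial sums
kept exactly (merged at 1e-9 resolution). A 1e-6 guard absorbs the
per-column float drift so a query exactly at a score level includes that
level's mass. The default match threshold is p <= 1e-4 per position,
the conventional scanner default.

**Similarity and clustering.** Similarity slides one matrix against the
other over all ungapped offsets and both orientations, requiring at
least 5 aligned columns; `cor` is the Pearson correlation of the
flattened aligned probability cells (defined as 0 when either side has
zero variance), and `ncor` scales cor by aligned width over the union
width spanned by both matrices at that offset. Union-width
normalization penalizes short spurious overlaps, which is the point of
a normalized correlation. Clustering is average-linkage agglomeration
on d = 1 - ncor, merging the best pair by average ncor at each step but
only while the pair passes both gates (average cor >= 0.6 AND average
ncor >= 0.4); ncor drives the distance and cor acts purely as a gate,
mirroring the dual-threshold convention for motif trees.

**Binomial enrichment.** For each PWM, the fraction of foreground
regions with >= 1 match is tested against Binomial(n_fg, p0), where p0
is the match rate in a background that is length-matched to the
foreground by resampling real background subsequences (this preserves
the background's empirical word content, a simple faithful stand-in for
"assuming random representation of decamers" without fitting a
high-order Markov model). When p0 is zero but matches exist in the
foreground, p0 is floored at 1/(n_bg + 1) and flagged. The empirical
FDR shuffles every PWM's columns (which preserves the information
content but destroys the motif), reruns the enrichment - twice by
default - and reports, per observed motif, the mean randomized count at
or below its p-value over the observed count; only the top 20 motifs
are reported by default.

# ATAC signal layer

**Cuts.** Each fragment contributes two cuts at the 5' bases of its
ends; the Tn5 +4/-5 offset correction is flag-controlled and on by
default. Whether upstream processing already applied the offset cannot
be detected from a cut track, hence the flag; the synthetic generator
emits already-positioned cuts, so default tests are offset-neutral.

**Open-region calling.** A deliberately simplified Poisson caller:
300 bp sliding windows (step 50) tested against
Poisson(max(lambda_global, lambda_local)), merged when significant, with
summit at the maximum-count base. The local rate is estimated with the
test window *excluded*; otherwise any region wider than the test window
leaks into its own background and masks itself. For the same reason the
default local window is 10 kb only: a 1 kb local window estimated from
the treatment track sits mostly inside real regions (~500 bp long) and
suppresses them below the fold gate - the same consideration that leads
full-scale callers to skip the small local window when no control track
is available. Both window sizes remain available as arguments, and the
calling gates are the conventional ones (p <= 1e-4, fold >= 4).

**Footprints.** A footprint is focal depletion of cuts over a motif
span relative to its 50 bp flanks: score =
log2((flank cuts/bp + 0.5)/(center cuts/bp + 0.5)), with a binomial
depletion test P(X <= x_center), X ~ Binomial(n_total,
w_center/w_total), BH-adjusted across sites. A site is called when
score >= 1, q <= 0.05 and the flanks carry >= 10 cuts. The epsilon of
0.5 pseudo-cuts/bp stabilizes the log at low depth and means the score
only clears 1 when the flanks are reasonably covered - shallow sites
are (correctly) not callable. This transparent flank/center score is an
original caller: published footprinters vary widely and the operative
definition here is simply "focal depletion", which this statistic
measures directly and which an oracle can verify by construction.
Control-vs-knockout comparisons use per-site score t tests and a
matched-loss statistic (a control footprint is lost when no knockout
footprint of the same PWM lies within 10 bp of its center).

**Nucleosomes.** Occupancy is the Gaussian-kernel density (bandwidth
20 bp) of midpoints of nucleosomal-length fragments (150-250 bp,
boundaries configurable), scaled per million fragments. NFR-nucleosome
pairing finds, within each open region, local occupancy maxima paired
with the nearest smoothed cut-signal maximum at least 300 bp away,
ranked by the accessibility differential; ties go leftmost for
determinism.

**High-confidence ChIP peaks.** Regions supported by >= 2 replicate
peak sets are re-tested against a Poisson null scaled from the
input/isotype control (tags capped at 1 per position first), with
p <= 1e-4, fold >= 4 and BH FDR <= 1e-3. The per-position cap is
applied to both tracks before counting, without strand separation.

# Pioneer analysis

For each factor, candidate sites carry four flags: open at t1/t2
(overlap with the timepoint's open-region set) and footprinted at t1/t2
(a called footprint of the same PWM within 10 bp). The opening index is

OI = #(closed_t1 & open_t2 & footprinted_t2) / #(closed_t1 & footprinted_t2)

and pioneer potential PP = log2((OI + 1e-3)/(bg + 1e-3)), where bg is
the global closed-to-open rate over all candidate sites of all factors.
Conditioning the footprint requirement on the *later* timepoint is a
declared choice (recorded in the table's metadata): it reads OI as "of
the sites this factor demonstrably occupies late, how many did it open",
which is the recoverable quantity on synthetic truth. The KS test
compares PP between differentially and comparably expressed factors; for
small groups the permutation null is enumerated exactly (which also
handles ties correctly), falling back to the asymptotic test beyond
20000 splits. "Intervals of pioneer potential" for cumulative plots are
deciles of PP.

# Integration

Gene-set enrichment is a one-sided Fisher exact test per set over an
expression-aware universe (genes in the TSS table with FPKM >= 1 in the
matching expression table, a configurable threshold) - without an
expression filter the universe inflates and every neuronal set enriches
trivially. The adjustment is Benjamini-Hochberg by default with a
strict Bonferroni mode also provided, since FDR control is the standard
companion to Fisher batteries but some reports prefer family-wise
bounds. A gene is a target when >= 1 high-confidence peak has it as
nearest TSS; an optional mode assigns distal peaks to the nearest gene
with significant expression change instead. Knockout dependence is
up/down/ns at q < 0.05 on the knockout DEG table, NA for absent genes.
Occupancy-accessibility correlation is Pearson on log2(x+1) per-million
coverages with the classical t = r sqrt((n-2)/(1-r^2)).

# The synthetic study

The generator emulates a two-timepoint (embryonic "t1", postnatal
"t2") x two-condition (control, conditional knockout) design. Default
scale: 2 chromosomes x 2 Mb, 10 factors x 60 sites plus 200 background
open regions, 2000 genes with 3 replicates per group.

Signal model: cuts are drawn per base as Poisson with rate 0.05
outside open regions and 2 inside (so a 100 bp flank carries ~200 cuts
- comfortably above the caller's 30-cut working range), multiplied by a
depletion factor 0.1 over bound motif spans. Open regions persist from
t1 to t2; each factor's closed t1 sites open by t2 at rate 0.8
(designated pioneers, 3 by default) or 0.1 (others). At t2 every factor
also engages its non-opened sites as "closed-bound" micro-footprints: a
local accessible patch (1 cut/bp over the motif +/- 50 bp) with the same
central depletion. These patches are footprint-callable but sit below
the open-region caller's fold gate, so such sites count as closed -
without this class, every called footprint would lie inside an open
region and the opening index would saturate at 1 for every factor,
making pioneer ranking meaningless. Nucleosomal fragments (lengths
~N(185, 15) truncated to [150, 250]) are drawn at dyads phased 200 bp
apart flanking each region center; NFR fragments (~N(60, 15) truncated
below 100) at region centers.

Knockout effects are planted as exact counts so recovery is assessable:
per-factor footprint losses first (focal factor 0.96 at t1 / 0.39 at
t2; SOX2-like 0.93 and NF-I-like 0.84 at t1; 0.60/0.30 otherwise),
then region losses (0.50 at t1, 0.22 at t2) drawn only from background
regions and regions of already-lost footprints, so retained footprints
always sit in retained regions and both planted fractions are
simultaneously recoverable. This ordering requires each factor's
footprint loss to be at least the region loss at that timepoint, which
the defaults satisfy.

Expression: log-normal baselines (log2 mean 5, sd 2), developmental
shifts of 2 log2 units for the pioneers and a random-sign 20% of other
genes, knockout shifts per planted cell-type set (70% of the "amacrine"
set induced at t1, etc.), replicate noise sd 0.25. DEG tables use
limma's moderated t with BH adjustment: at n = 3 replicates a per-gene
Welch test is underpowered and misses planted DE genes often enough to
break the generator's DE-flag contract, and variance moderation is the
field-standard remedy. ChIP simulation centers peaks on the focal
factor's bound sites with 20 bp jitter, 10% per-replicate dropout and
Poisson background peaks, plus a simple tag model (rate 1 inside peaks,
0.02 outside; isotype control background-only).

What the generator does *not* emulate - and hence what green tests do
not certify on real data: Tn5 sequence bias, GC effects, mappability,
replicate batch structure, overdispersed (non-Poisson) coverage,
fragment-length mixtures beyond the two planted classes, and genuine
motif co-occurrence structure. Passing recovery tests demonstrates the
estimators are correct under their stated model, not that the model
captures every property of real chromatin.

# Problem sizes and determinism

Unit tests run on 0.1-0.5 Mb genomes; the seed-suite properties
(footprint sensitivity/specificity, pioneer ranking, KS separation) use
100 seeds at reduced per-seed scale, chosen so each property still has
the sample size its tolerance needs (e.g. 25 bound + 25 null sites per
seed for the footprint rates; 10 factors x 20 sites for ranking). The
acceptance script runs the full design at 2 x 1 Mb with 60 sites per
factor, where the planted-fraction granularity (1/60 per site) is finer
than the +/-3-point recovery bands it reports against. Every stochastic
path flows through R's RNG, so a single seed makes generator outputs
and pipeline TSVs byte-identical across reruns (the summary file, which
carries a wall-clock line, is the one deliberate exception).

# Known limitations

- The open-region caller is intentionally minimal (no fragment-model
  shifting, no broad calls); it is calibrated for the generator's
  signal regime and small studies, not a MACS2 replacement.
- The footprint score conditions on candidate sites from the scanner;
  de novo footprint discovery is out of scope.
- PWM clustering is O(n^2) in the number of motifs with an O(n^3)
  worst-case merge loop - fine for hundreds of motifs, not for tens of
  thousands.
- The closed-bound patch model makes "footprinted while closed"
  detectable by construction; on real data that signal class is fainter
  and its recovery rate should be expected to be lower.
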