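---
title: "Mapping saltovirus integration sites from virion reads: models and methods"
author: "SaltoMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping saltovirus integration sites from virion reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transposable phages (saltoviruses; phage Mu and the Mu-like D3112 group of
*Pseudomonas aeruginosa* are the classic examples) replicate their genome by
replicative transposition: during the lytic cycle the ~37 kb phage genome is
copied into many positions of the host chromosome. Virion DNA is packaged
from these integrated copies together with the flanking host DNA — a short
left flank in a tight 31–36 bp range where packaging initiates, and a longer
right flank of up to a few kilobases filled in by headful packaging.
Sequencing virion DNA therefore reads out, at base-pair resolution, where
each packaged genome copy had inserted: every read spanning a phage–host
junction pins one transposition event to one host coordinate.

SaltoMap implements the full computational path from virion reads to an
integration-site landscape:

1. **junction extraction** — recognise reads carrying a phage end plus host
   DNA, apply the strict valid-read filter used with right-end enrichment
   libraries, and trim the phage portion;
2. **site mapping** — place the trimmed host fragments on a reference genome
   and tally events per position and orientation (`SiteTable`);
3. **coincidence statistics** — compare the number of positions hit
   repeatedly with a closed-form random-placement model;
4. **hotspot analysis** — call positions with extreme event counts, derive
   the adjacent degenerate consensus element, scan the genome for further
   occurrences, and quantify the motif-associated share of events;
5. **coldspot analysis** — sliding-window event density against GC content;
6. **self-insertion topology** — analyse the rare events that escape target
   immunity and land in phage genome copies, segmenting the phage genome
   into insertion-density domains, pairing them into supercoiled loops and
   locating the protected central gap (the strong-gyrase-site candidate).

A synthetic virion-read generator with ground-truth event tables makes every
stage testable without external sequence archives.

## The valid-read filter and trimming

Right-end enrichment digests virion DNA with a rare-cutting enzyme whose
last recognition site sits 181 bp before the phage right end, then size
selects and sequences the right-end fragments. `filterValidRight()` keeps a
read iff the read (or its reverse complement) **starts precisely** with that
181 bp right-end sequence and at least 12 bp of flanking DNA follow. "Starts
precisely" is implemented as an exact prefix match; a mismatch allowance
exists (`maxMismatch`, default 0) because tolerated sequencing errors are a
data-set property, not a constant of the method. Rejected reads are tallied
by reason, and the filter is idempotent and orientation-symmetric.

Left-end junctions (`extractLeftJunctions()`) are found by exact-match
seeding with the terminal 20-mer of the phage left end, followed by
extension at 95% identity; at least 12 host bases must precede the junction.
Each read counts one event; deduplication across overlapping reads is not
attempted because the flank-length distribution (31–36 bp over millions of
molecules) makes physical duplicates indistinguishable from independent
events with identical coordinates.

PCR chimeras that mimic junctions are bounded with the truncated-genome
control (`chimeraControl()`): mapping the read set on phage genomes
truncated at the left end and counting apparent junctions at the artificial
ends whose overhang places on the host genome.

## Fragment placement

`placeFragments()` is a purpose-built seed-and-extend placer, not a general
read mapper: fragments are short (typically 31–69 bp), error-free or nearly
so, and need exact accounting of the junction base. Three exact k-mer seeds
(k = 15; fragment start, middle, end, both strands) propose candidates,
verified by ungapped comparison; a gapped alignment fallback
(`Biostrings::pairwiseAlignment`) handles the rare candidate within the gap
budget. Acceptance thresholds mirror standard mapping practice: mismatches
at most 2% of fragment length, gaps at most 3%, identity at least 95%, with
fractional limits **floored** per fragment — so a 34 bp flank tolerates zero
mismatches. Fragments with several best-scoring locations are `ambiguous`
and excluded from the site table (the count is reported); this is a policy
choice, made explicit and configurable by filtering the placement table
otherwise.

The recorded junction position is the **first host base adjacent to the
phage end**, for both ends: for right-end fragments the low coordinate of a
plus-strand placement and the high coordinate of a minus-strand one, and
mirrored for left-end fragments. Plus-strand placements are `forward`
integrations. Internally all coordinate arithmetic is 1-based inclusive;
circular references wrap.

## The coincidence model

If T events fall uniformly on a genome of N positions, with R = T/N, the
expected number of positions carrying two coincident events is E2 = T·R/2,
and higher orders follow E(i+1) = ln(1/(1−R))·Ei/(i+1). The approximation
is good for R below 0.1 (a warning is raised beyond, and toy-scale runs of
the bundled pipeline do exceed it). `expectedSpectrum()` implements the
recurrence:

```{r}
library(SaltoMap)
expectedCounts(expectedSpectrum(25000, 6.3e6))
#>            2            3            4            5
#> 4.960317e+01 6.574319e-02 6.534725e-05 5.196664e-08
```

Interpretation: E2 approximates the expected number of coincident **pairs**
(C(T,2)/N), which for small R is indistinguishable from the number of
positions with at least two events; at the edge of validity (R near 0.1)
the two diverge by several percent, the pair count being the quantity the
closed form tracks. `observedSpectrum()` therefore reports both the
exactly-i and at-least-i counts so either comparison can be drawn, and
`coincidenceMonteCarlo()` provides the balls-in-bins check (mean pair count
agrees with E2 to within 2% at T = 100, N = 1000). Orientations are summed
when counting coincidences.

## Hotspots, the consensus element, and the motif scan

`callHotspots()` flags positions whose event count reaches a per-position
threshold — 3000 events in a 13.4-million-event experiment — and merges
above-threshold positions within 20 bp into one hotspot with paired peaks.
The pairing reflects the target-site duplication: forward and reverse
junctions of events at one site map a few bp apart, producing twin peaks.
The duplication length is not established for the D3112 group; 5 bp is
adopted from the observed paired-peak shift and kept configurable
(`duplicationOffset`). Because simulated experiments are smaller than 13.4M
events, the threshold auto-scales with the observed event total
(`referenceTotal` argument), keeping "hotspot" depth-invariant.

The conserved element adjacent to hotspots is recovered without a general
multiple aligner: the motif region aligns gaplessly, so `buildConsensus()`
finds a seed k-mer shared by a majority of the flank sequences, anchors an
ungapped column-wise alignment, extends while each column stays dimorphic
at 75% joint frequency, and trims terminal columns less conserved than the
seed's own worst column. Each column's IUPAC code covers the bases at
frequency 0.25 or more. This is a deliberate substitution for an aligner:
it is exact for gapless conserved blocks and degrades conservatively
(flagged empty result) otherwise. Known limitation: with ~14 flanks on a
65% GC genome, a terminal S (G/C) column is statistically thin against
GC-rich background, so block edges can shift by a column on noisy input.

`scanIUPAC()` scans both strands for the degenerate consensus, counting a
window position as mismatched when the genome base is **not a member** of
the motif column's IUPAC set; at most 3 mismatches by default. Overlapping
opposite-strand hits at one locus (the element is quasi-palindromic)
deduplicate to the fewer-mismatch hit. Indel-tolerant matching is not
implemented: a mismatch-only scan is the documented default, and hits whose
published description involves indels will be missed. The scanner is
verified against a brute-force sliding-window oracle in the test suite.
`motifEventShare()` then reports the fraction of all events within 120 bp
of any hit and the fold bias over the deduplicated footprint.

## Coldspots

`densityGCTrack()` computes events/kb and GC fraction in 1 kb windows
stepped by 200 bp (both configurable; the published region boundaries do
not state a window, so these are this package's operationalisation).
`callColdspots()` reports maximal runs of windows below 10 events/kb, at
least 1 kb long; runs separated by less than one window merge, so a single
noisy window inside a large cold region does not split it. Aggregate
density and GC are means over the member windows. The 10/kb rule is
calibrated to a full-depth experiment averaging 1300–1800 events/kb;
regions of intermediate density (e.g. ~30 events/kb at 52% GC, the rRNA
operon regime) are deliberately **not** coldspots, and the simulator's
52%-GC island verifies this distinction.

## Self-insertion domains, loops and the protected gap

Target immunity keeps the phage from inserting into its own copies, but
leaks: a fraction of events (0.4% in the modelled system) self-insert.
Their positions along the phage genome are binned at 50 bp
(`binProfile()`), and `segmentDomains()` places domain boundaries at sharp
local maxima: bins exceeding 5× the running median (21-bin window, floored
at one event), at least 10 bins apart. Bins inside user-supplied exclusion
zones — e.g. ±1 kb around a restriction site used for enrichment, which
creates artifact peaks — are masked before peak calling. Domains are the
inter-peak intervals plus two terminal intervals and tile the genome
exactly; the boundary bins themselves count toward neither domain (their
events are reported as `boundaryEvents`, masked-zone events as
`maskedEvents`), since crossing points are inaccessible to transposition in
the loop model. Domain density is count/(span length in kb) over the full
span.

`pairLoops()` encodes the supercoiled-loop reading of a nine-domain
profile: excluding the terminal domains, the interior domains pair
outermost-inward (second with second-to-last, …) and the central domain
forms the apex loop; per-loop event shares come from the domain counts.
`protectedGap()` searches ±1 kb around the genome midpoint for zero-event
runs of ≥30 bp — the protected core signature of a strong gyrase site.

## The synthetic generator: what it emulates, and what it does not

`makeHostGenome()` builds a circular chromosome at 65% background GC with
planted low-GC islands (written at their exact requested composition, so a
"42% GC island" is exactly that) and verbatim motif instances.
`makePhageGenome()` builds a linear genome starting TGT and ending ACA,
carrying the enzyme recognition sequence exactly at the configured cut
positions (spurious occurrences are mutated away), so the default digest
releases 6170, 30854 and 181 bp fragments.

`SiteModel` drives site selection: base weight 1, ×0.005 where windowed GC
(500 bp) is below 0.50, ×300 within 120 bp of a motif edge (the simulation
scenarios in the test suite use a 5 bp window so that events concentrate
into sharp peaks), immunity leak 0.004, duplication offset 5 bp applied to
the recorded junction of host-target reverse events. Self-insertions are
recorded at the sampled site unshifted, keeping the protected-gap geometry
exact; this is a simulator convention, stated here because the offset would
otherwise blur a 37 bp gap by 5 bp.

The phage self-insertion profile (`defaultDomainProfile()`) rescales a
nine-domain organisation (sizes 900, 2900, 6100, 5300, 7200, 4500, 3800,
5800, 700 bp; relative densities 100, 330, 800, 800, 1332, 620, 709, 1049,
100 events/kb) to any genome length, concentrates 5% of the mass at each of
the seven boundary crossing points (sharp spikes are what defines the
boundaries in the data; 5% keeps them above the 5×-median rule even beside
the densest domain), and zeroes an optional 37 bp protected gap.

`packageReads()` emits reads along simulated virion molecules: left flanks
of 31–36 bp, right flanks drawn from the 170–2500 bp size-selection range
and truncated by the read length, enriched-right reads starting exactly at
the cut preceding the 181 bp right end, and (in whole-virion mode)
junction reads at both molecule ends plus optional internal reads, so
chromosome ends are overrepresented as in real virion libraries.
Self-insertion events draw their flanks from the phage genome itself, which
is how such events are discovered downstream: their "host" fragments fail
to place on the host and place on the phage instead.

Not modelled: sequencing errors (off by default; mapping thresholds are
exercised with planted substitutions instead), PCR duplicates, GC
amplification bias, quality-score realism. Passing tests therefore
demonstrate the correctness of the algorithms under clean, structurally
realistic data — not robustness to platform noise.

## Problem sizes and numerical choices

The test suite runs one seeded end-to-end simulation with 1e5 events on a
100 kb host (14 planted motif sites; 1530 bp/42%, 13 kb/46% and — as a
negative control — 1500 bp/52% islands) against a 10 kb phage, chosen so the
full read→junction→placement→analysis chain completes in seconds while
leaving every rate (events per position, per window, per bin) within a
factor of a few of the full-scale experiment after threshold auto-scaling.
Domain/loop/gap recovery uses a dedicated 50,000-event self-insertion
sample, the scale at which boundary detection and a 37 bp gap are
statistically identifiable (at 0.4% of 1e5 events — about 400
self-insertions — a 200-bin profile cannot support nine domains, and zero
runs of 30 bp arise by chance; the larger sample matches the data regime
the domain analysis addresses, roughly 54,000 self-insertions out of 13.4
million events).

Other numerical choices: fractional placement limits are floored per
fragment; ties between equally good placements make a fragment ambiguous
rather than arbitrarily assigned; reads matching both phage ends go to the
longer overlap, ties discarded and counted; the running median in domain
segmentation is floored at one event so empty stretches do not make every
bin a "peak"; hotspot peak pairs record the two highest positions of a
merged cluster.

## Known limitations

* The consensus builder assumes a gapless conserved block; elements that
  differ by indels from the consensus are found only via the mismatch scan
  and may be missed at tight tolerance.
* The placer is not a general-purpose mapper: no paired-end awareness, no
  base-quality weighting, and seeds are exact — more than one substitution
  per seed region defeats it by design.
* Coincidence expectations assume uniform placement; they are a null model,
  not a fit.
* The loop model is a combinatorial pairing summary; no physical
  supercoiling is simulated.
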