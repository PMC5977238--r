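# SaltoMap

Mapping and analysis of transposable-phage (saltovirus) integration sites
from virion sequencing reads.

## The scientific problem

Transposable phages — phage Mu and the Mu-like D3112 group of *Pseudomonas
aeruginosa* — multiply their genome by replicative transposition into many
sites of the host chromosome. Virion DNA is packaged together with the host
DNA flanking each integrated copy: a short left flank (31–36 bp) and a
longer right flank shaped by headful packaging and, in enrichment designs,
by restriction digestion and size selection. Every sequencing read spanning
a phage–host junction therefore locates one transposition event at base-pair
resolution.

SaltoMap is for researchers who have (or simulate) such virion read sets and
want the full integration-site landscape: junction extraction with the
strict valid-read filter, placement of the trimmed host fragments on a
reference genome, per-position event tallies, coincidence statistics against
a random-placement null, insertion hotspots with their adjacent degenerate
consensus element (a REP/BIME-like palindromic repeat), low-GC coldspots,
and — from the rare self-insertions that escape target immunity — the
domain and loop organisation of the phage chromosome itself.

## The model at the core

If `T` transposition events fall uniformly on a genome of `N` positions and
`R = T/N < 0.1`, the expected number of positions carrying `i` coincident
events follows

    E2      = T * R / 2
    E(i+1)  = ln(1 / (1 - R)) * E(i) / (i + 1)

Observed spectra far above these expectations identify hotspots; windows of
less than 10 events/kb against a 1300–1800 events/kb genome-wide average
identify coldspots, which track low (<50%) GC content. Hotspot calling uses
a per-position threshold (3000 events in a 13.4-million-event experiment,
auto-scaled to the observed depth), pairing forward/reverse twin peaks
created by the ~5 bp target-site duplication. Self-insertion profiles are
binned at 50 bp, segmented into density domains at sharp boundary peaks,
and paired outermost-inward into supercoiled loops around a central apex
domain with a protected (gyrase-site-like) gap near the genome middle.

## Worked example

The closed-form coincidence expectations for 25,000 events on a 6.3 Mb
genome:

```r
library(SaltoMap)
expectedCounts(expectedSpectrum(25000, 6.3e6))
#>            2            3            4            5
#> 4.960317e+01 6.574319e-02 6.534725e-05 5.196664e-08
```

About 50 positions are expected to collect two coincident integrations and
essentially none three — so even a handful of positions with 3–5 events is
a strong hotspot signal.

A complete simulated experiment (100 kb host with 14 planted hotspot sites
and three GC islands, 10 kb phage, 20,000 events, right-end-enriched
reads), run end to end:

```r
res <- runPipeline(defaultRunConfig(), outDir = "salto_out", seed = 5)
#> [simulate] 20000 events, 20000 reads (0 events dropped)
#> [junctions] 20000 valid reads (rejected: too_short=0, prefix_mismatch=0, host_too_short=0)
#> [map] host: unique=19926, ambiguous=5, unmapped=69; phage self-insertions: 69 unique
#> [coincidence] R = T/N >= 0.1: the closed-form approximation is not valid there
#> [hotspots] 14 hotspots above scaled threshold 4.5
#> [hotspots] consensus YGGCGGATAACCGCRAGCGGTTATTCGCCCTACGG; 14 genome hits; event share 0.698
#> [coldspots] 2 coldspot region(s)
#> [phagedomain] 9 domains, 4 loops, 1 protected gap(s)
```

Reading the log: all 20,000 reads pass the valid-read filter (error-free
synthetic data); 19,926 host fragments place uniquely while the 69 that
fail on the host are the self-insertions, which place on the phage genome
instead. All 14 planted hotspot sites are recovered at the depth-scaled
threshold (3000 × 20,000/13.4M ≈ 4.5 events/position), the 35 bp degenerate
consensus is rebuilt from the hotspot neighbourhoods and found at exactly
the 14 planted loci, both low-GC islands are called as coldspots (the
52%-GC control island is not), and the self-insertion profile yields nine
domains, four loops and the planted 37 bp protected gap. The motif event
share (0.698) is high at toy scale because 14 boosted sites occupy a far
larger fraction of a 100 kb genome than of a 6.5 Mb one. Everything is
written under `salto_out/` (FASTA/FASTQ/TSV/bedGraph) with an md5 manifest;
re-running with the same seed is byte-identical.

The same stages are scriptable from a shell:

```sh
Rscript scripts/run_pipeline.R all --out salto_out --seed 5
Rscript scripts/run_pipeline.R phagedomain --sites salto_out/phage_sites.tsv \
    --phage salto_out/phage.fasta --out salto_domains
```

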