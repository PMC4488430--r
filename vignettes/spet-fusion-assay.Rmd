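---
title: "The SPET fusion assay in silico: probe design, library simulation, and split-read calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SPET fusion assay in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay and its computational core

Single primer enrichment technology (SPET) targets RNAs for sequencing with
a single capture probe per site: double-stranded cDNA is adapter-ligated, a
probe hybridizes to one strand and is extended by a polymerase toward the
adapter, and only extension products are amplified and sequenced. The key
consequence for gene-fusion work is that everything *downstream* of the
probe's 3' end is recovered, whether or not it was targeted. A fusion
transcript joining gene A to gene B is therefore detectable with probes
against only one partner.

`spetseq` reimplements the three computational pieces of this assay so the
single-partner property can be demonstrated and stress-tested entirely on
synthetic data:

1. **Panel design** (`design_panel()`): for every designable exon, one probe
   per strand of the ds-cDNA with its 3' end at an exon edge, pointing
   outward, so extension crosses the adjacent exon-exon (or fusion)
   junction; exons longer than the tile interval get additional probes at
   fixed anchor spacing on both strands.
2. **Assay simulation** (`simulate_fragments()`, `capture_and_extend()`,
   `emit_fastq()`): fragmentation, adapter ligation, hybridization,
   extension and paired-end sequencing, with a ground-truth record per read
   pair.
3. **Fusion calling** (`align_reads()`, `call_fusions()`): transcriptome
   k-mer alignment with chimeric (split) reads, junction-contig
   re-evaluation, and on-target enrichment metrics.

## Panel design rules and their parameters

Working in transcript coordinates, an exon occupying `[ts, te)` receives:

* an **antisense-strand** boundary probe with 3'-end anchor at `te - 1`
  (extension runs into the downstream exon), and
* a **sense-strand** boundary probe anchored at `ts` (extension runs into
  the upstream exon);
* if the exon is longer than `tile_interval`, **tile probes** at anchors
  `ts + k * tile_interval` on *both* strands, skipping anchors whose
  footprint would leave the exon or that duplicate a boundary probe.

Parameters (`panel_design_params()`):

| parameter | default | rationale |
|---|---|---|
| `tile_interval` | 300 nt | the assay's stated tiling density for long exons |
| `min_probes_per_exon` | 2 | one outward probe per strand per exon |
| `probe_length` | 40 nt | typical capture-probe footprint; configurable because the assay's own probe length is proprietary |
| `tail_sequence` | 20-mer constant | a universal priming site; only its existence matters here, not its sequence |
| `min_exon_length_for_probe` | `probe_length` | shorter exons cannot carry a full footprint; they are reported, not fatal |

Design choices that were genuinely open: the tiling anchors are measured
from the exon's transcript-5' end and placed on both strands (the assay
description fixes the 300-base spacing but neither the anchor origin nor
the strand policy); probes are deduplicated on their full sequence (tail +
footprint) so isoforms sharing an exon contribute one probe, matching the
"unique probes" accounting; and no mappability or thermodynamic filtering
is attempted (out of scope). Design is fully deterministic: output is
sorted by gene, genomic anchor and strand.

## What the simulator emulates — and what it does not

`generate_synthetic_genome()` builds a random genome with multi-exon gene
models at uniform base composition. Defaults (5 genes x 4 exons of 120-220
nt for the bundled demo; introns 100-500 nt) keep transcripts at a few
hundred nt so a desk-scale run exercises every code path. Fusion
transcripts are exact prefix+suffix concatenations of parent exons; without
CDS annotation the frame status is recorded as unknown.

The library model (`library_config()`):

* `n_molecules` abstracts RNA input mass; there is no ng-to-molecule
  conversion.
* Fragment counts per transcript are multinomial in abundance x length;
  fragment lengths are log-normal, truncated to the transcript. Fresh
  defaults are mean 400 sd 100 nt; `ffpe_mode` switches to mean 200 sd 80,
  emulating formalin-fragmented RNA (the real assay shows degraded input
  but publishes no length distribution — these are this package's choices).
* Hybridization is exact and full-length: a fragment is captured iff it
  fully contains a probe footprint on the matching strand; one eligible
  probe is chosen uniformly per fragment. There is no melting-temperature
  model, competition, or capture bias.
* R1 starts immediately 3' of the probe (the sequencing primer sits at the
  probe/insert junction), so the probe footprint itself is not sequenced;
  `probe_in_read = TRUE` flips this. R2 reads inward from the adapter end.
  Molecules shorter than the read length are 3'-padded with adapter.
* Errors are i.i.d. substitutions only; base qualities are constant. PCR
  duplicates are not simulated.

Consequences for interpreting green tests: passing suites show the *logic*
of the assay — probe placement, single-partner recovery, enrichment
accounting — is correct under clean hybridization and uniform capture.
They say nothing about real-data effects such as capture efficiency
differences, indels, multimapping repeat content, or FFPE deamination
artifacts, none of which the generator produces.

## The caller: numerical choices

Alignment is transcriptome-space (the assay targets cDNA), seed-chain-extend
over an exact k-mer index. Defaults (`caller_params()`): `k = 21`,
`min_overhang = 10`, `min_supporting_reads = 2`,
`max_mismatches_per_segment = 2`. These are this package's declared
thresholds (the original analysis used an external caller at default
settings whose internals are not restated); they are printed into the
`fusions.tsv` header of every run.

Decisions worth recording:

* **Unique placement.** Reads explained equally well by two genes are
  dropped, mirroring unique-alignment filtering; the drop is conservative
  by construction.
* **Junction homology.** When the bases flanking a breakpoint are shared
  between partners the junction can slide; calls report the leftmost
  (5'-most on the 5' partner) representation plus the homology length
  (`ambiguity`). The simulator's truth tables measure junction overhangs at
  the same leftmost position, so caller and truth agree exactly instead of
  disagreeing by the homology shift.
* **Supporting reads.** Split seeds only *nominate* junctions; support is
  then counted by re-evaluating every read without a full-length
  single-gene alignment against a junction contig (reference prefix +
  suffix around the breakpoint). A pair supports a junction when a mate
  matches the contig with at least `min_overhang` matching bases on both
  sides. Matching is anchored on the read's first or last 12-mer, so
  adapter padding at either end is tolerated; padding bases that happen to
  match the reference continuation count as aligned, which is also how the
  truth tables score them. This two-stage scheme is what makes support
  countable for reads whose second segment is shorter than `k` (down to
  `min_overhang`), and it is why zero-error simulations achieve exact
  truth/caller agreement.
* **On-target metric.** Forward reads only, counted as on-target when the
  alignment overlaps a probed-exon interval by at least one base — the same
  single-read, interval-overlap accounting as the original genome-space
  computation, transplanted to transcript space.
* **Degenerate inputs.** Zero reads is an error; all-unmapped input yields
  a mapped fraction of 0 and an undefined (NA) on-target fraction;
  fusion-free input yields an empty call table, not an error.

## Reproducibility and problem sizes

Every stage derives its RNG stream from one global seed
(`derive_seed()` adds a fixed per-stage offset), so a configuration
reproduces byte-identical FASTQ, call tables and checksums, and stages can
be rerun independently. The bundled demo (`demo_config()`) uses 5 genes,
one planted fusion and 20,000 molecules; the test suites run the same
pipeline at 800-4,000 molecules and 3-6 genes, sizes chosen so the full
suite exercises 20-seed replicate properties (exact truth agreement,
specificity) while remaining a desk-scale computation.

```{r demo}
library(spetseq)
res <- run_end_to_end(demo_config(seed = 1), "demo_run")
res$metrics
res$calls
```

## Known limitations

* The aligner is substitution-only (no indels or spliced genome alignment)
  and assumes uniform read length.
* Support counting under non-zero error rates is conservative: a read whose
  junction-spanning mate carries an error near the breakpoint may be
  missed.
* Read-through fusions between adjacent genes are not distinguished from
  trans events; there is no genomic-distance filter.
* The commercial panel itself (401 genes, 17,999 probes against RefSeq) is
  not reproduced: it depends on a proprietary designer and an unstated
  annotation version. The design rules here reproduce the *rules*, and the
  published probe arithmetic, not the catalogue.
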