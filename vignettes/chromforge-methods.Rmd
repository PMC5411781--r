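---
title: "chromforge: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromforge: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chromforge` upgrades fragmented assemblies to chromosome level with
comparative evidence, read-pair physical coverage and cytogenetic probe
maps, then analyses the breakpoints of the resulting karyotype. This
vignette explains the models each stage implements, the parameters that
matter, the choices made where the design was genuinely open, and what the
simulator-based tests do and do not establish about real data.

All coordinates in the package are 0-based half-open, identical to BED, so
tracks round-trip through files without shifts.

## Syntenic fragments and homeology maps

`detect_sfs()` chains pairwise alignment blocks into syntenic fragments
(SFs). Two consecutive blocks merge iff they share target sequence,
reference chromosome and orientation, reference coordinates advance with
the orientation, and **both** the target-side and reference-side gaps are
below the resolution. The dual-gap rule is deliberate: a one-sided rule
admits spurious merges across insertions in either genome. Blocks below
`min_block_bp` (default 5 kb — a free parameter; short blocks are dominated
by alignment noise) are dropped first, and blocks overlapping on the target
are resolved by keeping the longer one.

`build_homeology_map()` produces chromosome-scale homologous synteny blocks
(HSBs) at a stated resolution (150 kb by default, the same scale used for
SF detection). It chains at fine granularity first, then suppresses chains
shorter than the resolution and re-chains the survivors. The two-pass
scheme keeps HSB *boundaries* precise to the underlying alignment while
making events smaller than the resolution invisible; suppress-then-chain in
the opposite order would blur every boundary by up to the resolution, which
matters downstream because breakpoint intervals wider than 100 kb are
excluded from CNE analysis.

## PCF construction, verification, calibration

`build_pcfs()` is a deliberately simplified reimplementation of
reference-assisted adjacency scoring. Retention rule for an adjacency
between consecutive SFs of one scaffold: keep iff the spanning physical
coverage is at least `threshold_c` **or** reference and outgroup order both
support it. Everything else becomes a `SplitJoint` and the scaffold is cut.
Retained fragments are then ordered along each reference chromosome and
chained into PCFs when `w_ref·I_ref + w_out·I_out ≥ join_min` (defaults
1, 1 and 2: both genomes must agree). A weighted indicator score replaces
the original probabilistic adjacency model on purpose — the reusable
contribution is the verification loop and threshold calibration around it,
not the scoring internals. Because chaining follows a linear reference
ordering, circular support cannot arise and no cycle-breaking is needed.

**Physical coverage** at a position is the number of read-pair *fragments*
(outer-end to outer-end spans) strictly containing it. The coverage of a
joint is the **minimum** over up to 41 positions sampled across the gap
(`cov_mode = "min"`). A single gap-midpoint probe is available
(`cov_mode = "midpoint"`) but is not the default: when the gap between SF
hulls is wider than the library insert — which happens routinely, because
the blocks nearest a junction are short and fall below `min_block_bp` — the
midpoint sits outside the zero-coverage shadow of a chimeric junction and
reads span it freely, so a genuine mis-join is retained. The minimum over
the gap restores the intended signature: a chimeric junction anywhere in
the gap drives it to zero, while genuine joints keep full coverage
throughout.

`find_split_joints()` narrows each gap to the interval between the
innermost fine blocks attributable to the two flanking SFs (same reference
chromosome and orientation as the flank) and marks joints testable when the
narrowed gap is under 6 kb — the practical limit for PCR amplification
across the joint.

`calibrate_threshold()` turns verification outcomes into a genome-wide
coverage threshold: the smallest c maximizing
`A(c) = #(confirmed with cov ≥ c) + #(refuted with cov < c)`. Ties break
toward the smallest c (retain more species-specific structure); with only
confirmed joints the minimum confirmed coverage is returned, with only
refuted joints one above their maximum. The agreement objective is this
package's formalization of choosing the threshold "most consistent" with
verification results; it is brute-force checkable and the test suite checks
it against exhaustive scans on 1,300 random verification sets.

`refine_pcfs()` applies the outcomes: confirmed joints are welded
permanently (merging PCFs; the weld requires the flanking fragments to be
terminal members, the only configuration construction produces),
`alternative_confirmed` joints are rejoined in the swapped order, refuted
joints stay split (or split a PCF if the adjacency had been retained), and
PCFs conflicting with the cytogenetic map are split at their
lowest-coverage internal junction — cytogenetic evidence is treated as
terminal and overrides a confirmed weld.

## Probe panels

`filter_concordant()` keeps placements whose estimated insert length lies
within the library mean ± 3 SD with end sequences on opposite strands.
`classify_universal()` implements the cross-species hybridization rule: at
least 93 % of the probe alignable across genomes, and either one conserved
element (CE) of ≥ 300 bp, or — lacking a long CE — total repetitive content
strictly under 1290 bp together with at least one CE of ≥ 3 bp. The
alignability condition is applied to **both** branches (reading the rule as
replacing only the CE clause is possible; the threshold is a plain argument
if evidence favors the other reading). The "CE ≥ 3 bp" condition is
implemented as a presence flag, not a density. `select_spaced_panel()` is a
greedy sweep (first candidate per chromosome always accepted, then the next
candidate at least the target spacing away); the greedy rule guarantees all
panel gaps reach the spacing and every rejected candidate is within the
spacing of an accepted one.

## Anchoring

`assign_pcfs()` assigns a PCF to the chromosome holding a strict majority
of its mapped probes; a PCF with probes on two or more chromosomes is also
reported as an interchromosomal conflict (candidate mis-join). Ordering
uses the mean ordinal map position of each PCF's probes — FISH gives
relative order far more reliably than distance, so fractional map positions
are used only for rendering, never for ordering. Ties in mean position
break by PCF length (longer first, logged via the returned table).
Orientation is the sign of the Kendall-style concordant-minus-discordant
pair count between within-PCF probe coordinates and map order: `+` if
concordant, `-` if reversed, `?` for single-probe or exactly tied PCFs.
The rank-correlation sign was chosen over endpoint comparison because it
is robust to one displaced probe. Interleaved probe ranges of two PCFs
(map reads A, B, A) are a genuine monotonicity violation and raise an error
naming the probes; `on_interleave = "warn"` downgrades this for noisy maps.

## EBR detection and classification

The reference genome is treated as the ancestral proxy (a configuration
flag away from supplying a reconstructed ancestor instead). `detect_ebrs()`
emits one EBR per adjacent-HSB gap on a reference chromosome where target
continuity breaks (different target chromosome, orientation flip, or a
target-side order jump of at least the resolution). Intervals shorter than
1 kb are extended by ±1 kb; intervals longer than 100 kb are flagged and
excluded from density analyses. Extension is applied after detection and
before the size filter (the order is not dictated by the workflow; applying
the filter first could only admit intervals between 98 and 100 kb, which
the extension then pushes over the limit — the chosen order is the
conservative one).

`classify_ebrs()` types reference-side records by the flanking HSBs' target
chromosomes (same = intrachromosomal, different = fission) and emits one
fusion record per target-side junction of blocks from different reference
chromosomes, with reference flanks 10 kb deep at the joined block edges
(the flank depth when a junction abuts a reference chromosome end is a free
parameter). A record is well defined iff both flanking blocks are oriented.
One biological event can legitimately emit one fusion and one fission
record; event-group ids keep counting unambiguous, and the two breakpoints
flanking an inverted block run share a group so an inversion counts once.
`assign_lineage()` marks an EBR lineage-specific when no other species'
map is disrupted at that reference interval (± slack), and otherwise labels
it with the smallest clade of the supplied tree containing all disrupted
species.

## Window statistics

`window_scan()` tiles the reference with nonoverlapping 1-kb windows
(terminal short windows dropped), counts covered, CNE and TE bases, and
labels each window: EBR classes win over msHSB on overlap (EBRs are the
analysis target), interchromosomal labels win over intrachromosomal, and
msHSB labeling is restricted to blocks over 1.5 Mb. Windows with at most
half their bases covered are unusable and excluded from every statistic,
including the msHSB mean density that seeds the distance analysis.

`zero_window_distances()` measures, for every usable zero-CNE window, the
distance in windows to the nearest usable window at or above the msHSB mean
density — bidirectional minimum within the chromosome ("nearest" with no
stated direction), with zero-windows on chromosomes lacking any qualifying
window excluded and tallied rather than given infinite distances. Distances
are per-window, not per-region.

`compare_groups()` runs Kruskal–Wallis, then all pairwise two-sided
Mann–Whitney tests (gated on the omnibus p). For small groups the pairwise
p is an exact permutation probability by complete enumeration: U counts
pairs with x > y plus ½ per tie, and the two-sided p is the permutation
mass at least as far from n₁n₂/2 as observed. This definition handles ties
exactly (where the classical exact distribution is unavailable) and
coincides with `wilcox.test(exact = TRUE)` on tie-free data. Raw and
Benjamini–Hochberg-adjusted p-values are both reported; the large-sample
normal approximation takes over beyond the enumeration limit.

`te_enrichment()` compares per-10-kb-window TE density between
EBR-containing and EBR-free windows for each family whose elements average
over 100 bp, using Welch's t-test (the unequal-variance form — group sizes
and variances differ by construction) with BH adjustment across
class × family tests.

## The simulator: what it emulates, what it does not

The simulator is coordinate-level interval bookkeeping: sequence content is
never consulted by downstream mathematics, so none is generated (FASTA
emission would add nothing the pipeline reads). An ancestor genome
(geometrically decreasing chromosome lengths; one central msHSB covering
~30 % of each chromosome) is rearranged by an explicit, replayable plan —
inversions, single-cut fissions, end-to-end fusions (mirroring the observed
predominance of fusions and absence of reciprocal translocations in highly
rearranged avian karyotypes; translocations are implemented but off by
default) — with every breakpoint recorded in a truth set. The segment
bookkeeping is verified against a per-base label-replay oracle in the test
suite.

Plan generation keeps breakpoints clear of chromosome margins and msHSBs
(breakpoints deplete in conserved synteny) with a minimum separation, and
never fuses two chromosomes sharing an ancestor root — rejoining pieces of
one reference chromosome is not an interchromosomal event relative to that
reference, so such a fusion would be unrecoverable in principle and only
blur event counting.

Scaffold shredding cuts descendant chromosomes into roughly exponential
pieces (default mean 500 kb, minimum 50 kb; the real scaffold-length
distribution of short-read assemblies is not modeled beyond "N50 on the Mb
scale"). A scaffold is, with probability `chimera_rate`, the concatenation
of two pieces — never pieces that are genuinely adjacent in the descendant,
and never pieces ancestrally within 250 kb of each other, because a join
reconstituting a near-ancestral adjacency is legitimately supported by
comparative evidence and is not a detectable mis-join. Read pairs emulate a
3 kb ± 300 bp long-insert library at ~15× physical coverage placed
uniformly per scaffold; pairs spanning a chimeric joint are removed
entirely with probability `p_chim_zero = 0.9` (the joined molecule never
existed) or thinned to half rate — the coverage signature of chimeras is a
modeling choice, since only "insufficient evidence" is observable in
practice. Mean physical coverage is validated against the Lander–Waterman
expectation `n_pairs × insert / genome`.

Alignment blocks are derived exactly from the truth composition
(scaffold → descendant → ancestor), optionally split into ~60 kb sub-blocks
with 200 bp unaligned gaps, and eroded by up to `edge_erosion_bp`
(pipeline default 15 kb) at edges abutting planted breakpoints or
chromosome ends — breakpoint neighborhoods are repeat-rich and align
poorly, and this erosion is what gives detected EBR intervals their
realistic widths of tens of kb. No alignment noise beyond splitting and
erosion is modeled (no spurious mappings, no paralogy).

CNE tracks use an alternating renewal process (geometric element lengths,
mean 80 bp; exponential gaps scaled to the target density): 0.11 covered
fraction inside msHSBs, 0.02 elsewhere, matching the densities the window
scan should recover. Around each planted breakpoint a CNE desert is carved:
half-widths 19 kb (intrachromosomal), 23 kb (fusion flanks) and 35 kb
(fission), echoing the reported ordering of median zero-window distances.
A single unnamed `desert_halfwidth_bp` applies to fissions only. The
recovered medians exceed the planted half-widths by a travel offset
(distance from the desert edge to the first msHSB-level window through
0.02-density background); the medians' *ordering*, not their absolute
values, is the property the generator plants and the acceptance suite
verifies. TE tracks carry three families with one (LTR-ERV1) planted at
2× density within 20 kb of intrachromosomal breakpoints, mirroring the
expected enrichment pattern; fusion and fission flanks receive no
enrichment.

Probes are planted one per spacing window (at midpoints, so a 10 Mb
chromosome at 1 Mb spacing receives exactly 10), carry features drawn from
a configurable sampler, and feed a cytogenetic map ordered by true position
plus Gaussian noise (default 0: FISH order errors are not the phenomenon
under test). What passing tests show, therefore, is that the *algorithms*
recover planted structure exactly under clean evidence and calibrated
thresholds; they do not show robustness to alignment artifacts, repeat-
driven mismapping, cell-line rearrangements or probe cross-hybridization,
all of which real applications must absorb.

## Pipeline, problem sizes, determinism

`run_pipeline()` executes simulate → sf → pcf → verify → anchor → ebr →
stats as file-coupled stages (each stage reads only files in the output
directory, so every stage is re-runnable alone and the `exec/chromforge`
CLI maps 1:1 onto them). The default demo profile is a 20 Mb, 5-chromosome
genome with 10 inversions, 2 fissions and 3 fusions — sized so a full run,
the test suite and the acceptance script all complete in well under their
time budgets on one CPU; the acceptance script adds a 55 Mb, 12-chromosome
simulation with 32/18/12 events so that every window class holds at least
200 zero-CNE windows for the distance statistics. All randomness flows
through explicit seeds (one per stage, derived from the run seed); repeated
runs are byte-identical apart from wall-time fields.

The pipeline's EBR stage measures the *reconstructed* chromosomes. A
species-specific inversion split across scaffolds can be silently undone by
reference-guided chaining — exactly the bias the verification loop exists
to counter — so reconstructed event counts are expected to undershoot the
plan whenever coverage evidence cannot rescue a split rearrangement; the
rearrangement-recovery analyses therefore run the EBR module on the
simulated karyotype itself.

## Known limitations

- The adjacency score is an indicator sum, not a likelihood; `w_read`
  participates only within scaffolds (no cross-scaffold read pairs are
  tracked), so inter-scaffold chaining requires both comparative signals.
- Welding in `refine_pcfs()` requires the flanking fragments to be terminal
  members of their PCFs; other configurations (not produced by
  construction) are left split with a warning.
- `assign_lineage()` uses interval overlap with slack, not breakpoint-reuse
  modeling; shared-EBR labels are only as good as the supplied topology.
- The simulator plants at most two fragments per chimeric scaffold and does
  not model sequencing error, base-level mutation, repeat families at
  sequence level, or diploidy.
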