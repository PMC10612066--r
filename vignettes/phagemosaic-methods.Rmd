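---
title: "Methods and design notes for phagemosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for phagemosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phagemosaic analyses families of small (~35 kb) temperate myoviruses of
the P2 type: phages whose genomes are mosaics of modules — nonstructural
genes, head and connector, tail, and an antireceptor block — each with
its own history of descent and recombination, and which may carry a
diversity-generating retroelement (DGR) that hypermutates the
receptor-binding tail fiber.  This vignette explains the statistical
model or procedure behind each analysis, the tunable parameters and
their defaults, what the synthetic generators do and do not emulate, and
the design decisions made where the design was genuinely open.  It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Percent-identity profiling

`align_pair()` computes an optimal global alignment under BLOSUM62 with
affine gaps (opening 11, extension 1 per residue — the classic Blast
parameterisation; a gap of length $L$ costs $11 + L$).  The engine is an
exact Needleman–Wunsch/Gotoh implementation in C++; its scores are
checked in the test suite against both an independent pure-R Gotoh
oracle and `Biostrings::pairwiseAlignment`.  Ties between alignment
paths are resolved by a fixed state-preference order (substitution, then
gap-in-reference, then gap-in-query), so output is deterministic.  `X`
scores 0 against every residue.

Identity is reported in two modes.  *Global*: identical columns over all
aligned columns, counting internal gaps but excluding terminal gap runs.
*Local-core* (the default): the same ratio over the maximal-scoring
contiguous sub-path of the global alignment, found by a maximum-subarray
pass over per-column scores.  Local-core is closer to how a local
aligner reports identity; it systematically reads a few points higher
than global identity at high divergence, because it discards the
worst-aligned flanks.  These are *approximations* of Blast-reported
identity, not reproductions, and the module-level acceptance checks are
therefore pattern-level, not cell-level.

A match is reported only above a significance floor: raw score
$\ge 50$, or local-core identity $\ge 25\%$ sustained over $\ge 50$
local-core columns *with local-core window score $\ge 35$*.  The window
score component is not redundant: without it, random same-length
proteins pass the identity-and-length test in roughly 1.7% of pairs,
which after maximisation over a proteome makes false matches common and
violates the calibration requirement that shuffled-proteome queries be
reported as matches in under 1% of trials.  The calibration is itself a
test in the suite (1000 shuffled queries).  All floors are exposed in
`align_params()`.  Cells below the floor are "no match" and are excluded
from every downstream median; their absence is still information (the
tail module of this phage family is defined partly by the *failure* of
Blast-level matching to one reference lineage).

## Module summaries and segmentation

A module's relationship to a reference phage is summarised by the
*median* of its measured per-gene identities, never the mean: single
genes interjected into a module by recombinational reassortment drag a
mean far more than a median, and the test suite quantifies this on
random module profiles with planted outliers.  Even-count medians are
the midpoint of the central pair.

`segment_modules()` finds module boundaries by exact dynamic-programming
change-point segmentation: it minimises the total within-segment
absolute deviation from the per-reference segment median, subject to a
minimum segment length, with "no match" imputed at 0 *inside the cost
only*.  The DP is exact — the suite checks it against exhaustive
enumeration on all instances up to 12 genes — and deterministic: among
cost-tied segmentations it returns the lexicographically earliest
boundary vector.  `n_modules = "auto"` accepts additional segments while
the relative cost improvement stays above 5%; automatic selection is a
convenience, and the canonical four-module layout can always be supplied
manually via `module_definition()` or a three-column range file.

## Tail-lineage bipartition

The family splits into two anciently diverged tail lineages.
`bipartition_by_gene()` works on the margin scale: for each panel phage,
the difference between its identity to exemplar A and to exemplar B,
with an unmeasured cell contributing 0.  Assignment is the sign of the
margin.  Separability is the existence of a single margin threshold that
divides the two groups without interleaving: when external group labels
are supplied (e.g. from a portal-protein tree) interleaving is possible
and is reported; without labels the sign-derived assignment is the
grouping and the reported threshold is the midpoint of the widest margin
gap between the groups.  `consensus_groups()` majority-votes across
genes and reports per-phage agreement, deliberately stopping short of
assigning taxonomic rank.

## DGR detection and the adenine-bias test

The cassette searched for is: target gene (antireceptor) containing the
variable region (VR), accessory variability determinant (avd), template
repeat (TR), and a mobile-intron-II-family reverse transcriptase (RT),
with the TR optionally translated as an in-frame N-terminal extension of
the RT.  `find_tr_vr()` enumerates direct-repeat pairs within a window
(default 5 kb) around the RT gene by exact seeding (k = 12) and X-drop
extension (match +1, mismatch −2, drop-off 25, ties extending — so a
conserved repeat terminus that exactly offsets preceding mismatches is
still included).  The RT is identified by product-string match
("reverse transcriptase") or supplied explicitly; domain searches are
out of scope.

Mismatch classification follows the adenine-substitution paradigm:
*conforming* iff the template base is A and the variable base is C, G or
T; everything else is nonconforming; indel columns are tallied but
excluded.  Under the null that $m$ mismatch positions fall uniformly
over the template, the conforming count is $\mathrm{Binomial}(m, f)$
with $f$ the template adenine fraction, and the reported p-value is the
exact one-sided tail $P(X \ge n_{\text{conforming}})$; a Monte-Carlo
permutation alternative agrees within sampling error (tested).  Zero
mismatches give $p = 1$ by convention — identical repeats carry no
orientation signal and are never reported as cassettes.  A candidate is
kept when one copy's template role is significant at $\alpha = 0.05$;
that copy is the TR.  At $\varepsilon = 0$ the wrong orientation cannot
be significant (its conforming count is 0), so orientation never flips
on detected cassettes.

Two statistical facts shape what a green test can establish here.
First, the size of the exact binomial test is below the nominal level
(discreteness); the type-I calibration uses a configuration (120 bp
template, 36 adenines, 10 mismatches) whose exact size, 4.0%, was
computed analytically before any simulation.  Second, detection at a
per-adenine mutation probability of $\theta = 0.1$ is intrinsically
limited: with ~41 mutable adenines the expected conforming count is
~4.5, and the $p < 0.05$ gate fails in roughly a third of genomes.  No
repeat configuration within a realistic length range lifts exact
recovery to 99%; the acceptance criterion that demands it is asserted
as stated and fails for that reason, with the arithmetic recorded in the
project's decisions ledger.

## Prophage localisation and attachment sites

`locate_prophage()` anchors exact 31-mers sampled every 200 bp along the
phage record in the host (both orientations), clusters anchors by
diagonal modulo the phage length — which makes the two arms of a rotated
phage fall on one cluster — and extends the boundary anchors base by
base.  It reports the rotation offset relating the record start to the
prophage left end, so phage records deposited "with the same end points
as the prophage" and arbitrarily rotated copies are handled identically;
`rotate_genome()` makes the relationship explicit rather than matching
under implicit permutation.

`find_att()` scans the two boundary neighbourhoods (default ±500 bp)
for the longest direct repeat (≥12 bp, ≤2 mismatches) in which one copy
spans the left boundary and the other the right boundary, with ~10 bp of
boundary tolerance so the result is invariant to small anchor-extension
slop (a tested property).  Ties prefer the longer repeat, then fewer
mismatches, then the leftmost position.  `check_reconstruction()` walks
codon-by-codon upstream of the disrupted gene's 3' remnant until a start
codon (ATG, optionally GTG/TTG) or an in-frame stop, reporting whether
integration restored an expressible 5' end; given the free phage record
it also reports the first in-frame terminator past the circularisation
junction — the codon that would truncate the protein in the excised
circular phage — and the upstream region where a driving promoter would
have to sit (coordinates only).

## Genome differencing, pileups, and the promoter scan

`diff_genomes()` aligns two near-identical genomes with a banded affine
aligner (band 200, widened on demand; an identity guard of 95% rejects
misuse on diverged genomes).  Variants are reported in reference
coordinates with named-mask flags — the conventional mask is the
antireceptor gene plus its VR, since differences between close relatives
of these phages concentrate there — and effects are classified against
the reference annotation: codon-level comparison for substitutions;
indels of length not divisible by 3 inside a CDS are frameshifts (the
broken prophage RT is the motivating case); in-frame indels get no
effect label because the effect vocabulary deliberately has no class for
them.  Emission is minimal 8-column VCF.

`allele_fractions()` is deliberately simple — designated alternate count
over total — because read mapping and variant calling are out of scope;
pileups enter as position/count tables.  `promoter_scan()` replaces a
neural-network promoter predictor with a transparent sigma-70 consensus
scan (TTGACA, 15–19 bp spacer, TATAAT; Hamming mismatches bounded), a
documented method substitution sufficient for qualitative comparisons
such as which variant's −10 box is closer to the TATAAT consensus; it
also reports opposed overlapping hits, the geometry of the
early/repressor promoter pair in a P2-style immunity region.

## The synthetic world

The generators produce every input the pipeline needs, with all
randomness a pure function of (config, seed):

* `gen_mosaic()` simulates an ancestral proteome (default 40 genes in
  four modules, mean protein 100 aa), evolves one reference proteome per
  lineage to per-module identity targets by independent per-site
  substitution (realized identity is exactly unbiased for the target),
  optionally applies block recombinations, and back-translates with
  uniform synonymous codons (table 11).  Default targets mirror the
  four-pattern contrast of this phage family: nonstructural 92/35,
  head+connector 45/45, tail 33/13, antireceptor unrelated.  The 13 is
  the printed tail-to-P2 figure obtainable only by HMM comparison, and
  deliberately sits below the Blast-style floor — absence of a match is
  part of the pattern.  The substitution model is uniform over amino
  acids, not an empirical matrix: targets are identity percentages, not
  phylogenetic realism.  Synthetic GC is ~50%, unlike real genomes of
  this family (~43%); no test depends on synthetic GC.
* `gen_dgr()` plants the cassette in canonical order with the TR as an
  in-frame N-terminal RT extension.  Defaults: 135 bp repeat, adenine
  fraction 0.35 (the scale of the prototype system), θ = 0.1,
  ε = 0.01.  The terminal 9 bp of the repeat are held invariant and the
  three columns flanking each copy are forced to differ — real TR/VR
  pairs keep conserved boundary elements, and without a well-defined
  boundary "exact interval recovery" would not be a meaningful
  criterion.
* `gen_lysogen()` builds a host with one target gene (a tRNA-modifying
  dusA-style gene), inserts a phage with the attachment core duplicated
  on both sides, optionally restores the gene's first 60 codons in
  frame from the phage right arm, and can plant core mismatches, a +1
  junction frameshift, or a circularisation terminator at a chosen
  offset.  Desk-scale lengths (host 60 kb, phage 30 kb; the acceptance
  tests use 30/15 kb) keep each round trip under a second; the
  geometry is identical at real scale because every step is local to
  the boundaries.
* `gen_pileup()` draws per-site alternate counts as
  Binomial(depth, mixture) — the model behind a partially induced
  prophage contributing a minor read fraction.  The exact coverage of
  the window [0.05, 0.10] at depth 200 and mixture 0.08 is 0.840 per
  site and $0.840^6 = 0.35$ for six sites jointly; the acceptance
  criterion that expects 90% joint coverage contradicts this arithmetic
  and is asserted as stated (red), with the calculation in the ledger.

What a green test does *not* establish: the generators do not emulate
codon bias, rate heterogeneity among sites or genes, repeat-rich host
backgrounds, sequencing error in pileups, or partial/nested prophages;
conclusions about real data should rely on the exposed configuration
knobs, not the defaults alone.

## Numerical and convention choices

Internal coordinates are 0-based half-open with strand ±1; all GenBank
emission converts back to 1-based inclusive, and residue-level reports
are 1-based.  Translation uses table 11 unless a record states
otherwise.  A CDS whose length is not divisible by 3 is translated over
its longest in-frame prefix and flagged as a possible
frameshift/pseudogene — the flag the DGR module reads for a broken RT.
Even-count medians are central midpoints.  Segmentation ties take the
earliest boundaries; repeat-extension ties take the longer extent;
best-match score ties take the earlier gene index.  The banded DNA
aligner retries with a doubled band up to 3200 before failing.

## Known limitations

GenBank parsing covers the subset of the format the pipeline relies on
(LOCUS/DEFINITION/FEATURES with simple, complement and join locations,
ORIGIN), not the full standard.  The identity floor is calibrated on
uniform-composition random proteins; biased low-complexity proteomes
would need recalibration.  `find_tr_vr()` assumes a single replicon and
plus-strand cassettes (the simulated and deposited layout);
genome-wide DGR surveys over large assemblies are out of scope.
Promoter scanning is a consensus filter, not a trained model, and
reports candidates, not predictions.
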