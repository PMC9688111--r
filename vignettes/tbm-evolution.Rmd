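---
title: "Methods: comparative evolution of tankyrase-binding motifs"
author: "tbmevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative evolution of tankyrase-binding motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbmevo)
```

## The problem

Tankyrases (TNKS1/2) are poly-ADP-ribosyltransferases whose regulatory
reach in the cell is defined by the partners they bind.  Partner proteins
dock onto the tankyrase ankyrin-repeat clusters (ARCs) through a short
linear peptide, the tankyrase-binding motif (TBM).  The canonical grammar
is `Rxx[ACGP]xGxx`; two relaxed configurations, `Rx(4)Gxx` and
`Rx(5)Gxx`, are also bound in some partners.  Because TBMs sit in
disordered regions, they appear and disappear rapidly in evolution: the
hub protein is deeply conserved while its interaction motifs are not — the
classic linear-motif-binding-hub pattern.

`tbmevo` packages the computational side of this comparative question:
given ortholog sets of known human tankyrase partners, where do TBMs
occur, do they occupy the position homologous to the human motif, and how
does motif presence relate to the conservation and phylogeny of the
proteins involved?

## Motif grammar and scanning

The scanner (`scan_tbm`, `scan_all`) treats the three configurations as
fixed-length windows:

| name      | length | constraints                       |
|-----------|--------|-----------------------------------|
| canonical | 8      | R at 1, `[ACGP]` at 4, G at 6     |
| rx4       | 8      | R at 1, G at 6                    |
| rx5       | 9      | R at 1, G at 7                    |

The `Rx(n)Gxx` notation counts n wildcards between the arginine and the
glycine, which fixes the window lengths above; every canonical match is
by construction also an rx4 match, so a window is labeled with the most
specific configuration it satisfies (canonical over rx4 over rx5).  A
start position can legitimately produce both a length-8 and a length-9
hit.  The ambiguity code `X` never satisfies a constrained position —
a motif call should not rest on residues that were not confidently
sequenced — but is accepted at wildcard positions.  All overlapping
windows are reported; there is no greedy consumption.

```{r}
scan_tbm("RGCADGRD")  # TRF1-type site: canonical
scan_tbm("RPPVPGEE")  # Axin1-type site: position 4 = V, rx4 only
```

The curated table of human tankyrase partners shipped with the package
(`tbm_binders()`) lists one row per TBM site (26 sites across 22
partners, four partners carrying two sites each).  One site (USP25) is
printed as a 7-mer and flagged `truncated`: the canonical window needs 8
positions, so that site can only be scanned in a full-length sequence.
The second, non-canonical Axin1 motif is excluded throughout because its
binding rules are unclear.

## Alignment-anchored presence calls

Whether an ortholog "has" the motif is decided in alignment coordinates
(`classify_tbm`, `presence_matrix`).  The reference (human) row anchors a
residue-to-column map: the k-th ungapped reference column is residue k.
With C the column of the reference motif arginine:

* a hit whose arginine maps exactly to C is `canonical_aligned` or
  `relaxed_aligned`, by configuration;
* otherwise a hit within `nearby_window` columns of C is
  `nearby_unaligned`;
* otherwise `absent`; species without a row are `no_ortholog`.

The best verdict wins when several hits qualify.  The nearby rule stands
in for "possible TBM in a nearby, likely disordered region": no disorder
predictor is consulted, the window is plain column distance, and the
default of 30 columns is a declared convention of this package (reported
in the output metadata), not an empirical constant.  Setting the window
to 0 disables the rule, which is also the strictest and the only fully
deterministic setting — chance motifs in random background sequence can
always fall inside a generous window.

## Conservation profiling

`conservation_profile` summarizes each reference-anchored column by its
number of distinct non-gap residues and gap fraction.  Columns gapped in
the reference are excluded rather than re-assigned to flanking residues.
A residue is *strictly conserved* when its column carries a single
residue identity and no gaps (a uniform `X` column does not count).

The 1–9 grade is a deliberately simple, fully specified surrogate for
ConSurf-style normalized conservation grades: diversity counts are banded
into nine equal-width bins over `[1, max observed diversity]`, grade 9
for single-identity columns down to grade 1 for the most diverse band.
It is monotone in diversity and needs no tree; it is *not* a
phylogeny-aware rate estimate, does not correct for taxon sampling, and
two alignments' grades are not comparable when their diversity ranges
differ.  Strict-conservation projection onto structures is done by
`write_bfactor_pdb`, which rewrites only the B-factor column (bytes
61–66) of ATOM/HETATM records so the annotated file stays diffable
against the original.

Pairwise identity from an MSA (`msa_identity_matrix`) counts identical
non-gap matched columns over columns where at least one of the two rows
is non-gap; columns gapped in both rows say nothing about the pair and
are excluded.  The percent-identity conventions (here and in the
pairwise module) are named in every report because published identity
figures depend on them.

## Pairwise alignment

`global_align` and `local_align` are textbook Needleman–Wunsch and
Smith–Waterman with affine gaps (Gotoh three-state recursion).  Defaults
mirror the EMBOSS tools they stand in for: BLOSUM62 with gap open 10 /
extend 0.5 for global (Needle), open 14 / extend 4 for local (Matcher).
A gap of length k costs `open + k * extend`; end gaps are penalized;
`X` scores 0 against everything.  Traceback ties are broken
diagonal > up > left, so alignments are reproducible.  Tests verify the
scores against an independent cubic general-gap-cost dynamic program and
against `Biostrings::pairwiseAlignment`.

## Phylogenies

`distance_from_alignment` computes p-distances over pairwise-ungapped
columns, with the Poisson correction `-ln(1 - p)` by default and a cap at
`-ln(0.05)` for saturated pairs (p ≥ 0.95).  The JTT maximum-likelihood
distances used by full-scale phylogenetics packages are intentionally not
re-implemented: at the scales this package targets, the claim under test
is topology recovery, which the Poisson model supports; the model name is
part of the output metadata.

`neighbor_joining` is classical Saitou–Nei agglomeration with the
Q-criterion, a deterministic lowest-index tie-break, negative branch
lengths clamped to zero, and a closed-form three-point join at the end.
For additive matrices it reproduces the generating tree to numerical
precision.  `bootstrap_nj` resamples alignment columns with replacement
and attaches, to each internal edge of the full-data tree, the percentage
of replicate trees containing the same bipartition; consensus trees are
out of scope.  All resampling comes from a single generator seeded by the
caller, so a seed fully determines the Newick output.

## The simulator

`simulate_family` generates ortholog families with the statistical
structure the analyses assume, so every stage can be tested against known
truth with no downloads:

* a Yule species tree rescaled to a configurable depth (default 1
  expected substitution per site at the fastest-block rate), or a fixed
  user Newick;
* a root protein of ordered blocks — conserved domains and fast linkers.
  The default blueprint (three domains of 60/60/80 residues at rate 0.1,
  two 30-residue linkers at rate 1.0 with indel rate 0.05) miniaturizes a
  multi-domain protein at roughly 1/6 scale so that test suites run in
  seconds; rates were chosen once to give domains ~10–15% and linkers
  ~50–60% site divergence at default depth, the qualitative contrast the
  conservation module is meant to detect;
* uniform-exchange substitutions (a site hit by at least one Poisson
  event is redrawn uniformly — exact for this model, and it keeps the
  background motif-hit probability analytic:
  `(1/20)(4/20)(1/20)` per canonical window);
* indels only in linkers, geometric lengths, tracked by column identity
  so the emitted alignment is the true homology, never a re-alignment;
* planted TBMs: constrained positions written into the root and shielded
  from substitution; wildcard positions evolve freely (deliberately, to
  exercise the scanner's wildcard handling); indels never cut into a
  motif span; in taxa outside the designated subset the motif arginine is
  ablated to a random non-arginine residue at the tips, which makes
  absence calls at window 0 deterministic.

What the simulator does not emulate: realistic amino-acid frequencies or
exchangeabilities, rate variation within blocks, selection on motifs,
alignment error (the truth alignment is exact), and assembly artifacts of
transcriptome-derived sequences.  Tests passing on simulated families
therefore demonstrate pipeline correctness — coordinates, verdicts, tree
recovery — not robustness to real-data noise, and in particular not
robustness to MSA errors, which in real ortholog sets are absorbed by
manual curation.

`background_scan_rate` runs motif-free simulations and reports chance
hits per 100 residues by configuration with a t-interval across families;
it is the calibration for interpreting `absent`/`nearby_unaligned` calls.

## Numerical and design choices

* Residue and column numbering is 1-based throughout; the gap symbol is
  `-` internally, `.` accepted on read.
* Species tags resolve from a `species=` header key, else the id prefix
  before `|`; writers emit the key so tags survive round trips.
* Distance saturation cap, nearby window, grade banding and tie-breaks
  are all surfaced as arguments or documented constants — none is fitted
  to data.
* Problem sizes in the test suite (families of 6–8 taxa, ~260-column
  alignments, 100 bootstrap replicates, 1000-sequence scanner sweeps)
  were chosen as the smallest sizes at which each property is
  informative.
* Randomized entry points (`bootstrap_nj`, `simulate_family`, the CLI
  subcommands wrapping them) require an explicit seed; there is no
  wall-clock default.

## Limitations

The package deliberately stops short of several things its inputs might
suggest: it does not retrieve sequences, build MSAs (alignments are
inputs, or simulator truth), predict structures or disorder, estimate
maximum-likelihood trees, or model binding affinity beyond the
configuration class of a motif.  The conservation grade is a surrogate,
not a drop-in replacement for Bayesian rate estimation.  Identity
percentages depend on their stated conventions and should not be compared
across conventions.
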