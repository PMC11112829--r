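---
title: "Methods: prospecting and characterizing class III cellobiose dehydrogenases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prospecting and characterizing class III cellobiose dehydrogenases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdhprospect)
library(dplyr)
```

# Scope and model of the pipeline

Cellobiose dehydrogenase (CDH) is an extracellular fungal flavocytochrome:
an N-terminal cytochrome (Cyt) domain binding heme *b* through a Met/His
ligand pair, a flexible linker, and a catalytic FAD-dependent dehydrogenase
(DH) domain of the GMC superfamily. Class III CDHs are known almost
entirely from sequence data; prospecting them means triaging thousands of
database hits down to a handful of expressible candidates, and then
characterizing whatever gets expressed. This package implements that
workflow end to end:

1. **seqio** — FASTA input/output, merging of search results with
   deduplication by accession, and inclusive length filtering (150–1100
   residues for network building; 700–1000 for full-length candidates).
2. **ssn** — a sequence similarity network over all-vs-all local-alignment
   scores, analyzed across a ladder of decreasing score cut-offs.
3. **curation** — reference-anchored checks of the five functional
   criteria (signal peptide, Rossmann `GxGxxG`, catalytic His, N-terminal
   Cyt domain, heme ligands), redundancy reduction, sequence logos,
   domain splitting at the YDY anchor, sub-clade assignment from a tree
   and candidate selection.
4. **construct_design** — restriction-site domestication by synonymous
   codons, partitioning into 300–900 bp golden-gate synthesis modules with
   unique 4-nt fusion overhangs, and in-silico assembly validation.
5. **biochem** — activity, purification-table, absorption-coefficient,
   FAD-occupancy and UV-Vis feature calculators.
6. **synthetic_data** — generators for every input with planted ground
   truth, used by the test suite and the acceptance script.

# Similarity network scoring

Pairs are aligned locally (Smith–Waterman through Biostrings) under
BLOSUM62 with affine gaps (open 11, extend 1). The raw score $S$ is
converted to bits with Karlin–Altschul statistics,
$S' = (\lambda S - \ln K)/\ln 2$ using the standard gapped BLOSUM62
constants $\lambda = 0.267$, $K = 0.041$, and then to an expectation-style
alignment score

$$\mathrm{AS} = m\,n\,2^{-S'}$$

for sequence lengths $m, n$ (optionally scaled by an effective
search-space multiplier). Lower AS means stronger similarity. Edges are
computed once at the loosest threshold (default $10^{-30}$); every sweep
over stricter cut-offs is pure edge filtering, so components can only
split, never merge. Connected components — not density-based clusters —
define the sequence clusters, matching the visual separation criterion
used with network viewers.

The web tool originally used for this kind of analysis does not document
its exact score, so the package makes no promise of reproducing any
particular network's edge counts; instead, class-separation behavior is
validated on synthetic planted-partition families where the truth is
known. The `percent_identity` of an edge is computed on a canonical
orientation of the pair so that scoring is exactly symmetric.

# Reference anchoring and the curation criteria

Queries are anchored to an annotated class I CDH reference by global
(Needleman–Wunsch) alignment, giving a per-position map from reference to
query coordinates. The canonical class I coordinates are used throughout:
heme ligands Met65 and His163 in the Cyt domain and the catalytic His689
in the DH domain. The five criteria are operationalized as:

* **signal peptide** — built-in heuristic (below) or an external
  predictor's tabular calls, which take precedence;
* **Rossmann motif** — `G-x-G-x-x-G` must occur in the query region
  aligned to ±15 columns around the reference motif start (the exact
  search neighborhood is not prescribed anywhere, so it is a documented,
  configurable default);
* **catalytic His** — the query residue mapped from the reference
  catalytic position must be H;
* **Cyt domain** — at least 60% of the reference Cyt region must align,
  without gaps, to query positions preceding the DH start (a numeric
  reading of "contains an N-terminal Cyt domain", which has no published
  numeric rule);
* **heme ligands** — mapped positions must carry M and H.

A query whose global-alignment identity falls below 25% is flagged
*unanchorable*: all alignment-based criteria report unknown and the
verdict is excluded. The floor was set at 25% because under this aligner
(end-gaps penalized, BLOSUM62, 11/1) even unrelated random sequences reach
about 15–16% identity-over-columns — a floor of 15% would reject nothing.
Genuinely homologous queries anchor far above 30%.

**Shipped reference.** The real class I reference entry is not
redistributed with the package; instead `synthetic_reference()` builds a
deterministic *synthetic* stand-in: a pseudo-random 810-residue protein
carrying every landmark at the canonical coordinates (signal peptide,
M65, H163, unique YDY at 264, `GAGTSG` at 268, H689). Because anchoring
is relative to whatever reference is supplied, the synthetic stand-in is
fully functional for testing and for synthetic-data work; users analyzing
real data should supply the real reference via `reference_annotation()`.

**Signal-peptide heuristic.** Within the first 40 residues the heuristic
requires (1) at least one K/R in the first 8 residues (n-region), (2) a
run of ≥7 consecutive apolar residues starting by position 12 and ending
by 25 with mean Kyte–Doolittle hydropathy ≥1.5 (h-region), and (3) an
A/G/S within 6 residues after the run (c-region). It is a triage tool:
on the synthetic generator's canonical signal peptides its recall is
100%, but it is *not* a substitute for a dedicated predictor on real
sequences, and predictor output overrides it whenever provided. Counts
that depend on the real predictor (e.g. how many database sequences pass
criterion (i)) are therefore not reproduced by this package.

**Logos.** Sequence logos are defined on reference columns through the
anchoring maps (a star alignment), not on a full multiple alignment —
a deliberate substitution that avoids an external MSA dependency. Column
information content is $R = \log_2 20 - H$ bits, with the Basharin
small-sample correction available but off by default.

**Redundancy reduction** is greedy first-fit in input order at ≥99%
pairwise global identity (matches over aligned columns), which reproduces
the deterministic behavior of interactive alignment editors' redundancy
removal.

**Sub-clades.** The evolutionary-distance threshold (default 0.4) is
interpreted as *cumulative root-to-node path distance* after pruning
outgroups: the first edge on each root-to-leaf path whose child node
exceeds the threshold is cut, and each cut subtree is one sub-clade;
leaves never separated from the root form a single residual clade (so a
zero-depth star is one clade). Plausible alternatives — pairwise leaf
distance or subtree height — were considered; root-to-node distance was
chosen because it makes clade count monotone in the threshold and is the
reading that a fixed-radius cut in a tree viewer produces. Candidate
selection takes `per_clade` members from every clade, preferring records
flagged with a plant-associated lifestyle and breaking ties by accession
order, so selection is deterministic.

# Construct design

Domestication removes every occurrence (both strands) of the SacI, PmeI,
AscI, BbsI and BsaI recognition sites by single synonymous codon edits,
chosen to introduce no new site in an 8-bp neighborhood (pre-existing
neighboring sites are fixed in later iterations); among equivalent edits
the codon most frequent in a configurable usage table wins (uniform by
default, then alphabetical). The terminal stop codon is removed. The
translation is asserted unchanged after every run.

Fragmentation cuts at the codon boundaries mapped from the domain split —
the DH module starts 8 residues before the conserved YDY motif — and
subdivides any module that would exceed 900 bp of synthesized length.
Fusion overhangs are the CDS's own 4-mers at each junction; a junction
slides in codon steps until its overhang is unique, non-palindromic and
not the reverse complement of another in use. Fragments below 300 bp
(always the signal-peptide module) are padded with a neutral A/C/T-only
spacer placed 3′ of the reverse recognition site, outside the assembled
product; the A/C/T alphabet guarantees the spacer can never contain or
complete any of the five recognition sites, all of which contain G. The
stop module carries the TAA codon (plus, when needed for overhang
uniqueness, a ≤4-nt neutral tail after the stop, which is outside the
ORF). `validate_assembly()` simulates the one-pot reaction: BsaI-style
digestion strips adapters and spacers, ligation proceeds by exact 4-mer
overhang matching independent of fragment order, and the single product
must equal the domesticated CDS + TAA with a translation ending in a stop.

# Biochemical calculators

One unit (U) oxidizes 1 µmol of electron acceptor per minute. Volumetric
activity is `slope / (ε · d) × dilution / sample fraction` with ε in
mM⁻¹cm⁻¹, so an AU min⁻¹ slope becomes µmol min⁻¹ mL⁻¹ directly. Slopes
come from ordinary least squares over the whole trace by default (a fit
window is configurable); negative slopes clip to zero with a warning, and
a low R² triggers a nonlinearity warning. The shipped presets are DCIP at
520 nm (ε = 6.9), DCIP at 600 nm for pH 8 (11.8) and cytochrome *c* at
550 nm (19.6). The limit of quantification is 10 sample standard
deviations of blank reactions.

Purification tables derive total protein (explicit totals take precedence
over concentration × volume, because measured totals are what published
tables print), specific activity, yield relative to the supernatant,
purification factor and RZ = A420/A280. Below-detection-limit entries are
a distinct state (`"b.d.l."` in, `bdl = TRUE` out) and never coerce to
zero. All arithmetic is at full precision; rounding is for display.

ε₂₈₀ from sequence is 5500·nTrp + 1490·nTyr + 125·nCystine with all
cysteines assumed paired by default (⌊nCys/2⌋ cystines). Which residues
constitute the *mature* chain depends on a cleavage assumption that the
package does not guess, so published coefficient values are inputs, not
targets.

FAD occupancy follows the TCA-release logic: flavin molarity from
A450/ε₄₅₀ (default 11.3 mM⁻¹cm⁻¹), protein molarity from the native A280
iteratively corrected for the flavin's own 280-nm absorbance
(`P ← (A280 − FAD·ε_FAD280)/ε_prot280` to a 10⁻⁹ fixed point). The cited
iterative protocol is not spelled out in the primary literature this
package follows, so the fixed-point scheme and its constants are declared
here as the package's definition, with ε_FAD280 = 0 by default (making
the non-iterative estimate the out-of-box behavior). Normalization to
100% flavin loading divides the specific activity by the occupancy, with
relative uncertainties added in quadrature when supplied.

Spectral features: the Soret maximum is located in the 400–440 nm window
by quadratic interpolation around the grid maximum, requiring a strict
interior local maximum — a heme-free DH-domain spectrum, whose absorbance
rises monotonically toward the flavin band, is correctly flagged "no
Soret band". The oxidized→reduced peak shift, RZ of the oxidized
spectrum, α/β band amplitudes (545–575 / 515–545 nm) and the
reduced-minus-oxidized difference spectrum complete the report.

# Synthetic data: what it emulates, and what it does not

Every generator is deterministic under one explicit seed and returns its
ground truth.

* `generate_family()` plants a partition of sequence classes diverged
  from a common root along a caterpillar topology (the last class splits
  at the root, the first two are siblings), emulating nested class
  divergence. Substitutions follow a uniform-exchange model — sufficient
  for identity-controlled planting, but with none of the rate
  heterogeneity or indel structure of real protein families. Indels are
  off so planted coordinates stay exact. Designed identities include the
  1/19 coincidence correction for uniform replacement; realized pairwise
  identities land within ±3 percentage points of design. The *designed
  separation cut-off* is derived a priori from the identity targets via
  the expected-score model (expected raw score
  $L(p\,\bar m_{\text{diag}} + (1-p)\,\bar m_{\text{off}})$ converted
  through the bit score; geometric mean of the predicted within- and
  closest-between-class AS), not tuned on any observed outcome.
* `generate_cdh_set()` derives CDH-like sequences from the synthetic
  reference with background mutations that never touch the landmark
  coordinates, then applies targeted ablations (h-region poisoning,
  motif-glycine, catalytic-His, heme-Met, YDY single-point changes, an
  optional C-terminal extension); chance motif re-occurrences near an
  ablated landmark are scrubbed so truth labels are unambiguous.
  `ablate_features()` produces the feature-negative twin of an existing
  record, differing at exactly the recorded positions.
* `generate_tree()` plants clades whose internal nodes sit beyond the
  distance threshold while leaves stay shallow; `generate_cds()`
  reverse-translates with seeded codon sampling and plants recognition
  sites by synonymous rewrites at feasible positions; `simulate_assay()`,
  `simulate_spectrum()` and `simulate_purification()` invert the
  corresponding calculators' forward models exactly at zero noise.

Passing tests on these generators shows that the *computational* chain is
correct against known truth. It does not show that the heuristics (signal
peptide, Rossmann window, Cyt coverage) have any particular sensitivity
on real, indel-rich, compositionally biased sequences — that calibration
requires the external tools the real study used.

# Numerical choices and problem sizes

* Alignment tie-breaks are those of the underlying dynamic-programming
  implementation and are deterministic; pair scores use a canonical
  sequence orientation so both argument orders agree exactly.
* Sweep cut-offs must be strictly decreasing; components are renumbered
  deterministically by smallest member accession.
* Logo columns with zero coverage report zero information; frequencies
  always sum to 1 within 10⁻⁹.
* The validation suite and the acceptance script size their simulations
  for one CPU: an 80-sequence 4-class family (300-residue ancestors) for
  the network sweep, 200 sequences for curation precision/recall, 50
  sequences in 10 planted redundancy clusters, 20 seeded CDS for the
  construct round trip, and 100 seeded purification scenarios. These
  sizes give exact expectations (Rand index 1.0, zero residual sites)
  rather than statistical bands wherever the design permits.

# Known limitations

* The alignment-score model is this package's own; absolute AS values are
  not comparable to any specific web tool's numbers, only the relative
  separation structure is.
* The signal-peptide heuristic is a triage aid; external predictor calls
  should be supplied for real data.
* Clade assignment requires branch lengths and a rooted reading of the
  tree; alternative threshold semantics (pairwise distance, subtree
  height) are not implemented.
* Database counts from the original mining stages (live BLAST/hmmsearch)
  and predictor-dependent sequence tallies are inputs to, not outputs of,
  this package.
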