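# cdhprospect

A tidyverse-native R toolkit for prospecting **class III cellobiose
dehydrogenases (CDH)** — extracellular fungal flavocytochromes with an
N-terminal heme *b* cytochrome (Cyt) domain and a catalytic FAD-dependent
dehydrogenase (DH) domain — from bulk protein sequence sets, and for
computing the biochemical quantities used to characterize the enzymes once
expressed. It is written for enzyme discovery groups who mine sequence
databases for expressible candidates and then need the downstream
construct-design and assay arithmetic in one reproducible place.

The pipeline has six parts:

* **Sequence I/O** — FASTA reading/writing, merge-and-deduplicate of
  search results, inclusive length windows (150–1100 residues for network
  building, 700–1000 for full-length candidates).
* **Sequence similarity networks** — all-vs-all Smith–Waterman
  (BLOSUM62, affine gaps 11/1), raw scores converted to bits with
  Karlin–Altschul statistics and to an expectation-style alignment score
  `AS = m·n·2^(−bits)` (lower = more similar). Clusters are connected
  components, followed across a ladder of decreasing AS cut-offs; seed
  sequences pull their cluster out at a chosen cut-off.
* **Curation** — global-alignment anchoring to an annotated class I CDH
  reference (heme ligands Met65/His163, catalytic His689), the five
  functional criteria (signal peptide, Rossmann `GxGxxG`, catalytic His,
  N-terminal Cyt domain, heme ligands), ≥99%-identity redundancy
  reduction, reference-column sequence logos, domain splitting eight
  residues before the conserved YDY motif, sub-clade assignment at an
  evolutionary-distance threshold of 0.4, and deterministic candidate
  selection preferring plant-associated lifestyles.
* **Construct design** — removal of SacI/PmeI/AscI/BbsI/BsaI sites by
  synonymous codons, partitioning into 300–900 bp golden-gate fragments
  with unique 4-nt fusion overhangs and spacer padding for the short
  signal-peptide module, and in-silico digestion/ligation validation.
* **Biochemistry** — volumetric/specific activities from absorbance
  slopes (1 U = 1 µmol acceptor oxidized per minute; DCIP ε₅₂₀ = 6.9,
  DCIP ε₆₀₀ = 11.8, cytochrome *c* ε₅₅₀ = 19.6 mM⁻¹cm⁻¹), purification
  tables with b.d.l. propagation, ε₂₈₀ from sequence, FAD occupancy with
  iterative A280 correction and normalization to 100% flavin loading,
  and UV-Vis features (Soret peak and shift, RZ = A₄₂₀/A₂₈₀, α/β bands,
  difference spectra).
* **Synthetic data** — seeded generators for every input with planted
  ground truth (sequence families, feature ablations, trees, CDS with
  planted restriction sites, assay traces, spectra, purification
  scenarios).

## Worked example

Build a network over a synthetic 4-class family and watch the classes
separate as the cut-off tightens:

```r
library(cdhprospect)

fam <- generate_family(family_spec(n_classes = 4, members_per_class = 5,
                                   ancestor_length = 300, seed = 42))
net <- build_network(fam$records, threshold = 1e-10)
net
#> Sequence similarity network: 20 nodes, 123 edges (AS <= 1e-10)

sw <- sweep_components(net, 10^c(-20, -60, -100, -140),
                       seed_groups = split(fam$records$accession,
                                           fam$records$class_label))
glance(sw)
#>   cutoff n_components largest
#> 1 1e- 20            2      15
#> 2 1e- 60            3      10
#> 3 1e-100            4       5
#> 4 1e-140            4       5
sw$separation
#>   group  separation_cutoff
#> 1 class1            1e-100
#> 2 class2            1e-100
#> 3 class3            1e- 60
#> 4 class4            1e- 20
```

The most distant class (class4) occupies its own cluster already at
10⁻²⁰, class3 at 10⁻⁶⁰, and the sibling pair class1/class2 only at
10⁻¹⁰⁰ — the nested separation order the generator planted. At the
generator's designed cut-off (`fam$truth$designed_cutoff`, here
6.3·10⁻¹¹⁸) the components reproduce the planted families exactly (Rand
index 1.0), and `extract_cluster(net, cutoff, seeds)` pulls out a seed's
whole family.

Purification arithmetic from step measurements:

```r
steps <- tibble::tibble(
  step = c("Supernatant", "HIC", "AEX"),
  volume = c(4500, 750, 15), conc = c(0.3, 0.8, 4.5),
  total_protein = c(1310, 598, 68),
  total_activity_dcip = c(946, 542, 111))
purification_table(steps)
#>   step        total_protein total_activity specific_activity yield_pct
#> 1 Supernatant          1310            946             0.722     100
#> 2 HIC                   598            542             0.906      57.3
#> 3 AEX                    68            111             1.63       11.7
```

The supernatant row is the reference (yield 100%, factor 1); the final
step reaches 1.63 U mg⁻¹, an 11.7% yield and a 2.26-fold purification. A
specific activity measured at partial flavin loading is rescaled to full
loading by its occupancy:

```r
normalize_to_full_fad(9.4, 0.44)
#>   specific_activity_full_fad
#> 1                       21.4
```

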