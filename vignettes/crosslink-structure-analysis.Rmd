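---
title: "Cross-link networks on atomic structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link networks on atomic structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoxl)
```

## The problem

Cross-linking mass spectrometry (XL/MS) with a cleavable amine-reactive
linker such as DSSO identifies pairs of lysine residues that were close in
space in the native sample. Each identification is a cross-link spectral
match (CSM): two protein accessions, two 1-based residue positions, an
identification score and an FDR. Because the linker arm plus two lysine
side chains span a bounded distance, a confidently identified cross-link is
a distance restraint: the Calpha atoms of the two residues should lie
within roughly 30 Å of each other in any atomic model that is consistent
with the data.

`axoxl` turns tables of CSMs into amino-acid-resolution interaction
networks and then confronts those networks with atomic models. Its stages
are deliberately small and composable:

1. **Import and filter.** `read_xl_table()` parses exporter-specific
   CSV/TSV layouts through a column-map "dialect". `filter_records()`
   applies the conventional acceptance gates: FDR at most 1% (inclusive)
   and score strictly greater than 40. The strict/inclusive asymmetry is
   intentional and matches how these gates are conventionally quoted.
2. **Orthogroup collapsing.** `collapse_to_orthogroups()` replaces protein
   accessions by eukaryotic ortholog group ids (eggNOG-style tables are
   consumed, never computed), so that co-orthologs and paralogs are
   considered together and can be matched to human gene names. Collapsing
   relabels records; it never drops or merges them. Accessions without a
   group become singleton groups and are reported.
3. **Deduplication.** `deduplicate_links()` collapses CSMs into unique
   residue-pair links under a canonical unordered key (lexicographic by
   group, then residue), tracking support and best score. The output is
   sorted canonically, which makes every downstream result invariant under
   record permutation and endpoint swapping.
4. **Structure mapping.** `map_links()` places links on a structure via a
   chain map (group to chain ids) and optional alignment-based residue
   transfers, computes Calpha–Calpha Euclidean distances, and classifies
   them.
5. **Disambiguation.** `distance_heatmap()` and `satisfiable_by_any()`
   re-evaluate violated links across conformational ensembles;
   `reinterpret_intralinks()` re-evaluates extreme intramolecular
   violations as inter-copy contacts in a rigid oligomer lattice.
6. **Model placement.** `kabsch()` and `fit_model_to_chain()` superpose a
   candidate model onto a (possibly unassigned) backbone segment and
   `check_crosslink_consistency()` asks whether the placement satisfies the
   links it should explain.

`run_pipeline()` orchestrates stages 1–5 from one configuration and writes
machine-readable outputs; it is deterministic given identical inputs.

## Distance thresholds and their meaning

`xl_thresholds()` encodes the DSSO geometry with three cutoffs, in
Ångström:

* **satisfied**: distance ≤ 30. The linker span plus two lysine side
  chains bounds the Calpha–Calpha distance at about 30 Å; the boundary is
  inclusive ("less than or equal to").
* **moderate**: 30 < distance ≤ 40. Links in this band are longer than the
  ideal constraint but within the slack commonly granted for coordinate
  error and local flexibility; they are reported separately rather than
  folded into either side.
* **extreme**: distance > 100. Violations this large cannot be explained
  by flexibility of a single complex; they are the natural candidates for
  re-interpretation across conformations or oligomer copies.
* everything else (40 < d ≤ 100) is **violated**.

The thresholds are ordinary parameters: any analysis can tighten or loosen
them, with validation enforcing `satisfied ≤ moderate < extreme`.
Fractions are always reported over links with a numeric distance;
unmappable links (protein absent from the structure, position unaligned,
or residue not resolved) are tallied with their reason and excluded from
denominators, matching the convention of quoting satisfaction "of N mapped
XLs".

## Homo-oligomer ambiguity and the minimal-distance rule

When a group maps to several chains — a homodimer, or one protein resolved
in multiple copies — the spectroscopy cannot tell which copy reacted.
`map_links()` therefore evaluates every chain-pair assignment and records
the one with the minimal distance. This is the most permissive reading of
the restraint and the convention used in cross-link validation generally.
The same logic, extended across rigid-body copies, underlies
`reinterpret_intralinks()`: for a link (i, j) the minimum over ordered copy
pairs k ≠ l of d(copy_k·i, copy_l·j) is computed by exhaustive search. We
deliberately do not restrict the search to adjacent copies: with the
default of three copies the search is cheap, and exhaustiveness avoids
assuming the lattice adjacency that the analysis is supposed to test. The
repeat transform itself (rotation + translation) is user input, typically
taken from a determined structure or tomogram — the package never
estimates it.

## Cross-species residue transfer

Placing cross-linked residues from one species onto a structure solved in
another requires a residue-level correspondence. `global_align()` performs
global (Needleman–Wunsch) alignment with affine gaps; the implementation
is `Biostrings::pairwiseAlignment`, wrapped so that the package controls
the conventions:

* BLOSUM62, gap open 11, gap extend 1 — the standard protein defaults. A
  gap of length L costs `open + L · extend`.
* `X` is scored 0 against everything, making unknown residues
  alignment-neutral.
* Where several alignments are co-optimal, the traceback reported by the
  underlying library is used; it is deterministic, and the optimal score —
  which the tests verify against exhaustive enumeration — is unaffected.

`residue_transfer()` then maps each source position to the author number
of its aligned target residue, flagging `unaligned` (gap) and
`missing_in_structure` (aligned but not resolved) separately. The transfer
is refused wholesale — every position reported `unaligned` — when global
identity falls below 20%: below that, residue-level correspondence from a
pairwise alignment is not trustworthy, and a spurious mapping is worse
than none. For same-species structures whose author numbering is the
sequence numbering, `identity_transfer()` provides the degenerate mapping,
so both placement routes (alignment-based and direct numbering) are
supported.

## Rigid-body fitting

`kabsch()` implements the closed-form least-squares superposition: SVD of
the cross-covariance of the centred point sets, with the reflection
corrected by flipping the smallest singular direction whenever the
determinant would be −1, so the result is always a proper rotation.
Collinear point sets (second singular value numerically zero) are rejected
— the rotation about the common line is undetermined. `fit_model_to_chain()`
offers two correspondence modes. The sliding-window mode slides the
model's Calpha trace along the target chain's resolved Calphas and
superposes at every offset, returning the minimal-RMSD placement, the full
offset-vs-RMSD profile, and breaking ties toward the smallest offset (a
fixed, documented rule rather than an arbitrary one). The
sequence-aligned mode corresponds residues through `global_align()` and
superposes over positions resolved in both — appropriate when the
sequences are homologous but the register is unknown. Correspondence is
Calpha-only throughout: it is the convention used for the distance
analysis, and it keeps model fitting consistent with link classification.

## The synthetic-data generator

Every claim the test-suite makes about recovery is made on synthetic data
with known ground truth, generated by the package itself:

* **Chains** are Calpha traces with the 3.8 Å consecutive spacing of
  trans-peptide geometry: either self-avoiding random walks (uniform
  random step directions, minimum 3.0 Å separation) or ideal α-helices
  (radius 2.3 Å, rise 1.5 Å, 100° per residue). These are *geometric*
  stand-ins: they reproduce realistic distance distributions at linker
  scale but have no Ramachandran statistics, secondary-structure
  alternation, or side chains. Tests passing on them demonstrate the
  correctness of the bookkeeping and geometry, not robustness to the
  coordinate error, conformational heterogeneity and density of real
  structures.
* **The study conditions** (defaults of `synth_spec()`): 5 proteins of
  60–120 residues, 60 true links drawn uniformly from residue pairs within
  25 Å (comfortably inside the 30 Å constraint, as links from a real
  linker would be), a 10% false-link rate drawn uniformly from all residue
  pairs, a 10% duplicate rate emitting endpoint-swapped re-observations,
  and score/FDR distributions under which true and false links both pass
  the default filters — the false rate, not the score filter, is the
  stressor for the geometric classification. These values were fixed once
  as a realistic desk-scale emulation of a cross-linking experiment and
  are deliberately not tuned per test.
* **Ensembles** come from `make_ensemble()`, which rotates all residues
  past a pivot about an axis through the pivot Calpha — a hinge, the
  simplest domain motion that produces state-specific links.
* **Lattices** come from `make_oligomer_testcase()`: a 120-residue helix
  (about 180 Å end to end) repeated head-to-tail by a pure translation of
  one molecule length, with links planted between the last and first three
  residues. By construction these links span > 100 Å within the monomer
  and ≤ 25 Å between adjacent copies — the geometry that makes extreme
  violations reinterpretable.
* **Randomness** flows from one seed through named sub-streams (an
  FNV-folded seed per task label), so adding a generator never perturbs
  the draws of an existing one, and every artefact is reproducible from
  `(seed, label)`.

## Numerical and degenerate-input choices

* Parsing never silently drops data: each malformed row becomes one
  logged skip with a reason; self-links are rejected at parse time; an
  absent FDR column yields `NA` FDR, which passes the FDR filter with a
  warning (deposited tables are often pre-filtered, and failing them
  wholesale would be worse).
* Alternate locations are resolved by highest occupancy, ties broken
  alphabetically by altloc id; insertion codes are part of the author sort
  key. Residues without a Calpha carry `NA` coordinates — never a sentinel
  value — and a chain with zero Calphas is retained with a warning.
* Unmappable heatmap cells are ignored by the per-link minimum rather than
  treated as infinite violations; a link unmappable in every conformation
  is flagged explicitly.
* All output orderings are canonical (sorted by link key), which is what
  makes `run_pipeline()` byte-reproducible.

## Problem sizes

The bundled tests and the acceptance script run entirely on synthetic
data at desk scale: systems of 5 proteins (about 400–500 residues total),
link tables of 60–500 records, ensembles of 2–3 conformations, lattices of
3 copies, and the complete enumeration of global alignments for all
sequence pairs of length ≤ 4 over a 4-letter alphabet (115,600 pairs)
against the package's aligner. These sizes exercise every code path while
keeping the whole suite fast; the pipeline itself scales to
interactome-size tables (tens of thousands of records) because every stage
is vectorised or linear in the number of links.

## Known limitations

* Distances are Calpha–Calpha Euclidean. Solvent-accessible surface
  distances, which track the physical linker path more closely, are out of
  scope by design.
* Orthology inference, spectral identification, and model generation are
  consumed, not computed: the package starts from identification tables,
  orthogroup tables, and coordinates.
* The mmCIF reader does not write mmCIF, and density maps are not
  handled.
* The published interactome counts (tens of thousands of CSMs over a
  thousand proteins) require the deposited mass-spectrometry tables and
  large cryo-EM structures; the corresponding regression test documents
  what it would check and fails with an explicit message when those inputs
  are not staged locally.
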