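---
title: "Signature variation scoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature variation scoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssv)
```

## The model

The package scores a point mutation by how it moves a protein pocket's
*structural signature* relative to a curated set of template enzymes that
already exhibit a desired property (thermostability, product tolerance,
catalytic efficiency). The underlying assumption is that such properties
leave a geometric/physicochemical imprint on the catalytic pocket that a
distance-distribution fingerprint can detect, and that moving a
non-tolerant enzyme's fingerprint toward the tolerant group is evidence a
mutation is worth testing in vitro. The score is a triage signal, not an
energy: it orders candidates for bench work, it does not predict activity
quantitatively.

The signature of a structure is a cutoff-scanning matrix. Heavy atoms are
assigned one or more of 8 pharmacophore classes (hydrophobic, positive,
negative, H-bond acceptor, H-bond donor, aromatic, sulfur, neutral); for
each unordered class pair (36 of them) and each cutoff point
d ∈ {0.0, 0.1, …, 10.0 Å} the vector stores the *cumulative* number of
atom pairs at distance ≤ d whose class sets can realize that pair. The
default grid yields 36 × 101 = 3636 components. Two readings of the
dimensionality are possible — 100 disjoint bins (3600) or 101 cumulative
points (3636) — and only the cumulative-101 layout is consistent with the
canonical 3636-column convention, so that is what `compute_signature()`
implements; `brute_force_signature()` pins the exact counting rule with
an independent double loop.

Scoring: with a template database `T`,
`dSSV(X) = min over t in T of ||sig(X) - sig(t)||2`, the minimum taken
independently for wild and mutant (their nearest templates may differ —
a large signature change can land the mutant in another template's basin,
which is still beneficial if it shrinks the distance). Then
`ddSSV = dSSV(mutant) - dSSV(wild)`; negative is called beneficial,
positive not beneficial, and exactly zero neutral.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| pocket cutoff | 6.5 | Å | ligand-distance radius defining the catalytic pocket; 6–7 Å is where pocket fingerprints discriminate best, and 6.5 pulls in second-shell residues known to matter for glucose tolerance |
| grid | 0–10, step 0.1 | Å | the scanning range of the signature; 10 Å spans a pocket's diameter, 0.1 Å resolves packing changes |
| `neutral_tol` | 0 | score units | half-width of the neutral band; 0 means only an exact tie is neutral, matching the binary sign rule |
| alignment | BLOSUM62, gap 10/0.5 | — | global residue correspondence for pocket transfer between homologs |
| identity floor | 20 | % | below this the correspondence is unreliable and `map_pocket()` refuses |
| conservation threshold | 1.0 | fraction | only positions conserved in *all* template sequences are protected from mutation |
| ΔΔG cutoff | −2.0 | kcal/mol | "highly destabilizing" has no universal numeric definition; −2 kcal/mol is a conservative, documented assumption, and an explicit flag column overrides it |

All of these are arguments, not constants; the defaults reproduce the
published workflow.

## Counting rules and numerical choices

* Hydrogens and waters are dropped at parse time; crystallographic inputs
  rarely have hydrogens and the typing table is heavy-atom based.
  Alternate locations resolve to the highest-occupancy conformer (ties:
  alt-loc `A`, then first seen); only the first model of a multi-model
  file is read.
* Intra-residue atom pairs count; self-pairs do not. Distances are kept at
  full float precision; the cumulative cell for cutoff point `d` includes
  a pair at exactly `d` (inclusive ≤, with a 1e-9 guard against float
  representation of the 0.1 Å grid). Cutoff 0.0 counts only coincident
  atoms.
* Multi-class atoms (e.g. HIS ND1 = positive + donor + acceptor +
  aromatic) contribute one count to *each distinct* class-pair index
  derivable from the two atoms' class sets. Under single-class typing
  this reduces to partitioned counting, which is what the pair-count
  conservation property asserts.
* `nearest_template()` breaks exact ties by lexicographically smallest
  template id, for cross-platform determinism.
* Degenerate inputs: an empty structure signs to the zero vector (flagged
  semantics, not an error) so pipelines can proceed; an empty template
  database, mixed grids, or mismatched dimensions are errors.

## The pharmacophore table

The exact atom-typing of the original fingerprint tooling is not public,
so the package ships an explicit, versioned table
(`default_pharmacophore_table()`, also at
`inst/extdata/pharmacophore_classes.tsv`): aromatic = ring atoms of
PHE/TYR/TRP/HIS; positive = LYS NZ, ARG NE/NH1/NH2, HIS ND1/NE2;
negative = ASP OD1/OD2, GLU OE1/OE2, OXT; donor/acceptor per standard N/O
hydrogen-bonding roles (backbone N donor except PRO, backbone O acceptor);
sulfur = CYS SG, MET SD; hydrophobic = every non-aromatic carbon; neutral
= anything left classless. Whether HIS ring nitrogens should carry
`positive` in addition to donor/acceptor is genuinely open; the shipped
default includes it, and the table is plain data — pass a modified TSV to
`read_pharmacophore_table()` to change the convention without touching
code. Ligand atoms are typed by element fallback only and participate in
pocket *extraction*, never in signatures.

## Mutant construction

Full homology modeling is out of scope. `apply_mutation()` offers two
geometric modes: **truncate** renames the residue and keeps the
intersection of its atoms with the mutant type's canonical set (backbone
always kept) — it never invents coordinates, so it under-represents
growth mutations; **graft** additionally grows missing side-chain atoms
from an idealized internal-coordinate template (standard bond lengths and
angles, trans chain dihedrals, fixed ring closures, no clash resolution
or rotamer search). Both are deterministic. Externally modeled mutant
PDBs are first-class input to the scoring layer, which is agnostic to how
mutants were built.

## What the synthetic fixtures establish — and what they do not

The generators emulate the *mechanics* of real data: well-formed PDB
records, multi-residue pockets with realizable pharmacophore class sets,
template sets as bounded-noise copies of a base structure (uniform
per-coordinate jitter, chosen over Gaussian noise because bounded
displacement gives clean ordering behavior), and planted wild/mutant
pairs displaced along shared directions so the mutant is verifiably
closer to the template in signature space. Because scaled coordinate
displacement does not *provably* order Euclidean signature distances,
`plant_beneficial_case()` checks the realized ordering and, if ever
violated, redraws its direction set deterministically (seed + k); in
practice the first draw suffices.

A green suite therefore establishes: exact agreement of the signature
with an independent counting oracle, the metric and invariance properties
of the score, correct bookkeeping of the screen and filter chain, and the
published self-contained numbers (3636 components; 20/27 = 0.74
benchmark accuracy; 418 mutants from a 22-residue pocket; 86 → 77 → 19 →
15 filter cascade). It does **not** establish predictive performance on
real β-glucosidase structures: that depends on externally modeled mutants
and the curated template database, which are not desk-reproducible. The
shipped benchmark fixture evaluates the *published* scores, not scores
recomputed from structures.

On that benchmark, only accuracy is reproducible from the published
per-mutation table: with positive = beneficial the confusion counts are
tp = 10, fn = 1, tn = 10, fp = 6, giving precision 0.625 and specificity
0.625, whereas the published panel reports 0.89/0.92 — values not
derivable from the printed scores under any positive-class convention.
`evaluate_benchmark()` therefore reports both class conventions and the
package claims only the accuracy.

## Known limitations

* Truncate-mode mutants change the signature only by *removing* atoms;
  screens run in truncate mode are biased toward calling
  large-to-small substitutions beneficial. Graft mode mitigates but uses
  a single idealized rotamer.
* Pocket transfer uses global sequence alignment; it is reliable at the
  ~50 %+ identity of the motivating enzyme pairs but is not a structural
  aligner, and unmapped pocket positions are reported rather than forced.
* The score has no calibration: ΔΔSSV magnitudes are comparable within
  one template database and grid, not across databases.
* No mmCIF, nucleic acids, multi-model ensembles, or hydrogen placement.
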