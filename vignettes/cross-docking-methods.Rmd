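---
title: "Cross-docking for receptor ensemble selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-docking for receptor ensemble selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdockr)
```

## The experiment the package automates

A target protein with a flexible binding site is usually represented in
the PDB by many holo structures, each solved with a different ligand and
each with a slightly different pocket geometry. Which of those structures
should anchor a pose-prediction or virtual-screening campaign? X-ray
quality metrics (resolution, R-factor, B-factors) do not answer this,
because a pocket shaped around a small ligand may simply be unable to
accommodate a larger chemotype regardless of how well it was resolved.

Cross-docking answers it empirically: dock every co-crystallised ligand
of the family into every receptor structure of the family and measure, for
each (ligand, receptor) cell, how closely the docked poses approach the
ligand's own crystallographic pose. Receptors that reproduce *non-native*
ligand poses — low column-average RMSD, many docks under the 2.0 Å
convention — are the robust choices. The self-docking diagonal doubles as
a sanity check on the docking engine itself: if even re-docking fails, the
engine/scoring combination is unsuited to the target and raising the
search effort (`exhaustiveness`) is the first remedy.

`run_crossdock()` executes the full n×n grid: box placement, ligand
randomization, docking, symmetry-corrected scoring, best-pose selection,
and failure bookkeeping; `summarize_receptors()`, `rank_receptors()`,
`build_tables()` and `write_reports()` produce the analysis layer.

## Assumptions about the inputs

* **One shared frame.** All receptors (and hence all crystal ligand poses)
  must be superposed onto a common frame *before* the run, with whatever
  alignment tool the user prefers. The package never superposes anything —
  the entire point of the in-place RMSD is that a pose landing in the
  wrong place scores badly. This is a user precondition, checked only by
  documentation.
* **Pairing by name.** A receptor file stem ends in `-p`, its ligand in
  `-l`, sharing a root (`1hwj-p.pdb` / `1hwj-l.pdb`). Matching is
  case-sensitive on the root and extension-agnostic; orphans and ambiguous
  duplicates abort library assembly with the offending roots listed.
* **Waters out, cofactors in.** Crystallographic waters ({HOH, WAT, H2O,
  DOD}, configurable) are stripped from receptors at load time; every
  other hetero record (cofactors, coenzymes, ions) is treated as part of
  the receptor. Chain subsetting is user preprocessing, not performed
  here.
* **Hydrogens.** Parsed and retained in the molecule container, but
  excluded from all RMSD mapping: engine pose output routinely omits
  nonpolar hydrogens, which would make an all-atom RMSD ill-defined.

## The symmetry-corrected RMSD

For reference heavy-atom coordinates $r_i$ and pose coordinates $p_i$ in
the shared frame,

$$\mathrm{RMSD} = \min_{\sigma \in \mathrm{Aut}(G)}
  \sqrt{\tfrac1N \sum_{i=1}^{N} \lVert r_i - p_{\sigma(i)} \rVert^2},$$

where $\mathrm{Aut}(G)$ is the automorphism group of the reference
ligand's heavy-atom graph, restricted to element-preserving permutations.
Without the minimisation, a carboxylate rotated by 180° or a flipped
phenyl ring would be charged a spurious penalty for an arbitrary file
ordering of equivalent atoms.

Implementation choices:

* The graph comes from the file's bond block (mol2) or, for formats
  without bonds (PDB, pdbqt), from covalent-radius perception: a bond is
  placed where the interatomic distance is at most 1.3 × the sum of the
  two single-bond covalent radii. File-specified connectivity always wins
  over perception.
* Automorphism generators are computed with vertex colours = elements
  (bliss, via igraph) and the group is closed under composition with a
  breadth-first sweep. The closure is capped at `max_mappings`
  (default 10,000): beyond the cap the identity mapping is used, a warning
  is emitted and the result is flagged `symmetry_corrected = FALSE`. A
  pathological highly symmetric molecule must degrade one number, not hang
  a grid of thousands of cells.
* Correspondence between reference and pose atoms is positional: the pose
  is the engine's transformation of the submitted file, in the same atom
  order. `map_atoms_by_name()` covers engines that reorder atoms.
* The tests hold this route to *exact* (1e-9 Å) agreement with a
  brute-force minimum over all element- and adjacency-preserving
  bijections, enumerated as raw permutations on molecules of ≤ 7 heavy
  atoms — small enough for 7! candidates, independent enough to count as a
  second opinion.

Published cross-docking tables rarely state whether their RMSDs are
symmetry-corrected or hydrogen-inclusive. Ours are symmetry-corrected and
heavy-atom; values for symmetric ligands can therefore sit systematically
at or below numbers computed with a naive fixed mapping.

## Engine abstraction and the two selections

One interface, two adapters. The **Vina adapter** shells out to an
AutoDock Vina executable: inputs are converted to pdbqt with Open Babel
when needed, a per-cell work directory receives the engine's standard
config file (`receptor`, `ligand`, `center_*`, `size_*`,
`exhaustiveness`, `num_modes`, `energy_range`, `seed`), the ligand can be
pre-randomized with the engine's randomize-only mode, and the output
multi-model pdbqt (`REMARK VINA RESULT` energy lines) is parsed back. The
search and scoring are entirely the engine's; nothing of them is
reimplemented.

The **mock engine** exists so that every pipeline property is testable
deterministically: each pose is the crystal reference translated along a
seeded random direction by a specified offset, with energy assigned by a
monotone function of the offset (default $-10 + d$ kcal/mol) or planted
per cell. A uniform translation keeps the identity mapping optimal even
under symmetry correction (for any automorphism $\sigma$, the cross terms
cancel and the RMSD is $\sqrt{d^2 + c_\sigma}$ with $c_\sigma \ge 0$), so
the planted offset *is* the ground-truth RMSD to machine precision. That
identity is the pipeline's central self-consistency check.

Each cell keeps two selections because they measure different abilities:

* `best_rmsd` — the pose closest to the crystal mode, regardless of rank:
  could the engine *sample* the native pose at all?
* `best_energy` — the top-ranked pose and *its* RMSD: would a prospective
  screen, which only ever looks at the best-scored pose, have seen the
  native mode?

A receptor can look excellent under the first criterion and mediocre under
the second; the reports keep both, and the ranking function accepts either.

## Tunable parameters

| parameter | default | units | why this default |
|---|---|---|---|
| `exhaustiveness` | 8 | — | the engine's stock search effort; raise it when self-docking RMSDs are poor |
| `num_modes` | 9 | — | the engine's stock pose count |
| `box_size` | 25 | Å | generous cube around a drug-like site; oversizing wastes search effort, undersizing clips poses |
| `box_center` | `"native"` | — | each receptor's own co-crystallised ligand defines its site; well-defined because the frame is shared. `"cross"` switches to the incoming ligand |
| `success_threshold` | 2.0 | Å | the field's conventional cutoff; the inequality is **strict**, a dock at exactly 2.0 Å is a failure |
| `include_self` | `TRUE` | — | self-docks sit inside the published matrices (bolded, not excluded); a switch removes them |
| `band_scope` | `"matrix"` | — | percentile bands pooled over the whole matrix; `"column"` bands each receptor against itself |
| `max_mappings` | 10,000 | mappings | automorphism-closure cap (see above) |
| `randomize_first` | `TRUE` | — | removes bias toward the crystal conformation; randomization happens once per **cell**, with a per-cell seed |

Per-cell seeds are derived from the global seed and both root names with a
31-bit polynomial hash, so a grid is reproducible end-to-end while cells
remain independent — the sequential result is by construction what any
parallel evaluation order would produce.

## Reports

Six files, in the canonical naming: the long-form per-pose table
(`Output`), the per-cell best pose (`Output_the_best_RMSD`), and four
ligand × receptor matrices (`Table_the_best_RMSD`,
`Table_the_best_energy`, `Table_RMSD_for_the_best_energy`,
`Table_energy_for_the_best_RMSD`). RMSD matrices carry two footer rows —
per-receptor average and strict sub-threshold count — computed over
non-failed cells only, with failed cells shown empty and counted
separately (silently propagating NaN into a ranking would be worse than
any individual docking failure).

Traffic-light bands mark the 10th/50th/90th percentiles of the pooled
matrix values by the nearest-rank definition (`sorted[ceil(p/100·n)]`):
≤ t10 green, ≤ t50 yellow, ≥ t90 red, otherwise unbanded. We read the
banding specification as percentiles rather than literal permille — a
permille rank is meaningless on a few hundred cells, and the traffic-light
semantics (best tenth green, worst tenth red) only make sense as
percentiles. When thresholds collapse the better band wins, so an
all-equal matrix is entirely green. Spreadsheets render to two decimals
with fills and a bold self-docking diagonal (via a bundled openpyxl
helper when a `python` interpreter is available); CSV mirrors carry full
precision and are the machine-readable source of truth, with band
assignments in a sidecar file. All writes are atomic
(write-then-rename), and the run manifest deliberately contains no
timestamp so that identical runs are byte-identical.

## What the synthetic families do and do not emulate

`generate_family()` builds toy families: ligands on three topologies (an
asymmetric hetero chain; a carboxylate-like swap-pair with exactly one
non-trivial automorphism; a carbon ring with the full dihedral group) and
receptors that are 20-atom cages around each site plus a retained cofactor
atom and a few waters for the stripping path. Geometries are chosen so
covalent-radius perception recovers exactly the intended bond graph.
Everything is deterministic given the spec and seed, down to file bytes.

These fixtures exercise parsing, pairing, symmetry handling, grid
bookkeeping, aggregation and reporting — the package's own logic — with
exactly known answers. They do **not** emulate real docking: no physics,
no induced fit, no conformational search, no score noise beyond what is
planted. A green test suite therefore certifies the harness around the
engine, not the docking engine's accuracy on any real target; conclusions
about a real receptor family still require real Vina runs on prepared
structures. Published case-study matrices are additionally stochastic
(engine seeds, preparation choices), which is why no attempt is made to
reproduce their cell values here. (One oddity of the original case-study
description is carried as-is: its text says twelve holo structures while
listing eighteen PDB codes.)

Problem sizes in the shipped tests and acceptance script — grids up to
4×4, oracle molecules of ≤ 7 heavy atoms, 200 oracle trials — were chosen
as the smallest sizes at which every property (symmetry classes,
selection divergence, boundary behaviour, failure handling) is actually
exercised.

## Degenerate inputs and tie-breaks

* Best-pose ties (equal RMSD or equal energy) resolve to the lower engine
  mode index; ranking ties resolve to the complementary statistic, then
  lexicographic root order.
* A failed cell (engine error, atom-count mismatch) is recorded with its
  diagnostic; the grid continues. Only a grid with *every* cell failed is
  an error, as is a receptor column with no surviving cells at summary
  time.
* Zero-heavy-atom ligands, non-bijective mappings, and pose/reference
  atom-count mismatches raise typed errors immediately rather than
  producing a number.

## Known limitations

* Ligands are compared only against their own crystal pose; there is no
  maximum-common-substructure RMSD across different ligands.
* No flexible-receptor docking, no retrospective enrichment (actives vs
  decoys) analysis, and no chain/protonation preparation — those belong to
  the tools upstream and downstream of the harness.
* The in-place RMSD is only as meaningful as the user's structural
  alignment; a poor superposition shows up as uniformly inflated RMSDs
  that no setting here can repair.
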