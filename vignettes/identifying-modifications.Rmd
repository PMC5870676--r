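---
title: "Identifying protein modifications in 3D structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying protein modifications in 3D structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modfinder)
```

## The problem

Protein modifications — phosphorylation, glycosylation, acetylation,
hydroxylation, metal coordination, disulfide and isopeptide bridges —
leave direct traces in deposited coordinate files. A modified residue is
filed as a nonstandard chemical component with its own 3-character code; a
glycan or metal ion is a separate non-polymer group sitting at covalent
distance from a side-chain atom; a cross-link is an extra covalent bond
between residues. `modfinder` turns those traces into explicit annotation.

The design principle throughout is *geometry as evidence*: apart from the
purely code-based modified-residue scan, every identification requires the
relevant atoms to actually be at covalent-bond distance in the coordinates.
Metadata records that assert connectivity (SSBOND, LINK, CONECT) are parsed
but never used as evidence, so the scanner behaves identically on entries
that lack them, and annotation errors in deposited metadata cannot
propagate.

## The dictionary drives everything

Each modification is one declarative record: identity (internal id,
optional PSI-MOD `MOD:NNNNN` and RESID `AANNNN` accessions, names,
keywords), a category, the chemical components involved, and the atom pairs
that bond them. The three categories carry structural invariants, enforced
by `validate_definition()`:

* `modified-residue` — exactly one amino-acid component, no linkages;
* `attachment` — at least one amino-acid and one non-polymer component,
  joined by at least one linkage;
* `cross-link` — two or more amino-acid components whose linkage graph is
  connected.

Component entries may list alternate codes (e.g. the NAG/NDG anomers) and a
terminal restriction (`any`/`n`/`c`; pyroglutamate, for instance, is
N-terminal only). Linkage endpoints carry an *ordered* list of candidate
atom names — PDB entries differ in which of several chemically equivalent
atoms forms the bond (HIS `NE2` vs `ND1` toward zinc; any of the four irons
of a 4Fe-4S cluster) — and the first matching name wins, which keeps
matching deterministic without combinatorial growth. The bundled starter
dictionary (~23 records) covers all three categories and the common
chemistry; the XML format supports arbitrarily many more. Accessions are
filled only where the curator could verify them and are otherwise absent.

## Bond inference

Two atoms are covalently bonded when

$$ d_{\min} \le \lVert x_i - x_j \rVert \le r(e_i) + r(e_j) + t $$

* `t` — tolerance, default **0.4 Å**. The slack absorbs coordinate error
  and strained bonds; it is the single most influential parameter and is
  exposed everywhere (API and CLI).
* `r(e)` — single-bond covalent radii from a standard published
  compilation (Cordero et al. 2008), with high-spin values for Mn/Fe/Co so
  that metal–ligand distances in coordination sites fall inside the
  threshold. The paper-of-record for radii choice is deliberately a data
  table, not code: `read_radii_table()` overrides it from a two-column text
  file, and unknown elements fall back to a 1.5 Å default with a warning
  rather than aborting a batch.
* `d_min` — lower cutoff, default **0.5 Å**, rejecting duplicated-atom
  artifacts that would otherwise count as "bonds" at near-zero distance.

Close pairs are found with a uniform spatial grid whose cell edge is
`2·max(r) + t`, the largest possible threshold, so scanning the 27
neighbouring cells of an atom is exhaustive. The grid is an
*implementation*; the *contract* is the brute-force all-pairs criterion,
and the test suite and acceptance script verify equality of the two on
random atom clouds. Hydrogens are excluded from candidate pairs: every
dictionary linkage is heavy-atom, and including riding hydrogens would only
create spurious matches.

## The three scans

**Modified residues** are matched by comparing each polymer residue's
component code with the dictionary; output is ordered by chain and polymer
position. A nonstandard component floating outside any chain is *not* a
modified residue (it has no sequence position); it can still participate in
attachments.

**Attachments** are matched per linkage: polymer residues whose code and
atoms fit one end, non-polymer groups fitting the other, bond required
between them. One record is emitted per bonded (residue, group) pair — so a
zinc ion held by two histidines and two cysteines yields four records
sharing one group, and a 4Fe-4S cluster ligated by four cysteines yields
four. The alternative — one record spanning the whole coordination shell —
was considered and rejected: per-pair records compose (the shell is
recoverable by grouping on the non-polymer group id) while the aggregate
does not decompose, and per-pair granularity matches how sequence viewers
mark sites. A glycan chain of several sugars yields only the
protein-proximal record; sugar–sugar tree traversal is out of scope.

**Cross-links** enumerate residue-to-component assignments with
backtracking over the detected-bond graph restricted to the atoms the
definition names. Definitions are tiny (2–7 residues), so exact search is
cheap and auditable, and the suite checks it against brute-force assignment
enumeration. Automorphic duplicates from symmetric definitions (CYS–CYS)
are collapsed by canonicalizing on the sorted residue identity set;
deterministically, the lexicographically smallest assignment is kept.
Cross-links involving residues that are themselves nonstandard components
need no special machinery — codes are matched like any other.

Category overlap is deliberately not suppressed: a selenomethionine inside
a disulfide-bonded chain reports both. The categories are independent
statements about the structure.

## Structure reading

`parse_structure()` normalizes PDB and mmCIF input (via `bio3d`) into one
model per entry:

* **Waters** (HOH/DOD/WAT) are dropped; they are never modification
  components.
* **Altlocs**: one geometry per atom — the highest-occupancy conformer
  wins, ties break to the lexicographically smallest altloc. Keeping both
  conformers would make bond detection multi-valued.
* **Models**: multi-model (NMR) files contribute one selectable model,
  the first by default; annotation is per entry, not per ensemble member.
* **Polymer typing**: ATOM records are polymer. HETATM residues with a
  known modified-residue code lying inside (or adjacent to) a chain's ATOM
  numbering are polymer too — the PDB format files nonstandard chain
  residues as HETATM. The same rule serves both formats, since `group_PDB`
  mirrors ATOM/HETATM in mmCIF.
* **Identity**: author chain ids and residue numbers (with insertion
  codes) are the reported identity; polymer position is the 0-based file
  order within the chain.
* **Elements**: taken from the element column when present; otherwise
  inferred from the atom-name convention (first character in polymer
  residues, with selenium special-cased; two-letter prefix tried first in
  HETATM groups). Unresolvable atoms are skipped from bond detection with
  a warning rather than failing the entry.

Reports are canonically ordered (category, definition id, first residue)
and distances are printed to 2 decimals, so identical inputs give
byte-identical TSV — the invariance tests rely on this.

## What the synthetic fixtures emulate

`make_fixture()` builds polymer chains on an extended-chain template (Cα
spacing 3.8 Å, template side chains), then plants each requested
modification by moving its linkage atoms to the exact requested distance in
an isolated "lane" well below the backbone, one lane per planted site, so
sites cannot interact. Decoys are placed the same way at threshold
+ 0.2 Å — the sharpest false-positive probe the criterion admits. The PDB
and mmCIF renderings carry identical coordinates, and generation is
byte-deterministic per spec. `random_fixture_spec()` draws 2–4 planted
modifications across the full starter chemistry plus 0–2 decoys.

The fixtures emulate exactly what the method consults: component codes,
polymer membership, atom names, and inter-atomic distances. They do *not*
emulate real stereochemistry, crystal packing, disorder, missing atoms, or
B-factor-dependent coordinate error. Passing the planted-truth suite
therefore demonstrates that the identification logic is correct given
coordinates; it does not measure recall on real entries, where missing
side-chain atoms (which correctly fail to match — no imputation is
attempted) and unusual naming are the practical failure modes.

Problem sizes used by the tests and acceptance script — 100 seeded
fixtures, 100 random 200-atom clouds for the oracle-equivalence check, ~20
cross-link arrangements — were chosen as the smallest sets that exercise
every definition and both search paths while keeping a full run in the
order of a minute.

## Known limitations

* The dictionary is a representative starter set, not the full curated
  catalogue of 400+ modifications; archive-scale scan counts depend on
  dictionary completeness.
* Attachment records are per bonded pair; consumers wanting one record per
  coordination shell must group by non-polymer group id.
* No bond-order perception, angle checks, or energy criteria: a single
  distance threshold is the entire bond model, as intended.
* Nucleic-acid modifications are out of scope; components on nucleic-acid
  chains are simply never matched as amino-acid components.
* Symmetry/assembly expansion is not performed; bonds across crystal
  contacts of unexpanded copies are invisible.
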