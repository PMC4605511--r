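---
title: "Surveying peptide palindromes in protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying peptide palindromes in protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propalin)
```

## The problem

A peptide palindrome (PALIN) is a contiguous stretch of protein sequence
that reads identically in both directions at the character level —
`QKAKQ`, `VGFFGV`, `GDNPRPNDG`. Unlike DNA palindromes there is no
complementation involved. Pentapeptide and larger palindromes are common
in globular proteins, and the interesting questions are structural: do
they prefer a secondary-structure conformation, are they buried or
exposed, how densely are they packed against the rest of the protein,
and do they sit near functional sites? `propalin` implements the full
survey pipeline that answers those questions for any set of protein
chains in PDB format, together with a synthetic-structure generator that
makes every stage testable without network access.

## Detection model

For each chain the scanner derives a one-letter sequence from the
ATOM-record polymer residues (not SEQRES), so every reported position has
coordinates. The classical search takes each window as a *probe*,
inverts it into a *target*, and slides the target along the sequence; a
window whose inversion matches at its own position is a palindrome. The
package enumerates self-palindromic windows directly — provably
equivalent to the probe/target search once probe/target duplicates are
collapsed, which a dedicated oracle test verifies on a thousand random
sequences. Three exclusion filters follow:

* **CARPs** — continuous single-amino-acid repeats (`AAAAA`). We use the
  strictest reading: a window is a CARP only when *all* residues are
  identical; two-letter repeats such as `ALALA` are genuine palindromes
  and are kept.
* **Missing atoms** — windows containing a residue whose expected heavy
  atoms (per the standard chemical component definitions, hydrogens
  ignored) are not all present are removed, because their structural
  annotations would be unreliable.
* **Nonstandard residues** — anything mapping to `X` (MSE, PTR, ...) can
  never be inside a palindrome: `X` is an unknown, and an unknown is
  never equal to itself. This is conservative and deliberate.

All co-centered sub-palindromes are reported by default (every
odd-length palindrome of length `L >= 7` contains one of length `L - 2`
about the same center); `scan_config(maximal_only = TRUE)` keeps only
windows not contained in a longer palindromic window, for analyses that
want one hit per locus.

Scan lengths default to 5–9 residues. Pentapeptides dominate real
surveys, and beyond nine residues hits become vanishingly rare; both
bounds are configurable.

## Structural annotations

**Secondary structure.** Residue states are assigned from backbone
hydrogen bonding following the Kabsch–Sander scheme: the amide hydrogen
is placed 1.0 Å from N opposite the preceding carbonyl, the bond energy

$$E = 0.084 \left( \frac{1}{d_{ON}} + \frac{1}{d_{CH}} -
\frac{1}{d_{OH}} - \frac{1}{d_{CN}} \right) \cdot 332 \;
\text{kcal/mol}$$

defines a hydrogen bond when $E < -0.5$, and n-turn and bridge patterns
yield `H`/`G`/`I` helices, `E`/`B` strands, `T` turns, `S` bends
(CA virtual-bond angle above 70°), `C` otherwise, and `-` for residues
without backbone coordinates. Hydrogen bonds are evaluated across *all*
chains in the file, so inter-chain sheets are found. When a precomputed
DSSP file is supplied (`dssp_dir`), its codes take precedence. The test
suite cross-checks the assigner against an independent DSSP
implementation (mdtraj, via Python) on ideal helix and sheet fixtures
and requires exact agreement on helix/strand cores.

A whole palindrome is then categorised. The survey convention is that
*coil* means entirely `C`, while helix and strand are the dominant
state; we operationalise "dominant" as a strict majority (> 50%) of `H`
(respectively `E`). Whether `G` counts toward helix, `B` toward strand,
and the majority fraction itself are parameters of `ss_rule()`, because
the category boundaries are a genuine judgement call and moving them
shifts the helix/strand/irregular split.

**Solvent accessibility.** Per-residue SASA is computed by Shrake–Rupley
sphere sampling: each heavy atom's solvent sphere (van der Waals radius
plus a 1.4 Å water probe) is covered with a deterministic golden-spiral
lattice of 960 points and the unoccluded fraction scaled to the sphere
area. Radii default to C 1.70, N 1.55, O 1.52, S 1.80 Å; unknown
elements fall back to 1.7 Å with a warning. The occlusion context is all
chains plus het groups; crystallographic waters are excluded by default
because retained waters would bury surfaces inconsistently across
entries (both switches are exposed). A palindrome's value is the mean of
its residues' values. A lone carbon atom reproduces the analytic sphere
$4\pi(1.7+1.4)^2 \approx 120.76$ Å² to within quadrature error, total
SASA is rotation-invariant to 0.1%, and quadrupling the point count
moves totals by under 1%.

**Neighborhood contacts.** The structure is split into the palindrome's
atoms (target) and all other polymer atoms of all chains (source). A
source residue is counted once — regardless of how many of its atoms
qualify — if any heavy atom lies within 3.2 Å of any palindrome atom.
Hydrogens are excluded; het groups are excluded from the count by
default (`include_het` reverses this) because they are scored separately
as functional interactions.

**Functional interactions.** Four independent flags: *ligand* (a
non-water, non-metal het atom within 3.9 Å), *metal* (likewise for metal
elements), *site/catalytic* (a palindrome residue is listed in a PDB
SITE record or a user-supplied catalytic-residue table, or contacts such
a residue within the cutoff), and *disulphide* (a palindrome cysteine SG
within 2.3 Å of another SG). The 3.9 Å default is a typical
protein–ligand contact threshold; it is configurable because annotation
databases do not all use the same distance.

## Sequence properties and classification

Average hydropathy uses the Kyte–Doolittle scale (I 4.5 ... R −4.5),
unweighted mean over the window — necessarily symmetric under reversal,
and bounded by [−4.5, 4.5]. Position frequency matrices (20 × L counts)
drive consensus calls (per-column argmax, lexicographic ties) and
logo-ready FASTA exports grouped by length and category; for any
palindrome-only input, column *i* of the PFM equals column *L*+1−*i*
exactly, which the tests verify by recount.

Occurrence modes are computed pairwise within a chain: *nested*
(interval containment), *overlapping* (intersection without
containment), *consecutive* (exact adjacency — the window ending at
author residue *r* followed by one starting at *r*+1), and *repeated*
(identical sequence at distinct intervals). *Chameleons* are identical
sequences observed with different categories in different structures.
Family aggregation uses the PDB HEADER classification string, with
unlabelled entries binned as `UNCLASSIFIED`.

## Matched controls

To ask whether palindromes behave differently from arbitrary peptides,
the pipeline draws one non-palindromic window of identical length per
hit, uniformly at random (with replacement) over all valid placements in
the same chain set — passing the same completeness filter and never
coinciding positionally with a hit. Sampling is governed by a single
integer seed, so reruns are byte-identical. Uniform-over-placements was
chosen over uniform-over-chains so that long chains contribute controls
in proportion to the windows they actually offer.

## The synthetic-data generator

Two generators make the pipeline testable end to end without downloads:

* `generate_sequence_with_palindromes()` draws a background sequence
  from configurable residue frequencies (uniform by default) and
  overwrites planted palindromic windows at stated positions, recording
  the truth intervals. Accidental background palindromes are permitted
  and reported by a post-scan, so recovery tests can separate planted
  truth from chance. Under a uniform background the expected number of
  palindromic windows of length $L$ per chain is
  $(n - L + 1)\,(1/20)^{\lfloor L/2 \rfloor}$; the suite checks the
  simulated mean against this closed form.
* `build_ideal_peptide()` places backbone atoms (N, CA, C, O, and CB for
  non-glycine) by sequential internal-coordinate construction with
  standard bond geometry (N–CA 1.458, CA–C 1.525, C–N 1.329 Å, ω =
  180°) at requested φ/ψ — helix (−57°, −47°) or strand (−139°, 135°)
  presets — and writes valid PDB files. Recomputed dihedrals match the
  request to well under 0.1°. `build_antiparallel_sheet()` adds a
  180°-flipped second strand placed by a deterministic optimisation that
  drives the paired inter-strand O···N distances to 2.9 Å and the
  amide-H···O distances to 1.9 Å — a purely geometric criterion,
  independent of the secondary-structure assigner it is used to test.
  Het decoys (e.g. a zinc ion) can be appended to exercise the
  interaction flags.

What the fixtures do *not* emulate: side chains beyond CB, realistic
packing density, crystallographic disorder, waters, or the residue
composition of real proteins. Passing tests therefore demonstrate
algorithmic correctness — exact window arithmetic, the counted-once
rule, quadrature accuracy, hydrogen-bond pattern detection on ideal
geometry — not that any particular biological census is reproduced.
Survey-scale statements (hit totals, category percentages, SASA and
contact ranges) depend on the input chain set and are reported by the
pipeline rather than asserted by the tests. Because the ideal-geometry
fixtures only carry full side chains for alanine and glycine, the
structure-level test surveys use A/G-rich chains so that the
missing-atom filter, which is honest about the generated atoms, does not
empty the hit list.

## Numerical and policy choices

* Sequences derive from ATOM records; SEQRES is parsed only to report
  observed status. All annotations are structural, so a palindrome must
  have coordinates.
* Alternate locations: highest occupancy wins, ties go to altloc `A` or
  first encountered. Multi-model files: first model only (the survey
  targets crystal structures).
* Modified polymer residues deposited as HETATM (MSE, SEP, ...) stay in
  the chain and map to `X`; true het groups are separated, waters
  flagged.
* Author residue numbering with insertion codes is preserved verbatim;
  outputs use 1-based inclusive intervals ("167–171" style), internal
  indices are 0-based half-open.
* Output tables are UTF-8 TSV; FASTA wraps at 60 columns.
* Degenerate inputs: chains shorter than the minimum window return empty
  hit tables; chains under 3 residues get no regular secondary
  structure; collinear superposition inputs warn but return a solution;
  glycine positions have no side-chain divergence value.

Test problem sizes were chosen to finish in minutes on one CPU: 1,000
sequences for the oracle-equivalence check, 1,000 planted-recovery
trials, 1,500 chains for the background-rate calibration, and 3–6 entry
synthetic surveys for the end-to-end invariants.

## A worked example

```{r example, eval = FALSE}
dir <- tempfile(); dir.create(dir)
freqs <- setNames(rep(0, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
freqs["A"] <- 0.6; freqs["G"] <- 0.4
g <- generate_sequence_with_palindromes(
  35, planted = list(list(sequence = "GAAAG", position = 6)),
  residue_frequencies = freqs, seed = 301)
m <- build_ideal_peptide(g$chain$sequence, "helix", pdb_id = "SV01")
write_pdb(m, file.path(dir, "sv01.pdb"))

res <- run_pipeline(pipeline_config(pdb_dir = dir, seed = 17))
res$hits[, c("sequence", "start_resno", "end_resno", "ss_category",
             "avg_sasa", "n_contacts", "avg_hydropathy")]
res$summary$ss_composition_hits
```

## Limitations

* The built-in assigner follows the Kabsch–Sander patterns but is not a
  bug-for-bug DSSP replica (no β-bulge extension, no pi-helix
  preference); supply DSSP files for published-grade assignments on real
  structures.
* Shrake–Rupley with 960 points carries ~1% quadrature error; the radii
  set is explicit because published SASA values depend on it.
* The inverted-pair search (the same pentapeptide appearing elsewhere
  *reversed*, at a different locus) is out of scope: a hit here is a
  window that is its own inversion.
* mmCIF input, assembly/symmetry expansion, and live annotation-database
  queries are not supported; SITE records and user tables stand in for
  the latter.
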