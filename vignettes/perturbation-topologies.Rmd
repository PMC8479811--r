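---
title: "Building alchemical perturbation topologies with perttop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building alchemical perturbation topologies with perttop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perttop)
```

## The problem

Relative free-energy calculations transform one molecule into another along
an unphysical (alchemical) path. In the single-topology approach both end
states share one merged atom set: atoms present in both molecules keep one
set of coordinates and switch their force-field parameters with the coupling
parameter, and atoms present in only one state are retained as
noninteracting *dummy* particles in the other. Writing such a perturbation
topology by hand means deciding, atom by atom, which atoms correspond, which
become dummies, and which bonded terms change — a tedious and error-prone
step. `perttop` automates it: it computes a maximum common substructure
(MCS) of the input force-field topologies under the matching rules that
alchemical practice imposes, and serializes the result in GROMOS11 and
GROMACS dialects.

The match is computed on the *force-field topology*, not on chemical
structure: two atoms "agree" when their types, masses, charges and incident
bonded-term parameters agree numerically. No aromaticity or stereochemistry
perception is involved — if the parameters differ, the pair is a
perturbation, whatever the chemistry says.

## The search

The engine is an iterative branch-and-bound enumeration over atom-match
tuples (one entry per state; `NA` marks an explicit dummy match):

1. The seed candidates are all cross-state atom pairs (*n × m* for two
   states; anchored on the first state for more).
2. Candidates for growing a partial solution are drawn from the first
   neighbours of the already-matched atoms in every state, plus the dummy
   option, and are sorted so that extensions estimated to lead to
   low-penalty completions are tried first.
3. Adding a tuple updates the penalty bookkeeping: atom-level mismatches of
   the new tuple, and every bonded term whose atoms have all been assigned,
   compared against its image in each other state. A term with no image is
   *created/removed*, which is allowed only for non-bond terms and only on
   request. Bonds are never created or removed: a candidate that would make
   a bond exist in one state but not another is not generated.
4. A solution is complete when every atom of every state is in the solution;
   remaining unmatched atoms are paired with dummies at that point.

Pruning uses an admissible bound: the penalty accumulated so far plus the
minimal number of dummy matches any completion must still add. That minimum
exploits two structural facts — every future search tuple carries a real
atom of the anchor state, and each leftover atom ends in a single-atom row
with one dummy entry per remaining state. The bound never exceeds the score
of any completion, so pruning cannot remove an optimal solution; the test
suite verifies both the bound's admissibility and that disabling pruning
leaves every best score unchanged, and cross-checks the engine against
exhaustive enumeration on all small fixture pairs and dozens of random
attributed graphs.

Because subgraph matching is exponential in the worst case, a node-expansion
budget (default 500,000 expansions) aborts with a diagnostic rather than
running unbounded. Multistate searches are noticeably slower than pairwise
ones; they are intended for small sets of closely related compounds, not
for screening libraries.

### Scoring

Every individual perturbation contributes a weighted penalty: dummy match,
atom-type / mass / charge mismatch, perturbed bond / angle / proper /
improper dihedral, dihedral-multiplicity change, and created/removed term.
Weights live in `score_spec()`; categories listed in `forbid` are
infinitely penalised. The default — dummy weight 1000, all mismatch weights
1 — maximises the number of matched atoms with matched parameters as the
secondary criterion. With the default weights, solutions are compared on the
exact lexicographic pair (dummy count, weighted mismatch) rather than one
float, so weight magnitudes cannot cause round-off artifacts; custom weights
or a `custom_score` function switch to plain numeric comparison. Parameter
equality is decided on resolved numeric values (relative tolerance 1e-9;
charges, absolute 1e-6 e), never on parameter labels, so identical physics
under different type codes is not a perturbation.

Numerical choices worth knowing: masses and parameter values use relative
tolerance because force constants span orders of magnitude; charges use an
absolute tolerance matched to printed file precision; candidate and solution
orderings break ties by atom index, making every search deterministic and
repeated runs byte-identical.

### Ring policies

Partial ring matches would let an alchemical transformation open or close a
ring, which distorts end-state sampling. The default policy
(`complete_individual_rings`) therefore allows partial matches of polycyclic
systems only ring-by-ring: each individual ring is matched completely or not
at all, fused neighbours may remain unmatched (their shared-edge atoms are
excused), bridged pairs match as a unit, and spiro rings are independent.
The stricter `complete_only` forbids partial polycyclic matches entirely.
Ring-to-nonring matches are budgeted: at most two atoms sharing a bond
(default), one atom, or none; the same budget governs ring-to-ring matches
for which no complete or fused-partial correspondence exists. Ring systems
are perceived as a smallest set of smallest rings with deterministic
lexicographic tie-breaking, capped at 12-membered rings — macrocycles are
treated as acyclic for matching purposes, which is a deliberate scope limit.
With three or more mutually fused rings the pairwise rule is applied
transitively (each ring all-or-nothing, shared edges counted once); this is
an extrapolation of the two-ring rule and is the package's own choice.

### Dihedrals, multiplicity, created/removed terms

Two pairing procedures are provided. `all_four_atoms` pairs a dihedral only
with the dihedral on exactly its four mapped atoms — appropriate when
dihedrals are generated exhaustively from connectivity. `middle_two_atoms`
groups dihedrals by their mapped central bond and pairs them within the
group, preferring equal multiplicities — appropriate when one dihedral is
defined per rotatable bond. In the grouped procedure, dihedrals with no
equal-multiplicity partner are classified as created/removed (allowed only
with `allow_make_break_bonded`), unless `allow_multiplicity_change` permits
pairing them with a multiplicity penalty; the within-group pairing order is
fixed by sorting on (multiplicity, parameter values) for determinism. The
pairing is only decided once a solution is complete, so the incremental
bookkeeping defers dihedral accounting to completion under this procedure.

The combination of these switches selects between qualitatively different
pathways for the same pair of molecules. For the lysine→acetyllysine
fixtures, permissive settings (central-bond pairing or multiplicity changes,
plus term removal) transform a hydrogen directly into the acetyl carbon;
with restrictive settings the acetyl group grows from dummies instead, and
the dummy audit then reports the acetyl carbon's five bonded interactions
with the unperturbed region, two of them redundant.

### Tie-breaking by coordinates

Symmetric molecules produce families of equal-score solutions (the
trimethylation example has 3! = 6). Given one coordinate set per state,
`select_best()` ranks equal scores by the RMSD over matched atoms, computed
on the coordinates exactly as provided — no least-squares fit, because for
ligands posed in a binding pocket the pose *is* the information. For N > 2
states the spread is the root mean square of pairwise RMSDs, or equivalently
the RMSF around the mean structure; over the same atoms the two are related
by ⟨RMSD²⟩ = 2N/(N−1)·⟨RMSF²⟩, a constant fixed analytically from the
identity Σ<sub>s&lt;t</sub>|x<sub>s</sub>−x<sub>t</sub>|² =
N·Σ<sub>s</sub>|x<sub>s</sub>−x̄|² and verified numerically to 1e-10 in the
tests.

## Dummy atoms and the anchoring audit

Union atoms missing from one state get the configurable noninteracting type
(default `"DUM"`), zero charge, and their real-state mass in the dummy
state; bonded terms entirely inside a dummy region keep their real-state
parameters in both states so the dummy geometry stays defined; dummy atoms
inherit the exclusion list of their real state. A dummy should be attached
to the unperturbed atoms by three nonredundant bonded terms (one bond, one
angle, one dihedral-type term positioning it); `audit_dummies()` counts, for
each dummy, the bonded terms joining it to otherwise non-dummy atoms and
flags counts above three as redundant and counts of one or two as
under-anchored. Removal of redundant terms is ambiguous and is deliberately
*not* automated — the audit warns and leaves curation to the user. Atoms
anchored purely through other dummies (count zero) are positioned by the
dummy-region terms and are not flagged.

## Multistate searches, EDS topologies and cycles

`multistate_search()` matches all states simultaneously; the result is the
minimum structure of which each compound is a substructure — a common
scaffold. By default it forbids every bonded-term perturbation (only atom
types, charges and masses may switch), the setting aimed at
enveloping-distribution-sampling reference topologies;
`build_eds_topology()` then produces one union topology whose restriction to
any state reproduces that state's input exactly, and
`pairwise_from_multistate()` extracts all N(N−1)/2 pairwise perturbation
topologies, mutually consistent by construction so the cycle of mappings
composes to the identity. Multistate seeding is anchored on the first
state: every searched tuple carries a real atom of state 1, and atoms of
other states without a state-1 partner become dummies. Tuples real only in
two non-anchor states are therefore not formed; for closely related
congeneric series this costs nothing, and it is what makes the search and
its pruning bound tractable. If the forbids exclude every cross-state match,
an explicit no-solution object is returned rather than an empty mapping.

## File formats

GROMOS11 solute topologies are read and written in block format
(TITLE/ATOMTYPENAME/SOLUTEATOM/BOND(H)/BONDANGLE(H)/DIHEDRAL(H)/
IMPDIHEDRAL(H) with the *TYPE parameter blocks); solvent blocks are ignored
— perturbation concerns the solute. GROMACS topologies are preprocessed
textually (`#include` inlined, `#define` macros substituted; unresolved
includes are an error), and only the first moleculetype is read. Atom
indices are 1-based on disk and in memory. Parameters are carried
numerically between dialects without functional-form conversion.
Perturbation output uses dual A/B columns in GROMACS
(`[ atoms ]` rows with typeB/chargeB/massB, A- and B-state parameters on
each bonded line) and a reference topology plus
PERTATOMPARAM/PERTBONDSTRETCH/PERTBONDANGLE/PERTPROPERDIH/PERTIMPROPERDIH
blocks in GROMOS, with inline numeric parameters and type names so the files
are self-contained; terms absent in one state are written with a zero force
constant there, and that convention round-trips. EDS output is an MPERTATOM
multistate block (GROMOS) or one full per-state topology sharing the union
atom list (GROMACS). Per-state exclusion lists merge on output. Only
topology content is emitted — soft-core settings and other simulation input
are out of scope, not least because the two engines define soft-core
potentials differently.

## The toy systems and what the tests do (and do not) show

`make_fixture()` builds deterministic united-atom toys: methanol/ethane, the
lysine side chain with its trimethylated and acetylated forms, alkanes and
methylated cyclohexanes, fused/bridged/spiro polycycles, and a
halogen-substituted congeneric ligand series, each with a deterministic
coordinate set. Their force-field constants are invented but internally
consistent — shared types are shared across molecules (the N–H bond type is
identical in the amine and amide forms, which is what lets the amide
hydrogen be matched), and every expectation about them in the tests is
computed by an oracle, not copied from a real parameter set. The fixtures
exercise the matching rules, not force-field realism: passing tests show the
search, scoring, policies, serialization and audits are correct on
topologies of this size and kind, and say nothing about the thermodynamic
quality of any particular pathway, which only simulation can judge. Problem
sizes were chosen so the full suite — including exhaustive-enumeration
cross-checks on every pair of small fixtures and on dozens of random
attributed graphs of up to seven atoms — runs in a few minutes on one CPU.

## Known limitations

* No chirality/stereochemistry checks; matching is purely graph- and
  parameter-based.
* Macrocycles (>12-membered rings) are treated as acyclic for the ring
  policies.
* Multistate matching is anchored on the first input state (see above).
* Redundant dummy-anchoring terms are detected and reported, never removed.
* No force-field assignment: inputs must already be parameterized; no
  solvent, box, or restraint handling; no simulation input generation.
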