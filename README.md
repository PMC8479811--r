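# perttop

Automated alchemical perturbation-topology builder for relative free-energy
calculations.

Setting up a single-topology alchemical transformation — which atoms of
compound A become which atoms of compound B, which atoms vanish into
noninteracting dummies, and which force-field terms get perturbed — is the
error-prone manual step in front of every relative free-energy calculation.
`perttop` automates it for people who run such calculations with GROMOS or
GROMACS: it reads two (or more) force-field topologies, finds their maximum
common substructure (MCS) under chemically meaningful matching rules, and
writes ready-to-use perturbation topologies in either engine dialect.

## The method

The MCS search is an iterative branch-and-bound enumeration in the style of
the VF graph-matching algorithms. Starting from the full *n × m* list of
cross-state atom pairs, the current solution grows by one atom match per
step, candidates being drawn from the first neighbours of the atoms already
matched; matches to dummy atoms are explicit candidates. Each added match
updates a penalty score

> S = Σ<sub>c</sub> w<sub>c</sub> · n<sub>c</sub>,  c ∈ {dummy, atom type,
> mass, charge, bond, angle, proper dihedral, improper dihedral,
> multiplicity, created/removed term}

with user-defined weights w<sub>c</sub>; setting a category to "forbidden"
gives it infinite weight and excludes whole classes of pathways (e.g. *no
perturbed bonds*). The default maximises the number of matched atoms, with
matched atom types as the secondary criterion, compared exactly on a
lexicographic (dummy count, weighted mismatch) key. An admissible estimate
of the best score still reachable from a partial solution prunes branches
that can no longer beat the best enumerated solution, so pruning never
changes the result, only the runtime.

Matching is constrained by the rules relative free-energy practice
requires:

* bonds are never created or removed across the match;
* rings match completely or not at all — partial matches of fused polycyclic
  systems are allowed ring-by-ring, bridged systems match as a whole, spiro
  rings are independent;
* ring atoms may match non-ring atoms only within a small budget (two bonded
  atoms / one atom / none);
* dihedrals are paired either on all four atoms or on the central bond, with
  optional multiplicity perturbation and optional creation/removal of
  non-bond bonded terms (mainly improper dihedrals).

Equal-score solutions (symmetry!) can be ranked by the atom-positional RMSD
of the matched atoms over supplied coordinates — computed without
superposition, so ligand poses in a binding pocket are respected. For more
than two states the spread is ⟨RMSD²⟩<sup>1/2</sup> over state pairs or
equivalently ⟨RMSF²⟩<sup>1/2</sup> (they differ by the factor 2N/(N−1)).

A simultaneous search over three or more topologies yields a common
scaffold, used to build enveloping-distribution-sampling (EDS) reference
topologies (no bonded-term perturbations allowed, atom types switch per
state) and closed thermodynamic cycles of pairwise perturbation topologies.
Dummy-atom bonded connectivity is audited: a dummy should be anchored to the
unperturbed region by three nonredundant bonded terms; redundant or missing
anchors are reported with a warning, never removed silently.

## Worked example

Lysine side-chain trimethylation, using the built-in united-atom toy
systems (see `fixture_names()`):

```r
library(perttop)

lys <- make_fixture("lysine_side")
k3c <- make_fixture("trimethyllysine_side")

sols <- mcs_search(list(lys$top, k3c$top),
                   search_options(enumerate_all_best = TRUE))
length(sols)
#> [1] 6
```

Six solutions share the best score because the three amine hydrogens can be
assigned to the three N-methyl groups in any of 3! ways. Coordinates break
the tie:

```r
best <- select_best(sols, list(lys$coords, k3c$coords))
best
#> <match_solution: 2 states, 8 tuples (8 cross-state matches, 0 dummy entries)>
#>   score total: 18  breakdown: atom_type=4 mass=3 charge=5 bond=3 angle=3
tidy(best)
#> # A tibble: 8 × 4
#>   tuple state1_atom state2_atom status
#>   <int> <chr>       <chr>       <chr>
#> 1     1 C1          C1          unperturbed
#> 2     2 C2          C2          unperturbed
#> 3     3 C3          C3          unperturbed
#> 4     4 C4          C4          perturbed
#> 5     5 N           N           perturbed
#> 6     6 H1          M1          perturbed
#> 7     7 H2          M2          perturbed
#> 8     8 H3          M3          perturbed
```

All 16 atoms are matched (no dummies); each hydrogen→methyl match perturbs
the atom type, mass, charge and its N–H→N–CH3 bond and angle terms — that is
the `atom_type=4 mass=3 charge=5 bond=3 angle=3` breakdown (the nitrogen and
C4 change type/charge as well). Forbidding bond perturbations instead grows
the methyls from dummies:

```r
sol2 <- mcs_search(list(lys$top, k3c$top),
                   spec = score_spec(forbid = "bond"))[[1]]
pert <- build_pert_topology(sol2)
glance(pert)[, 1:5]
#> # A tibble: 1 × 5
#>   n_atoms n_dummy_a n_dummy_b n_perturbed n_unperturbed
#> 1      11         3         3           2             3
autoplot(pert)     # blue unperturbed / red perturbed / grey dummies
write_perturbation(pert, "lys_to_k3c", "gromacs")
```

From a shell, the same run is

```sh
inst/cli/perttop pair lysine.top k3c.top --dialect gromos --out pert
inst/cli/perttop multi lys.top k3c.top kac.top --eds --out eds
```

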