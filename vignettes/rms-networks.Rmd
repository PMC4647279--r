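---
title: "Reaction Molecular Signature networks: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction Molecular Signature networks: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rmsnet` classifies metabolic reactions by the chemical transformation
they perform and searches a reduced, transformation-level network for
conserved modules. This vignette is the package's own account of the
model: what is computed, which knobs matter, what the synthetic data
generator does and does not emulate, and where we made design calls
that another implementation could reasonably make differently.

## 1. From molecules to signatures

Molecules enter as SMILES or MDL Molfile V2000 records and are
**standardized**: implicit hydrogens become explicit atoms (a valence
table with charge adjustment: C 4, N 3±q, O 2±q, S {2,4,6}, P {3,5},
halogens 1), and rings of size 3–7 are tested with a simple
Hückel-style model — every ring atom must either take part in an
in-ring double bond or be a lone-pair donor (N, O, S without any double
bond), an exocyclic double bond disqualifies the ring, and the π count
must be 4k+2. Qualifying rings get aromatic atoms and bonds, so the
Kekulé variants of one ring map to a single graph. Standardization is
idempotent; the model name (`huckel-simple`) is recorded on the
molecule because every downstream string depends on it.

The **atomic signature** of height *h* rooted at an atom is a canonical
string of the induced ball of radius *h* (all atoms within *h* bonds
plus all bonds among them). Tokens are `[element]` with charge suffix
(`[O-]`, `[N+]`) and lowercase elements for aromatic atoms; bond
prefixes are nothing/`=`/`#`/`:`. Canonicalization rules:

* **Acyclic balls** (the overwhelmingly common case at h ≤ 2): child
  subtrees are emitted in the order that makes the concatenated branch
  string bytewise minimal — with at most four children this is an
  exhaustive minimum over ≤ 24 orderings per node, so the result is a
  true lexicographic minimum over all branch orderings, independent of
  atom input order.
* **Cyclic balls** (a 3–5 ring inside a height-2 ball): an atom
  reachable by two short paths appears once, and each extra edge
  becomes a SMILES-like ring-closure token `%n` attached after the
  atom token of both endpoints, numbered by first appearance. Because
  closure numbering couples the branches, the canonicalizer enumerates
  the DFS child orderings globally (with a step cap) and keeps the
  bytewise smallest complete string.

The **molecular signature** is the multiset of atomic signatures over
all atoms — counts always sum to the atom count, which the tests
assert, together with permutation invariance and exact agreement with
an independent brute-force canonicalizer on random molecules.

*Why heights 1 and 2?* Height 1 captures the reaction center — the
atoms whose bonding changes plus their immediate partners. Height 2
adds the chemical context that modulates reactivity. Beyond height 2
the strings become so specific that most describe a single reaction,
which defeats classification; the package warns above height 2 but
does not forbid it.

*Stereochemistry* is parsed but deliberately **not** encoded:
signatures are constitutional. Two reactions differing only in
stereochemistry of the periphery receive one class. An extension hook
(a different atom-token function) is the natural place for a stereo
layer.

## 2. Reaction signatures and classification

The raw RMS of a balanced reaction at height *h* is the signed multiset
*products − substrates* of molecular signatures, weighted by
stoichiometry. Atoms whose environment is unchanged cancel; what
remains is the transformation itself. Three reaction classes never get
signatures and are reported with reasons instead: transport reactions
(the translocated substrate is unchanged), reactions with a missing or
unbalanced equation, and chemically null transformations (empty
difference at the height in question). Exclusion, not pooling, keeps
the classes chemically meaningful.

Serialization is fixed — entries `±count:signature`, bytewise-sorted,
joined by `|` — so edit distances are reproducible run to run. To merge
the two directions of one transformation, the serialization is compared
with that of the negated multiset and the smaller string becomes the
key; the orientation flag records which direction was kept. A non-empty
signed multiset can never equal its own negation, so the merge is
always well defined.

Height-1 classes are exact key-equality groups. Height-2 sub-classes
are built *inside* each height-1 class: members' height-2
serializations (negated first for members whose height-1 orientation
was `reversed`, so the two directions stay aligned) are compared with
plain Levenshtein distance, clustered with Ward linkage
(`hclust(method = "ward.D")`), and the tree is cut at a **cophenetic
threshold of 90** (raw edit-distance scale). The threshold's unit is
worth stating because Ward merge heights grow with cluster sizes: two
groups of identical strings at raw distance *d* merge at a height of
roughly *d* times the group size, so sizeable sub-groups separate well
below a raw distance of 90. The threshold and linkage are exposed
(`h2_threshold`, `h2_linkage`); a cut at 0.5 degenerates to "split
exactly the groups of identical strings", which the tests use to pin
down the generator's planted heterogeneity deterministically.

## 3. Network reduction and transition probabilities

The reaction network has one node per pathway-member, non-transport
reaction and one directed edge per ordered pair linked by a *main
compound* — a metabolite a pathway declares biologically relevant to
both reactions (this is what keeps ATP, water and friends from turning
the graph into a hairball; it is also why only pathway members appear:
only they distinguish main compounds from co-substrates). Links whose
compound fails the product/substrate check are skipped with a warning;
links citing unknown reactions are an error.

Reduction merges the reactions of one class into one node. An RMS edge
i→j (i ≠ j) exists when at least one reaction edge crosses the classes;
its transition probability is

> Pr(RMS_j | RMS_i) = (# reaction edges from class-i members to class-j members) / (# outgoing reaction edges from class-i members).

Two choices deserve a note. *Self-loops are avoided*: consecutive
same-class reactions produce no RMS edge. *The denominator includes the
within-class edges anyway*, so each node's outgoing probabilities sum
to 1 minus its within-class fraction — the row deficit is exactly the
self-loop mass. The alternative (excluding within-class edges from the
denominator) would renormalize rows to 1; we kept the total-outgoing
denominator because the worked probability example counts all five
outgoing edges of a class. Tests assert the conservation identity
(crossing + within = total) and the per-node deficit exactly.

A reaction used in both directions by different pathways contributes
edges in both directions; edge multiplicity is deduplicated at the
level of ordered reaction pairs, with all supporting (pathway, main
compound) pairs recorded on the edge.

## 4. Node weights

* `wRea` — the number of classified reactions in the class, counting
  reactions that never entered the pathway network. It measures how
  many distinct substrate contexts the transformation is known in.
* `wPageRank` — PageRank (damping 0.85) on the unweighted RMS digraph,
  dangling mass redistributed uniformly. The solver is igraph's exact
  PRPACK; the `pagerank_tol` parameter therefore validates the
  probability sum rather than stopping an iteration. The hypothesis
  being encoded: important transformations accumulate incoming links
  from other transformations.
* `wProt` — enzyme diversity. Proteins are grouped by exact multiset
  equality of their domain composition. For composition Dom_j and
  class RMS_i with N_joint shared proteins, d2r = N_joint/N_dom and
  r2d = N_joint/N_rms; the association score is their harmonic mean —
  a sensitivity/specificity compromise that is small whenever either
  side is promiscuous. The class weight is the geometric mean of
  N_dom × score over the compositions with N_joint ≥ 1. The scale is
  deliberately hybrid (a count times a ratio, kept as defined); only
  comparisons between paths of the same kind are meaningful. Classes
  with no known protein are **orphan enzyme activities**: their weight
  is undefined (`NA`), never zero, and the undefinedness propagates
  into any path score that would use it as a factor.

## 5. Paths, PCI and conserved modules

All loop-free directed paths of 1–4 edges are enumerated by
depth-first search with bytewise-sorted neighbor exploration, which
makes the emission order deterministic (lexicographic in the node
sequence); a node-count cap guards combinatorial blow-up, and the
enumeration is tested for exact set equality against a brute-force
oracle. Known pathways are translated into overlapping windows of the
same lengths (windows touching an unclassified reaction, or mapping two
consecutive reactions to one class, are dropped — the latter mirrors
the self-loop exclusion).

The **PCI** of an RMS path is the number of *distinct reaction paths*
realizing it that are contiguous within a single known pathway; one
reaction path appearing in several pathways counts once. A relaxed
per-edge rule (each consecutive pair supported by some pathway, not
necessarily the same one) is available as `support = "edge"`; the
strict single-pathway rule is the default because a module should be a
fragment some pathway actually traverses. Paths with PCI ≥ 2 — the same
chemistry realized by at least two different reaction sequences — are
conserved chemical transformation modules.

Path scores multiply, over the path's *factor nodes* (all but the
terminal), the node weight by the transition probability to the next
node, then take the (edge-count)-th root. The terminal node's weight is
not a factor — the formula is implemented exactly as defined, with the
closed-form consequences the tests pin down (a 2-node path with weight
4 and probability ½ scores 2; a 3-node path with weights 4, 9 and
probabilities ½, ½ scores 3). A consequence worth knowing: `scoreProt`
is undefined iff an orphan class occurs among the factor nodes; an
orphan *terminal* leaves the score defined.

## 6. What the synthetic generator emulates — and what it does not

`generate_fixture()` builds the package's study conditions from a seed:

* **Families** (default 6) of valence-correct molecules sharing head
  chemistry but differing in tail length (3–8 carbons). Tails of at
  least 3 carbons make the height-2 ball of the reaction center
  identical across families, so planted height-1 classes are exactly
  uniform.
* A **planted three-step module** — alcohol → aldehyde → imine → amine,
  with H₂/NH₃/H₂O bookkeeping keeping every equation balanced by
  construction — applied to every family as one pathway (types cycle
  through Biosynthesis/Degradation/Energy). Each window of the module
  is therefore realized once per family: expected PCI equals the family
  count.
* **Decorated tails** (default: half the families, seed-chosen) carry a
  2-hydroxyisopropyl branch on the attachment carbon: invisible at
  height 1 (the branch sits two bonds from every changed atom) but
  visible at height 2, planting genuine sub-class heterogeneity.
* **Background chains** (default: up to 3 families, one distinct chain
  each) add a feeder reaction producing a planted intermediate (ester
  hydrolysis, amine oxidation, gem-diol dehydration) and a dangler
  consuming one (acid formation, formamide formation, nitrile
  formation). Used once each, their windows have PCI 1 and can never
  be mistaken for modules; the feeders also give the planted classes
  the extra incoming links a chemical hub accumulates.
* **Proteins** per non-orphan operator with operator-specific domain
  compositions, plus a few promiscuous two-domain proteins shared
  between the first two operators (driving association scores below
  1); a configurable fraction of operators (feeders first) stay
  **orphan**, and one transport plus one null reaction exercise the
  exclusion paths. Operators carry plausible EC numbers, including one
  transformation annotated with different EC branches in different
  families and one multi-EC reaction, so the Rand-index comparison has
  realistic discordance.

What it does **not** emulate: cofactor chemistry (CoA thioesters,
NAD(P) pairs), stereochemistry, reversible-direction conflicts between
pathways, multi-substrate main-compound ambiguity, and the sheer scale
of a curated database (thousands of reactions, signature strings of
hundreds of characters). Passing tests on fixtures therefore show the
machinery is correct under controlled conditions, not that any
particular biological database will yield a given module count.

Problem sizes were chosen so the full suite and the reproduction script
run in well under a minute each: 6 families ≈ 26 reactions ≈ 35
molecules, with signatures cached per compound and height.

## 7. Numerical and degenerate-input choices

* All string sorts use bytewise (`radix`) order — no locale
  dependence.
* Class ids (`H1.0007`, `H1.0007.2`) are assigned per run, in bytewise
  order of the serialized keys; they are stable for fixed inputs and
  parameters but are *labels*, not portable identifiers across
  datasets.
* `hclust` needs ≥ 2 items: singleton classes yield one sub-class
  directly; all-zero distance matrices short-circuit before
  clustering.
* Empty networks: reduction of an empty reaction network is an error
  for the node-reduction rate (undefined ratio); PageRank refuses an
  empty graph; path enumeration of an empty graph returns an empty
  table.
* Molfile output writes formal charges as `M  CHG` properties and
  aromatic bonds as type 4; the reader accepts both `M  CHG` and the
  legacy atom-line charge codes.
* The pipeline's provenance log stores parameters and input digests so
  that reruns can be compared file-by-file; rerunning with identical
  inputs and configuration is byte-identical, which the tests assert.

## 8. Known limitations

* The aromaticity model is intentionally simple; fused polycyclic
  aromatics and exotic tautomers may standardize differently than a
  full perception toolkit would. Since signature strings depend on the
  model, classifications are comparable only within one model.
* Signature strings are canonical *for this package's dialect*; they
  will not match byte-for-byte the output of other signature
  implementations, and class ids are not portable identifiers. All
  downstream logic depends only on string equality and distances
  within one run, so this is self-consistent.
* Levenshtein distance on serialized multisets is sensitive to entry
  count: two large RMS differing in a single entry are "closer" than
  two small ones differing in the same way, relative to string length.
  The cophenetic threshold is an absolute distance, so very large
  reaction centers cluster more readily — same behavior as the original
  formulation, but worth keeping in mind when tuning `h2_threshold`.
* PCI counts support only through declared pathway links; conserved
  chemistry spanning pathway boundaries is visible to the relaxed
  per-edge rule but not to the strict default.
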