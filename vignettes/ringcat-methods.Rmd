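---
title: "ringcat: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ringcat: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringcat)
```

## The detection model

RING finger domains are zinc-binding domains of roughly 40–110 residues in
which eight metal-ligand residues (cysteines and histidines, with a few
tolerated substitutions) coordinate two zinc ions. The canonical spacing is

```
C -x2- C -x(9–39)- C -x(1–3)- [4] -x(t)- [5] -x2- C -x(4–48)- C -x2- C
```

where positions 4 and 5 carry the type identity: RING-H2 = (H,H),
RING-HC = (H,C), RING-v = (C,H), RING-C2 = (C,C), RING-D = (H,D),
RING-S/T = (H, S-or-T), RING-G = (H,G), and the spacer `x(t)` between
ligands 4 and 5 is type specific: 2–3 residues for RING-H2, RING-HC, RING-D
and RING-S/T, 4–5 for RING-C2 and exactly 7 for RING-v. Everything is
declarative: `load_type_table()` reads a YAML description of the seven types
(shipped at `inst/extdata/ring_types.yaml`), and the scanner, the simulator
and the alignment machinery are all driven by that table. Detection is
purely geometric — no profile or HMM scoring — which is the point: the
*central core*, ligand 3 through ligand 6, spans 9–16 residues in every
allowed spacer combination and is diagnostic of the type on its own
(`central_core_span_bounds()` returns `(9, 16)` analytically, and the
longest pattern needed across the variable region from ligand 3 to ligand 5
is 13 residues, attained only by RING-v).

`scan_protein()` anchors on the central core and extends outward: ligand 2
is sought 9–39 residues upstream of ligand 3 with ligand 1 two residues
before it, and ligands 7–8 are sought 4–48 and then 2 residues downstream of
ligand 6. Hits that cannot place a boundary pair are dropped by default
(`allow_partial = FALSE`), mirroring the practice of excluding proteins
lacking boundary metal ligands; enabling partial hits marks them instead.

Two relaxations exist, both opt-out and both flagged on the hit:

* **Boundary substitutions** (`boundary_substitution` flag): slots 1, 2, 7
  and 8 tolerate H or D, admitting family-level deviations such as an
  eighth-ligand C→D or C→H. The tolerated universe is restricted to
  {H, D, S, T, G} by validation.
* **Spacer extensions** (`extended_spacer_4` / `extended_spacer_7` flags):
  +1 residue after ligand 4 and +2 after ligand 7, the only length
  deviations reported at family level in surveyed repertoires. All other
  spacers carry no allowance.

Coordinates are 0-based half-open internally; `hits_report()` converts to
1-based inclusive at the user boundary. `X` and other non-standard letters
never satisfy a ligand slot but count as spacer residues.

Overlapping candidate placements are resolved deterministically
(`resolve_overlaps()`): fewer deviation flags, then non-partial, then higher
type priority, then smaller span, then leftmost. The priority order follows
the types' abundance in real repertoires (H2, HC, v, C2, D, S/T, G). Because
the slot-4/5 identities are mutually exclusive across types, same-placement
type ambiguity cannot arise without tolerated substitutions; the tie-break
chain mostly arbitrates alternative boundary placements, where the
smaller-span rule keeps the most compact domain.

`brute_force_oracle()` is a second, independent code path — exhaustive
enumeration of all 8-tuples from per-slot match sets, joined left to right —
kept for verification: the test-suite asserts exact equality of both paths,
pre- and post-resolution, on seeded random corpora (uniform and C/H-enriched
residue draws, the latter because uniform 150-residue sequences rarely
contain valid cores) and on all planted/decoy corpora.

## Families versus lone genes

Relatedness is deliberately measured *outside* the RING domain: detected
domains are masked (`mask_ring()`, mask character `X` scoring zero against
everything), and every pair is aligned locally (Smith–Waterman semantics via
`Biostrings::pairwiseAlignment`, BLOSUM62, affine gaps open 11 / extend 1).
Scores are normalized by the self-score of the shorter sequence, so
identical sequences score 1.0 and the measure does not depend on database
size the way E-values do. An edge requires a normalized score of at least
0.3 (the `threshold` parameter; the original survey names BLAST but no
cutoff, so this is a package choice, exposed). Families are single-linkage
connected components — transitive membership, consistent with "putative
orthologs related by sequence" — and singletons are lone genes.

Groups are named systematically: families `FHH`/`FHC`/`Fv`/`FCC`/`FD`/
`FS-T`/`FG` by the modal RING type of their members' hits plus a two-digit
ordinal in decreasing-size order (ties by first member id); lone genes
`LHH`/`LHC`/`Lv`/`LCC` likewise. Legacy family names (ATL…UTL) are aliases
supplied via a mapping file, never inferred. Cross-species assignment
(`assign_to_reference()`) uses full-length, unmasked similarity, matching
the original protocol of reiterated searches with entire polypeptides;
queries below threshold are `novel`.

## RING-domain phylogenies

Because every complete hit shares the same eight-ligand architecture, a
heuristic multiple aligner is unnecessary: `anchor_align()` anchors the
eight ligand columns and right-pads each of the seven spacer regions with
gaps to its maximum observed length. This replaces a general-purpose MSA
deliberately; an externally produced alignment can be imported with
`read_alignment_fasta()` instead. `complete_deletion()` then removes every
column containing at least one gap (ligand columns are gap-free by
construction and always survive).

Distances are p (observed mismatch fraction), Poisson-corrected
(−ln(1−p)) or gamma-corrected (α[(1−p)^(−1/α) − 1], default α = 1); for
p ∈ (0,1) gamma ≥ Poisson ≥ p pointwise. Saturated pairs clamp to
`max_distance` (default 5) with a warning. Empirical substitution-matrix
models (Dayhoff/LG/JTT) used in the original analyses are not reimplemented;
the Poisson/gamma corrections are the documented stand-in, and maximum
likelihood trees are out of scope — only the neighbor-joining branch is
provided.

`ring_nj()` implements Saitou–Nei agglomeration with the standard
Q-criterion in-package rather than delegating, because the contract fixes
behaviour a library call does not expose: ties on Q break to the
lowest-index pair, and negative branch lengths clamp to zero with a warning,
so results are bit-reproducible. The reference implementation in `ape` is
used as an independent cross-check in the tests, together with the additive
oracle (for any additive matrix the generating topology and branch lengths
are recovered exactly). `ring_bootstrap()` resamples columns with
replacement, rebuilds the tree per replicate, and reports percentage support
per internal edge of the original tree; supports are seeded, reproducible,
and invariant to row order (rows are sorted internally before resampling).
`write_newick()` emits branch lengths, internal support labels and quotes
labels containing metacharacters; `ape::read.tree` round-trips the output.

## Gene structure

`parse_gff3()` (via `rtracklayer`) reduces each gene to one representative
transcript — the longest total CDS, ties by lexicographic transcript id;
the original survey does not state its choice. CDS intron count is the
number of CDS segments minus one. A 5'UTR intron is an intron lying
*entirely* upstream of the CDS start in transcript orientation; an intron
straddling the UTR/CDS junction counts as a CDS intron (the boundary case is
undefined in the source material, so the package fixes it this way and
tests it). When `five_prime_UTR` features are absent the UTR is inferred
from exon minus CDS. Profiles are invariant under coordinate reflection
with strand flip — a standing test. Group summaries report the min–max CDS
intron range (a single value when degenerate) and any-member 5'UTR
occurrence, with members lacking models listed separately.

## Conservation profiles and motifs

`build_profile()` computes per-column residue frequencies over non-gap rows
and a consensus: the modal residue when its frequency reaches the cutoff
(default 0.5), or the class consensus `J` when the hydrophobic class
{A, V, L, I, M, F, W, C} reaches the cutoff and exceeds the modal frequency
(the class membership is a package choice; the source figure uses `J` for
"any hydrophobic residue" without enumerating it). `extract_blocks()`
returns maximal runs of columns at or above a conservation cutoff (default
0.8), bounded to widths 6–100. This deterministic block extraction is a
*semantic* stand-in for EM-based motif discovery (the original LOGO
inventory is a product of MEME, whose algorithm is deliberately not
reimplemented); it recovers planted conserved runs but will not find subtle
or gapped motifs. `scan_motif()` matches user-supplied degenerate consensus
patterns (width 6–100) and reports the signed distance from motif end to the
nearest downstream domain start (negative = upstream), and
`motif_sharing()` marks a motif present in a group when at least half the
members (configurable) carry it. The shipped
`gld_like_synthetic.motif` is a constructed example matching the
simulator's planted motif — the published GLD consensus exists only as a
LOGO image, so no transcription is shipped.

## The synthetic-data generator

`make_proteome()` inverts the scanner's constraints: ligand residues from
the canonical sets, spacer lengths uniform over the allowed ranges, spacer
and flank residues from a background distribution (uniform over the 20
letters by default, configurable). Its defaults define the package's study
conditions: six families dominated by RING-H2/RING-HC (sizes 8, 6, 5, 4, 4,
3), 10% within-family divergence, an ATL-like 12-residue motif planted 10
residues upstream of the domain in the first two families, four lone genes,
one two-domain protein, and two decoys per class. Families descend from a
single assembled ancestor, mutated per member at the divergence rate with
ligand positions and the motif core exempt, so pairwise identity outside
the domain calibrates to (1−d)² plus a small coincidence term. Every
emitted protein is post-checked with the scanner and resampled if it
accidentally contains any placement beyond the planted ones — truth
manifests are therefore unambiguous, at the cost of a mild deviation from
pure background sampling in the flanks.

Decoys violate exactly one constraint of exactly one type: a spacer one
residue beyond its base range (detectable only via the flagged extension
allowance, hence invisible with extensions disabled), a ligand mutated to a
non-tolerated residue (never detectable), or a missing boundary (sequence
ends before ligands 7–8 fit; only a partial hit is possible). The decoy
false-positive rate is accordingly measured with extensions disabled.

What the generator does *not* emulate: real amino-acid composition,
insertions/deletions within families, domain architecture beyond the RING
and one motif, or realistic family-size distributions. Passing tests
demonstrate correctness of the machinery under controlled conditions, not
performance on real proteomes.

`make_gff3()` builds gene models with requested CDS intron counts and
5'UTR-intron occurrence on alternating strands; `evolve_on_tree()` evolves a
domain along a tree with independent per-site Poisson substitutions, ligand
sites held fixed.

## Numerical choices and problem sizes

* Seeds are mandatory wherever randomness exists (simulation, bootstrap);
  identical spec + seed gives byte-identical output.
* Saturated distances clamp to 5 by default; negative NJ branch lengths
  clamp to 0; both warn (replicate trees inside the bootstrap suppress the
  clamp warning, since only their bipartitions are used).
* Equal-length sequences normalize similarity by the smaller self-score.
* Benchmarks used by the tests and the acceptance script: 500 random
  150-residue sequences for scanner–oracle equivalence (half C/H-enriched
  so that the corpus actually contains placements); a ~200-protein proteome
  (24 families, 32 lone genes, 12 decoys, 2 two-domain proteins) for
  recall/false positives; the default 41-protein panel for clustering ARI
  and 20%-divergence assignment; 5–8-taxon additive matrices for NJ; an
  8-leaf balanced tree at rate 0.15 substitutions/site/unit for
  topology-recovery (chosen so an internal branch carries ~10 expected
  substitutions over a typical ~68-residue domain without saturating the
  deepest pairs); 50 gene models for the GFF3 round-trip; 50 seeded runs of
  a 6-member, 40%-divergence family for 20-column block recovery (high
  divergence is what makes background columns drop below the 0.9
  conservation cutoff while the exempt motif columns stay at 1.0).

## Known limitations

* Detection is geometric: a sequence satisfying the spacing by chance is a
  hit; no score separates marginal from confident matches.
* The anchored alignment presumes correct ligand assignment by the scanner;
  misplaced ligands would propagate into distances.
* Distance corrections ignore among-site rate variation beyond the gamma
  shape parameter and use no empirical substitution matrix.
* Single-linkage clustering can chain families together through one
  intermediate sequence; the threshold is the only guard.
* Block extraction finds ungapped, uniformly conserved runs only.
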