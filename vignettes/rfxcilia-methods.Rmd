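---
title: "Methods: anchored RFX surveys, IFT conservation and co-occurrence states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored RFX surveys, IFT conservation and co-occurrence states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, scoring rules, numerical choices and
known limitations behind `rfxcilia`. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The scientific problem

RFX transcription factors carry a 76-residue winged-helix DNA-binding domain
(DBD) whose nine DNA-contact residues are conserved across the family. In
animals they drive ciliary gene expression through X-box promoter motifs;
across eukaryotes, however, cilia and RFX genes dissociate — ciliated algae
and protists lack RFX, several fungi kept RFX after losing cilia. Mapping
that relationship requires four coupled analyses: find RFX DBDs in peptide
proteomes, measure IFT/BBS gene conservation, place recovered DBDs on a
phylogeny, and classify species by cilia/RFX co-occurrence. This package
implements all four over a synthetic-proteome simulator so that every stage
is testable against known ground truth without genome downloads.

## Alignment engine and scoring

Local (Smith–Waterman) and global (Needleman–Wunsch) alignments use the
Gotoh three-state recursion with affine gaps; a gap of length $k$ costs
$g_o + k\,g_e$ (defaults $g_o = 11$, $g_e = 1$, BLOSUM62), the de facto
standard protein-search parameterisation. `X` residues score 0 against
everything and never count as identities. Scores are integer-valued, so the
C++ traceback can compare doubles exactly.

Tie-breaking is deterministic rather than canonical: among equal-scoring end
cells the smallest (query end, target end) wins, and the traceback prefers
aligned columns over gap-in-target over gap-in-query, stopping as soon as
the remaining prefix contributes nothing. Any co-optimal alignment has the
same score, identities differ only in degenerate ties, and reruns are
bit-identical — which is the property the pipeline actually needs.

The engine is verified against an independent brute-force oracle: an
alignment is an increasing matching of aligned residue pairs, with residues
between consecutive pairs forming one gap run per sequence (any other
arrangement costs extra gap opens and can only score lower). Enumerating all
$\binom{m+n}{m}$ matchings and scoring them directly gives exact maxima for
short sequences, sharing no code with the DP.

**Corrected percent identity.** The survey's acceptance statistic divides
identical aligned positions by the *full ungapped query length*:
$\mathrm{PID} = 100\,I/|q|$. A partial hit is thereby penalised for query
residues it fails to cover — a 38-residue perfect half-domain match scores
50, not 100.

**Empirical significance.** Instead of analytic e-value statistics (tied to
one search tool's internals), significance is a composition-preserving
shuffle test: the target is permuted $n$ times (default 199), the best local
score recomputed per shuffle, and
$p = (1 + \#[\text{null} \ge s])/(n+1)$; acceptance at $p \le \alpha$
(default 0.01). The plus-one estimator cannot report 0 and is exact-level
under exchangeability. One consequence worth knowing: when a *best hit over
$m$ proteins* is tested against shuffles of its single best target (the
classic one-way best-hit design), selection inflates the per-cell
false-present rate to roughly $m/(m+n)$. Spurious cells are rare and weak
(corrected PID far below 20), so they never affect ciliation calls or RFX
tiers, but an all-absent row is not guaranteed for decoy proteomes — the
tests assert the calibrated bound instead.

## Anchored detection and tiered classification

Each seed query carries nine 0-based anchor positions. An anchor counts as
conserved only if it lies inside the aligned query interval, is aligned to a
residue (not a gap), and is identical at that column. Classification:

- `RFX`: PID ≥ 40 **and** anchors conserved = 9 (both boundaries from the
  published screening rule);
- `RFX_LIKE`: otherwise, PID ≥ 25 and anchors ≥ 5 — the floor is this
  package's choice; the published examples of the weak tier sit at 29% and
  27% PID with 5/9 anchors, so 25 admits both while random hits (PID ~5–12)
  stay far below;
- `NONE` otherwise.

The published anchor positions are shown only graphically in the source
literature, so the packaged anchor set (and the 76-aa seed DBDs themselves)
are synthetic stand-ins, generated once from a fixed seed and shipped as
plain-text files; both are arguments wherever they are consumed.

**Iterative expansion.** Taxon groups are searched in a stated order with
the query list frozen at group start (order-independence within a group);
after each group, the extracted domain of every new RFX-tier call joins the
query list, with anchors mapped through the alignment onto target
coordinates. A mapped query that lost anchors to gaps is *detection only*:
its hits cannot demonstrate nine-anchor conservation and are capped at
`RFX_LIKE`. Queries are deduplicated by exact sequence; per protein only the
best hit (score, then PID) is classified, since no known family member
carries two DBDs. Calls are named `<species>_cRFX<k>` by descending PID, so
a weak RFX-like call takes the number after the strong calls.

## Synthetic data as the testbed

`evolve_domain` substitutes each position independently with probability $d$
(the replacement drawn from background frequencies excluding the current
residue, so a substitution always changes the residue); anchors can be
preserved exactly. With no indels, expectations are closed-form: preserved
anchors give expected raw identity $100(1 - d(L-a)/L)$ (73.6% at $d = 0.3$
for $a = 9$, $L = 76$). Proteome simulation embeds evolved domains between
random flanks among i.i.d.-background decoys and records exact truth
intervals; everything is a pure function of its seed. Clade series evolve a
domain along an `ape` tree with Poisson($\ell \cdot$ sites) substitution
events per branch.

Background frequencies are the Robinson–Robinson set (BLAST's protein
background), used consistently for decoy generation, substitution targets
and profile log-odds.

What the simulator does *not* emulate: indels (so corrected PID of true
implants is only mildly trimmed at the edges), domain shuffling, repeats,
low-complexity sequence, and real phylogenetic covariance among proteome
members. Passing tests therefore demonstrate the machinery's correctness and
calibration on clean signals, not performance on real proteomes.

## IFT scan and ciliation

The 24 queries (Motors: DYNC2H1, KIFAP3, KIF17, KIF3B, KIF3A; Complex A:
IFT122, IFT140, WDR35, WDR19; Complex B: IFT88, IFT80, IFT172, IFT57,
CLUAP1, IFT52, IFT20, IFT81, IFT74; BBS: BBS5, TTC8, BBS2, ARL6, BBS1,
BBS7) are scanned one-way (no reciprocal-best-hit filtering): per query the
best local alignment over the proteome, recorded as corrected PID if the
shuffle test accepts. The packaged queries are 200–400-aa synthetic
stand-ins sized for desk-scale tests; the scanner itself handles full-length
proteins.

Ciliation is not computed in the source literature (it is curated); the
pipeline needs a computed surrogate for co-occurrence states, so a species
is called ciliated iff ≥ 50% of the 24 queries are conserved at PID ≥ 20
(both knobs in `run_config()`, both boundaries inclusive). The thresholds
separate full rows from empty rows cleanly on synthetic worlds; per-species
manifest overrides mirror literature-curated labels and are logged when
applied.

## Phylogeny

Distances: global-align each pair of DBDs, take the p-distance over aligned
residue columns (gap columns excluded), and apply the Poisson correction
$-\ln(1-p)$, capped at $p = 0.95$ (distance ≈ 3.0) so saturated fungal-style
pairs cannot destabilise the tree; capped pairs are flagged. Pairwise
distances replace a progressive multiple alignment because the domains are
near-equal-length and highly similar, where the two agree closely.

Neighbor joining is implemented from scratch (Q-criterion agglomeration,
lowest-index tie-breaking, negative branch lengths clamped to zero with the
deficit moved to the sister branch) and returns `ape::phylo` objects. Its
oracle is the NJ consistency theorem: on additive matrices the true tree is
recovered exactly — verified on random trees with path-distance agreement to
1e-9. `ape::nj` serves as an independent cross-check, never as the
implementation.

Clade assignment is nearest-reference by path length with exact ties
honestly `UNASSIGNED`, chosen over formal monophyly tests because the
unrooted, support-free topology makes nearest-reference both robust and
simple to reason about. Reference panels ship as a synthetic four-group
construction (three shallow groups, one deep fungal-style group).

## Domain profiles

Ungapped position-specific scoring matrices stand in for profile HMMs: the
annotated domains are short and the downstream conclusions are
presence/absence architecture strings, so insert/delete states are
deliberately out of scope (the interface permits a later drop-in). Column
scores are Laplace-smoothed log-odds
$\ln\frac{c_r + \lambda b_r}{(n+\lambda) b_r}$ with $\lambda = 1$; the
expected score of a background residue is non-positive per column by
Jensen's inequality (verified numerically). Acceptance thresholds are
calibrated per profile as the 0.99 quantile of best-window scores over 1000
seeded background proteins of length 300, so the expected per-protein false
annotation rate is 1%. Scanning reports maximal non-overlapping windows
greedily by descending score; architectures merge profile annotations with
the DBD call, resolve overlaps by score, and join names by start coordinate
(`AD-DBD-B-C-DD`).

## Co-occurrence states and problem sizes

`BOTH` / `CILIA_ONLY` / `RFX_ONLY` / `NEITHER` partition species by
(RFX count ≥ 1) × ciliation; the partition and its monotonicity in the count
are property-tested. No ancestral-state reconstruction is attempted — states
are per-species observations, not inferred history.

Problem sizes used by the tests and acceptance script — chosen as the
smallest scales at which each property is decisive: oracle sweeps over all
reduced-alphabet pairs of lengths ≤ 2 plus 150 random pairs of lengths ≤ 8;
100 additive trees of 4–10 leaves; 50 proteomes × (1 implant + 50 decoys)
for sensitivity/false positives; 500 trials for null calibration; an
eight-species world for the end-to-end report. The shuffle count is 199 in
end-to-end runs and 99 in unit tests (the floor that still resolves
$\alpha = 0.01$).

## Known limitations

- No indel support in the simulator (v1), hence no test coverage of
  gap-heavy homology at the classification boundary.
- One-way best hits, not reciprocal: paralog/ortholog confusion is out of
  scope by design.
- The packaged seeds, anchors, IFT queries and profile alignments are
  synthetic; conclusions about real lineages require swapping in curated
  sequences.
- Profile scanning is ungapped; a single internal indel shifts the window
  and can drop a true domain below threshold.
- DNA-level (six-frame) searches of unannotated genomes are not
  implemented; the pipeline consumes peptide proteomes only.
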