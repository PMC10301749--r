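---
title: "Methods: plasmid mobility typing and broad-host-range screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasmid mobility typing and broad-host-range screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`plasbhr` characterizes plasmid nucleotide sequences for their potential as
broad-host-range (BHR) delivery vectors. The scientific model is simple and
rule-based, mirroring how the field reasons about conjugation:

* a plasmid is **conjugative** (self-transmissible) when it encodes both a
  relaxase and the mating-pair-formation machinery of a type IV secretion
  system (T4SS);
* a non-conjugative plasmid is **mobilizable** when it carries an origin of
  transfer (oriT) that a co-resident conjugative element can act on;
* everything else is **non-mobilizable**.

Evidence for these calls, and for five host-range-associated feature
categories — complete toxin–antitoxin (T-AT) systems, partitioning proteins
(Par), plasmid SOS inhibition (Psi), mating-pair stabilization (MPS), and
DNA methyltransferases (MTases) — comes from homology of predicted ORFs (or
plasmid DNA, for nucleotide references such as oriT and RNA antitoxins)
against user-supplied, category-tagged reference panels. A plasmid with at
least three of the five feature categories is a BHR candidate; candidates
are dereplicated by average nucleotide identity (ANI) clustering at 95%.

## ORF calling

ORFs are called deterministically on all six frames: an ORF runs from the
first start codon (ATG/GTG/TTG, bacterial translation table 11) after the
previous in-frame stop to the next in-frame stop, stop included, with a
90 nt default floor. This is intentionally simpler than a trained gene
caller: downstream analysis consumes ORF *catalogs* filtered by strong
homology, so precise start-site discrimination and RBS scoring add nothing
here, and nested/overlapping ORFs are all reported because homology, not
the caller, decides relevance. Codons containing N translate as X, and X
never terminates an ORF, so ambiguity cannot split a gene in two.

For circular replicons (`topology = "circular"`) the scan appends a 3 kb
junction-spanning extension; origin-crossing ORFs keep `end > length` so
that span arithmetic (`end - start` divisible by 3, protein length
`(end - start)/3 - 1`) stays valid, and ORFs starting inside the extension
are dropped as duplicates. The default is linear, the conservative choice
when topology is unknown.

## Alignment and statistics of hits

Local alignment is exact Smith–Waterman with affine gaps (an Rcpp kernel;
a gap of length *L* costs `open + L·ext`): BLOSUM62 with 11/1 for
proteins, +2/−3 with 5/2 for nucleotides, both strands searched in
nucleotide mode. Identity is identical columns over all alignment columns
(gap columns included); coverage is aligned reference residues over
reference length. Coverage is computed over the *reference* because the
reference sets are the queries against an ORF database, so "query
coverage" refers to the reference side.

E-values use the Karlin–Altschul form `E = m·n·2^(−bits)` with
`bits = (λS − ln K)/ln 2`, `n` the total residue count of the search
database. Protein mode uses the published gapped BLOSUM62(11/1) constants
λ = 0.267, K = 0.041; nucleotide mode uses the ungapped λ for the +2/−3
scheme at uniform base composition (solved numerically at load) with a
configurable K (default 0.41). Composition-adjusted statistics and
per-matrix gapped-λ recomputation are deliberately out of scope: the
E-value exists to apply fixed filter semantics, not to reproduce BLAST
numbers bit-for-bit.

Per-category filters are strict inequalities exactly as printed — an
identity of exactly 50% fails a ">50%" rule:

| tier | categories | E | identity | coverage |
|------|------------|----|---------|----------|
| base | REP, TOXIN, ANTITOXIN, RNA_ANTITOXIN | < 1e−5 | > 50% | > 50% |
| raised coverage | VF, ARG, T4SS, RELAXASE | < 1e−5 | > 50% | > 70% |
| raised identity | PAR, PSI, MPS | < 1e−5 | > 80% | > 70% |
| MTase | MTASE | < 1e−5 | > 50% | > 50% |
| oriT (nt) | ORIT | < 1e−5 | > 90% | > 90% |

The MTase coverage tier is a package choice (the upstream tool's built-in
coverage threshold is not public), as is the MOB-typer-style 90/90 oriT
tier; both are exposed in `default_thresholds()`. Search skips pairs only
via exact upper bounds (a target too short to reach the coverage gate; a
perfect score that would still fail the E-value gate), so pruning cannot
change results.

## Mobility and typing rules

The T4SS "machinery" requirement is operationalized as: at least one hit to
an MPF ATPase reference (VirB4/TraC class, flagged by an `_ATPase` suffix
on the reference id or family) *and* at least three distinct T4SS reference
genes. Both knobs are configurable; the defaults encode minimal multi-gene
evidence rather than a single lucky hit. The ATPase flag is read from the
reference id as well as the family because the family field carries the MPF
type (MPFF, MPFT, ...) used for `mpf_type` voting.

Two mobilizable rules are provided. The default, `strict_paper`, calls
mobilizable only on detected oriT, matching the definition used for cohort
headline counts. The alternative `relaxase_or_orit` also accepts a
relaxase alone (transfer in trans), a defensible superset when oriT
references are sparse. Conjugative calls do not additionally require oriT
detection: relaxase + T4SS suffices, since oriT reference coverage is the
weakest link in any panel.

Types: `mob_type` is the family of the highest-bitscore relaxase hit
(lexicographically smallest on ties), `mpf_type` the MPF family with the
most distinct T4SS genes hit (highest single bitscore on ties), and
`inc_types` the set of all Rep families, so multi-replicon plasmids retain
every Inc type.

The T-AT feature requires a *complete cognate pair* by default — a toxin
hit whose partner family appears among protein or RNA antitoxin hits —
because lone toxins are common and say little about stable residence;
`tat_pair_required = FALSE` restores the lone-toxin reading.

## ANI and dereplication

ANI is fragment-based (ANIb-style): each sequence is cut into consecutive
1,000 nt fragments (short remnant dropped), each fragment locally aligned
to the whole partner on both strands, and fragments with ≥70% fragment
coverage and ≥30% identity count as aligned; ANI is the mean identity over
aligned fragments, symmetrized across the two directions. Undefined ANI
(nothing aligned) never links plasmids. This replaces MUMmer-based ANIm
with an exact in-package computation while preserving the ≥95% clustering
semantics; the fragment gates are the standard ANIb ones. Clustering is
single-linkage (connected components) by default because the dereplication
statement "clustered together at >95%" carries no linkage; complete
linkage is available where within-cluster pair guarantees matter. Cluster
ids are numbered by smallest member id, so output order is deterministic.

## Cohort statistics

Group comparisons (length, GC, ARG presence across the three mobility
classes) use the tie-corrected Kruskal–Wallis test (delegated to
`stats::kruskal.test`) followed by Dunn's post hoc z-tests with Bonferroni
adjustment — the classical 1964 pairing; Holm is a knob. ARG presence is
encoded 0/1 and reuses the rank machinery. The chi-square approximation is
used by default even at small n, with an exact-style permutation p-value
behind `p_method = "permutation"` for calibration work. Per-ARG tables
report the fraction of carriers that are conjugative or mobilizable to one
decimal, the form in which such contingencies are usually quoted.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of clinical plasmid
cohorts with planted, machine-readable truth; every test of recovery in
this package runs against it. Choices and defaults:

* **Class mix 0.47 / 0.29 / 0.24** (conjugative / mobilizable /
  non-mobilizable) — the proportions seen in resistant-isolate plasmid
  collections.
* **Lengths** are class-conditional log-normals with medians ~12 / 6 /
  2.5 kb and σ 0.25–0.35, preserving the empirical ordering conj > mob >
  non-mob at desk scale (real cohorts run to hundreds of kb; the analysis
  is length-scale-free, so the vignette-scale medians keep the full suite
  in minutes, and they are config, not claims about any dataset).
* **GC 0.55 / 0.50 / 0.45** — conjugative plasmids GC-richest, again the
  qualitative empirical ordering.
* **Cassette divergence 0.05** amino-acid substitutions on planted
  proteins (nucleotide-level for oriT/RNA elements): far inside every
  threshold tier, so classification errors measure pipeline defects, not
  borderline thresholds. Divergence is amino-acid-level because all
  protein tiers filter on protein identity.
* **ARG probability 0.7 / 0.6 / 0.15** — resistance genes enriched on
  mobile plasmids; **feature probability 0.45 / 0.35 / 0.10** per
  host-range category, giving roughly binomial(5, p) BHR rates.
* **Clusters**: 3 seed plasmids copied twice each with 2% substitutions.
  Copies are mutated *outside* planted cassette spans — shared gene
  content conserved, backbone diverged — so cluster copies keep their
  planted mobility/feature truth while pairwise ANI lands near 98%.
  Cluster seeds are forced to be BHR candidates so the dereplication step
  always has planted structure to recover.

Cassettes are reverse-translated with uniform synonymous codon choice,
framed `ATG…TAA` with a leading in-frame stop guard so the ORF caller
recovers the planted protein exactly, and written over a randomized
partition of the backbone (replicon length is preserved and spans can
never overlap, so generation cannot fail on a crowded backbone). Each
plasmid draws from a substream seeded by `(base seed, index)`, so plasmid
*i* is identical across runs and stable when `n_plasmids` changes.

What the generator does **not** emulate: operon structure and synteny,
insertion sequences and repeats, recombination, codon-usage bias, and
database-scale reference redundancy. Passing recovery tests therefore
demonstrates the pipeline's internal correctness under clean planted
signal, not performance on real, repeat-rich sequence.

## Numerical and degenerate-input choices

* Alignment score ties break toward the earliest reference/target end
  coordinate — deterministic for any input.
* `gc_content` excludes N and other ambiguity codes from numerator and
  denominator and returns `NA` for all-ambiguous sequences; IUPAC codes in
  plasmid input are accepted and scored as N (mismatch) in alignment.
* An all-tied Kruskal–Wallis sample reports H = 0, p = 1 (no evidence)
  rather than NaN.
* Cohorts with fewer than two mobility classes skip group comparisons
  with a logged notice; an ANI step with fewer than two BHR candidates is
  skipped and noted.
* If a BHR candidate is shorter than the ANI fragment size, the fragment
  size is lowered to the shortest candidate for that run (logged).

## Problem sizes used in validation

The shipped suite validates at: n = 60 default cohorts for truth recovery;
200 random pairs against an independent local-alignment oracle; 10 × 10 kb
pairs at 2% substitutions (expected ANI 98) plus 1,000 random instances
against a union-find clustering oracle; 10,000 null simulations of 3 × 30
observations for type-I calibration of the Kruskal–Wallis path; and
byte-level determinism of repeated runs on a 12-plasmid cohort. These
sizes are the package's chosen validation scale — large enough for stable
empirical rates, small enough to run anywhere.

## Known limitations

* Exact Smith–Waterman is O(nm); traceback memory is one byte per cell.
  Desk-scale cohorts are fine; megabase-scale inputs want a seeded
  accelerator, which would have to reproduce these scores exactly to keep
  the test suite meaningful.
* Fixed Karlin–Altschul constants (no composition adjustment) make
  E-values conventional rather than BLAST-identical.
* ARG and MTase detection are plain homology against user panels; curated
  per-gene cutoffs, SNP-conferred resistance and target-recognition
  matching are out of scope.
* Host-range *rank* prediction (which taxa a candidate actually enters)
  is not attempted; the BHR flag is a screening heuristic over stability
  and defense-evasion content.
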