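---
title: "Mining 5'-anchored SSU rRNA reads for primer-evading lineages"
author: "primerscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining 5'-anchored SSU rRNA reads for primer-evading lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerscout)
```

## The problem

Amplicon surveys of microbial communities depend on "universal" PCR primers
binding conserved regions of the SSU rRNA gene. The binding regions are not
perfectly conserved: a lineage with several substitutions in the 8F or
Arch21F site, or even a single substitution in the primer's last four 3'
positions, fails to amplify and is structurally invisible to the survey.
Meta-transcriptomic libraries built by ligating an adaptor to the intact 5'
terminus of SSU rRNA molecules capture those binding regions without any
primer bias, so the reads themselves can be interrogated: which active
organisms would the universal primers have missed? `primerscout` implements
that interrogation end to end — site evaluation, OTU screening, targeted and
degenerate primer design, and distance-based novelty assessment — with a
seeded synthetic-data generator standing in for the (external) sequencing
data.

## Site evaluation

Every read is assumed 5'-anchored: its first base is the biological 5'
terminus. The binding site of the domain-assigned primer (8F for Bacteria;
Arch21F for Archaea and for domain-unclassified reads, which sit with the
archaeal primer in the standard evaluation layout) is the first $L$
nucleotides, $L$ the primer length. Comparison is IUPAC-set-wise: primer
code $c$ matches read base $b$ iff $b$'s expansion set is a subset of
$c$'s. An ambiguous read base therefore counts as a mismatch unless the
primer code covers every base it could be — the conservative choice, which
never inflates "matching" counts.

The classification rule, applied verbatim from the field's practice:

* **matching** — 0 mismatches, or exactly 1 mismatch located at primer
  positions $1 \dots L-4$;
* **mismatching** — ≥ 2 mismatches, or 1 mismatch within the last four
  positions ($L-3 \dots L$), because a 3'-terminal mismatch blocks extension;
* **incomplete** — the read is too short to contain the site;
* **unevaluable** — more than 10% of site bases are ambiguous (configurable).

"Last four" means positions $L-3,\dots,L$ inclusive. Patterns are printed in
the conventional dialect — `=` at matching positions, the observed read base
at mismatches — so `C==TA===========TA==` against Arch21F reads as
substitutions at positions 1, 4, 5, 17 and 18. At degenerate primer
positions a consistent read base prints `=`; an inconsistent one prints the
base.

`max_offset` (default 0) allows a small 5' scan for residual adaptor bases;
the placement minimizing the mismatch count wins, ties to the smallest
offset. Increasing `max_offset` can only decrease the minimal count (a
tested invariant).

Evaluation summaries report, per domain and primer, incomplete / matching /
mismatching-with-1–2 / mismatching-with-≥3 counts. Published summary tables
of this shape do not always reconcile their column sums with the quoted
complete-site totals; `summarize_evaluations` therefore exposes both
bookkeeping conventions in its `"complete_sites"` attribute rather than
silently choosing one.

## OTU screening

Reads (optionally co-clustered with reference sequences) are clustered by
the greedy centroid contract of the usual amplicon tools: visit sequences
longest-first; each joins the first centroid with identity ≥ 0.85, else
founds a new centroid. Identity is defined — since the original tools only
name their binary — as matching columns divided by all alignment columns of
an end-gap-free global alignment with match +1, mismatch −1, first gap
position −5, extension −1. Terminal gap overhangs count in the denominator
(two-way identity); a one-way mode (divide by the shorter sequence) is a
config switch, since which convention the original clustering used is not
recorded. The alignment kernel is compiled (banded affine dynamic
programming; the band is wide enough that any alignment reaching the cutoff
lies inside it, so accept/reject decisions are exact), with an exact-duplicate
short-circuit and a 5-mer prefilter that skips only centroids sharing no
5-mer with the query.

Screening keeps OTUs satisfying *all* of: unclassified at domain and/or
phylum (every read member; a rank is unclassified when missing or matching
`unclassified|unknown|uncultured`, configurable); complete binding sites in
every member; ≥ 3 mismatches in every member; ≥ 10 reads. Reference
sequences never count toward size — read support is what the size criterion
means. The per-OTU pattern reported is the modal member pattern, ties broken
lexicographically (the aggregation rule is not recorded in the original
workflow; modal is the least surprising choice). Screening is monotone:
relaxing any single criterion never removes a passing OTU (tested).

## Primer design

Candidates are enumerated exhaustively over the group consensus's first
100 nt at lengths 16–20. The consensus is the per-position union of member
bases (the minimal IUPAC code covering all of them), so by construction any
candidate covers every member with zero mismatches. Gates:

* **Melting temperature 45–52 °C**, applied to *every* expansion of a
  degenerate candidate (strict gate: each covered variant must itself be
  amplifiable). The default model is the Wallace rule $2(A+T) + 4(G+C)$ —
  transparent and hand-checkable at these lengths. A nearest-neighbor model
  (unified duplex parameters, entropy salt correction
  $\Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]$ at 50 mM Na⁺, 500 nM oligo,
  $T_m = 1000\,\Delta H / (\Delta S_{corr} + R\ln(C/4)) - 273.15$) is
  available via `tm_method = "nn"` and agrees with an independent
  published-parameter implementation to well under 0.5 °C. The two models
  disagree in a characteristic way: the historically published targeted
  primer 21AF has Wallace $T_m = 58$ but NN $T_m = 50.4$, i.e. it passes
  the 45–52 °C gate only under the NN model, which is what the original
  web-tool-based design would have used. The Wallace default is kept for
  transparency; reproducing published primer sets is an NN-mode exercise.
* **Degeneracy ≤ 32** (product of per-position alternatives; the bundled
  degenerate primer 26ABF, at 24, passes).

Specificity against a reference set counts sequences containing a
forward-strand site with at most `max_mismatches` (default 0) mismatches
*and* no mismatch in the last four primer positions — the 3'-weighted rule
again. Coverage scans all placements and reports the best one with the
evaluation module's matching call.

Merging two groups' sites into one degenerate primer requires a
registration, which published records rarely state. `find_shared_window`
recovers it by search: all window placements are scored by the number of
positions whose expansion sets are disjoint; minimal score wins, ties broken
first by smaller offset difference, then toward the 3'-most window. The
last tie-break is deliberate: SSU variable region V1 sits at the 5' end, so
among equally compatible windows the downstream one lies in more conserved
sequence. With this rule the documented Type A/Type B windows (both at
offset 20 of their groups' 5' regions) are recovered and their union is
exactly 26ABF, `G(G/C)(G/A/C)(C/T)ACTGCTATCGG(A/C)TT`, degeneracy
$2 \times 3 \times 2 \times 2 = 24$. The reverse primer (1492R and its
22-mer variant) is treated as user-supplied and only validated via
reverse-complement coverage; the package does not design reverse primers.

## Distances and novelty

Near-full-length sequences (strictly longer than 1200 ungapped nt — the
"over 1200 bp" filter) are compared on a supplied alignment. The uncorrected
distance is differences over compared columns with the classical
conventions: columns gapped in both sequences are skipped; terminal gap
overhangs are ignored; a run of consecutive gap columns in one sequence
counts as a single difference and a single compared column (`gap_mode =
"onegap"`). Both gap conventions and the terminal-gap treatment are config
switches, because the cited distance tools document them as options. Columns
with more than 50% gaps can be dropped beforehand (`filter_alignment_columns`);
the threshold is configurable since the original column mask is not
published.

A group is called a **candidate phylum** relative to another when even its
closest member is beyond the phylum-level identity boundary:
$d_{\min} > 1 - 0.75 = 0.25$, strictly. The boundary case $d_{\min} = 0.25$
does not fire — a documented, tested choice.

Species-level OTUs of full-length sequences reuse the same greedy clustering
at 0.97 after the length filter. The package consumes pre-aligned FASTA; a
center-star progressive aligner (`align_small`) is bundled strictly as a
small-synthetic-set fallback and is not meant for real rRNA alignments.

## The synthetic generator

`simulate_dataset` emulates the study regime the pipeline is built for:

* **Templates.** One ~1500 nt template per group, all derived from one
  random master so that between-group identity lands near 0.70 (well below
  the 0.85 read cutoff), with the universal-primer site and one mid-template
  block held conserved. The per-position substitution probability is solved
  from the identity target accounting for double-hit collisions.
* **Planted groups.** Each `plant_spec` names a template, a primer, a
  mismatch pattern (the site is rebuilt from primer + pattern), an
  abundance, a lineage and a complete-site fraction. The two default novel
  groups reproduce the published Type A / Type B architecture: Arch21F-site
  patterns `C==TA===========TA==` (12 reads) and `=====T=C=======A====`
  (25 reads) in a 50,000-read background — the ~1/20,000 rare-biosphere
  regime scaled to desk size — including the within-group A/G variant
  position that makes the merged primer degenerate. Novel-group abundances
  are complete-site read counts (the screening rule only sees complete
  sites), so their `complete_site_fraction` is 1; the background default is
  0.98, matching the few-percent incompleteness typical of these libraries.
* **Incomplete reads** are represented as reads shorter than the primer
  site. A read that instead *started* mid-primer would be indistinguishable,
  to a 5'-anchored evaluator, from a heavily mismatched complete site; the
  length representation keeps manifest statuses exact. This is the one
  place the generator deliberately simplifies reality.
* **Determinism.** One seed drives everything; per-spec substreams are
  derived arithmetically from it, so outputs are byte-identical across runs
  and machines.
* **Sequencing error** is off by default; when enabled (uniform
  substitutions), planted sites and variant positions are re-imposed after
  error injection so the manifest remains exact ground truth.

What passing tests on this generator do **not** show: robustness to real
chimeras, platform error profiles, intragenomic 16S variation, or reads
whose 5' termini are only approximately complete. The generator's
between-group identity is homogeneous along the molecule except for the
planted blocks, which real rRNA is not.

## Numerical choices and limitations

* Problem sizes in the shipped tests and acceptance script: 50,037 reads per
  pipeline run across ten seeds, 1,000 random aligned pairs for the distance
  oracle, exhaustive 60-case single-mismatch sweeps — sizes chosen so the
  whole suite exercises the full regime in a few minutes on one CPU.
* Clustering is deterministic given input order; input order is
  longest-first with stable ties, so equal-length inputs keep file order.
* `U` is normalized to `T` on all ingest (rRNA data may arrive in the RNA
  alphabet); storage is uppercase canonical.
* Primer files are accepted in IUPAC or the parenthesized `(C/T)` dialect;
  outputs emit both.
* Coordinates in all tabular outputs are 0-based half-open; prose and
  patterns use 1-based primer positions (so "the last four nucleotides"
  reads naturally).
* The package does not detect whether a read is rRNA, remove chimeras,
  build trees, or design reverse primers; it assumes pre-screened input.
  Dataset-scale counts from any particular survey require that survey's
  reads and reference databases and are out of scope — the synthetic
  regime, with its exact manifests, is the testable stand-in.
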