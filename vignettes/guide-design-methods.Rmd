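---
title: "Methods: PAM-anchored sgRNA design and off-target screening for bacterial CRISPRi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAM-anchored sgRNA design and off-target screening for bacterial CRISPRi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidescreenr)
library(dplyr)
```

## The problem

Chromosomally encoded, inducible CRISPR interference (CRISPRi) in *E. coli*
represses a gene by parking catalytically dead Cas9 (dCas9) on its DNA,
guided by a single guide RNA (sgRNA) whose 20-nt spacer base-pairs with a
genomic protospacer next to an N-G-G PAM. Converting the generic strain into
a strain targeting a new gene takes a single 90-nt recombineering oligo, so
the design problem is purely computational: for every annotated open reading
frame (ORF), find a 20-mer near the start codon whose genomic context is a
valid PAM site and whose sequence is specific enough that dCas9 will not
silence anything else.

`guidescreenr` implements that screen end to end: ORF validation, candidate
enumeration, tiered genome-wide specificity profiling, filtering and
ranking, oligo construction, a transcriptome-level off-target audit, and the
two descriptive models (sigmoid dose-response, gamma fluorescence
distribution) used to characterise the tunable promoter driving dCas9.

## Coordinate frame and site anatomy

All matching happens in the genomic CC-prefixed frame: an N-G-G PAM on one
strand reads as 5'-`CC N [20-nt protospacer]`-3' on the other, so every
candidate site is a 23-mer starting with `CC` on the scanned strand. In this
frame the PAM-proximal end of the spacer is the *left* end of the 20-mer:

* **region I** — the PAM-proximal 7 nt (site positions 4–10). Binding
  specificity is dominated by this seed-proximal segment, so candidate
  ranking uses region I abundance.
* **regions I + II** — the PAM-proximal 12 nt (positions 4–15).
* The screen lengths 10, 15 and 23 are exactly `CC + N + 7`, `CC + N + 12`
  and `CC + N + 20`; the three k-mer indices answer the exact-abundance
  questions at those lengths.
* `CT` and `TC` prefixes are the weak-PAM variants (N-A-G / N-G-A read on
  the opposite strand) and are screened alongside `CC`.
* "Mismatches outside the PAM" are mismatches within the 20-mer; the PAM
  dinucleotide must match one of the prefixes exactly and position 3 (the
  PAM N) is a free position, never counted as a mismatch.

Internally every coordinate is 0-based half-open; GenBank/GFF3 1-based
inclusive coordinates are converted at the I/O boundary, which keeps window
and k-mer arithmetic free of off-by-one special cases.

## ORF validation

An ORF is admitted to the screen when its first codon is an NTG start
(`ATG`, `GTG`, `TTG`, `CTG`) and its last codon a stop (`TAG`, `TGA`,
`TAA`), read on the coding strand. Nothing else is required: length
divisibility by 3 is reported as a warning, not a failure, because the
screen's admission rule names only the terminal codons. When both ends fail,
`failed_start` takes precedence, and the aggregate failure count is what the
report summarises. A codon containing `N` fails its membership test — the
conservative reading for ambiguous assemblies. Compound (`join`) locations
are skipped with a warning: the single-window screen is defined on simple
intervals, and how multi-segment CDS were handled upstream is not
specified, so skipping plus logging is the only defensible default.

## Candidate enumeration

Within each valid ORF the coding strand is scanned from the A of the start
codon; a candidate is any `CC`-anchored position whose offset (of the
site's first base, 0-based) is at most `window_nt` (default 150 nt), that
starts inside the ORF, and whose full 23-mer fits in the genome — crossing
the ORF's 3' boundary is allowed, since the window exists to keep the guide
near the promoter-proximal end, not to confine the protospacer to the ORF.
The 150-nt default is the published positional limit; it is a parameter, not
a constant.

By default only the coding strand is scanned (the screen is defined on the
ORF's own `CC`-prefixed subsequences, and CRISPRi efficacy is
strand-dependent); `scan_both_strands = TRUE` adds template-strand sites over
the same window, with the offset measured as the coding-strand offset of the
site's start-codon-proximal base. The choice is echoed into output headers.

## Canonical k-mer counting

Exact-abundance tiers use canonical k-mer indices: a k-wide window slides
along the forward strand (wrapping k−1 positions past the origin on a
circular replicon), windows containing `N` are skipped, and each window is
counted under the lexicographic minimum of itself and its reverse
complement. Each double-stranded site is therefore counted exactly once —
including reverse-complement-palindromic k-mers — which is the abundance
semantics the screen's downstream thresholds assume. The index is an
in-memory hash; a bacterial genome at k ≤ 23 needs no disk-backed structure.
Tests verify equivalence against a brute-force both-strand scan on random
genomes, strand symmetry, and the circular/linear unrolling identity.

## Off-target tiers, filtering and ranking

Per candidate the profile holds:

| column | meaning |
|---|---|
| `n_region1_cc` | canonical abundance of the 10-mer (`CC`+N+region I) |
| `n_region1_nearpam` | same 10-mer with `CT`/`TC` substituted for `CC` |
| `n_region12_cc`, `n_region12_nearpam` | 15-mer analogues |
| `n_exact23` | canonical abundance of the full 23-mer (self included) |
| `n_mm1` … `n_mm4` | PAM-prefixed sites at exactly that Hamming distance |

Mismatch tiers cannot be answered by a canonical index (it has no
Hamming-ball query), so they come from a windowed scan of both genome
strands for 23-mers whose first two bases are `CC`, `CT` or `TC`, comparing
the trailing 20-mer to the candidate's protospacer. The candidate's own
genomic site is excluded from the mismatch tiers and included in
`n_exact23`: a unique guide has `n_exact23 = 1`, so the removal threshold is
`n_exact23 > 1` — "any exact match" cannot include the self-match or every
guide would be removed.

`filter_and_rank()` removes candidates with an exact duplicate or any 1- or
2-mismatch site, then sorts survivors by increasing region I abundance
(`CC` + near-PAM), ties broken by offset. The 10/15-mer near-PAM abundances
are *reported and used for ranking only*, not for removal: the published
removal rule names only exact, off-by-1 and off-by-2 matches. The 3- and
4-mismatch tiers are likewise reported for the expression audit, not used
for removal. Per gene, the least-abundant region I site is reported even
when no candidate survives filtering.

## The recombineering oligo

The single-step strain conversion uses a 90-nt oligo: 35 nt of 5' homology
to the sgRNA cassette, the 20-nt spacer, 35 nt of 3' homology. The homology
arms are strain-specific chromosome context and are deliberately **not**
defaulted — inventing biological sequence would be worse than requiring it —
so `oligo_config()` demands both arms, and the package ships a clearly
labelled synthetic placeholder pair for tests. By default the spacer handed
to the builder is the reverse complement of the genomic protospacer (the
strand that base-pairs as the sgRNA spacer in the N-G-G frame);
`spacer_as_revcomp = FALSE` emits the protospacer verbatim, and
`emit_reverse_complement` flips the whole oligo for lagging-strand
targeting. Both switches are recorded in output headers because cassette
orientation is strain-specific.

## Expression-level off-target audit

Given per-gene paired abundances (uninduced / induced, RPKM-like), the audit
builds match-tier gene subsets for the spacer: genes containing, anywhere in
their annotated extent on either strand, a PAM-prefixed window with (i) an
exact region I match, (ii) ≤ 2 mismatches over regions I+II, or (iii)
exactly 3 or 4 mismatches over the full 20-mer. Membership tests the
annotated gene extent only (no promoter flanks; flank rules are not part of
the published mapping), windows fully contained in the extent. Tiers
overlap by construction.

Each tier's log2 fold-change distribution is compared to the global
distribution with a two-sample, two-sided Kolmogorov–Smirnov test (the
source analysis names no test; KS is the natural all-purpose
distribution-equality choice, Mann–Whitney is available), with no
multiple-testing correction. Fold changes use a configurable pseudocount,
default 0: genes with a zero abundance are flagged undefined and excluded
from tests rather than silently offset. The on-target gene's rank within a
tier uses ascending log2 fold change with ties sharing the better rank, and
`hamming_vs_repression()` probes for a distance–repression relationship by
Spearman correlation (undefined under zero variance, and reported as such).

## Dose-response and fluorescence-distribution fits

The dose-response of the arabinose-inducible promoter is fitted with the
logistic $f(x) = f_{max} / (1 + e^{-(x - x_{1/2})/\gamma})$, where $x$ is
the inducer concentration (% w/v), $f_{max}$ the saturating signal,
$x_{1/2}$ the half-max concentration and $\gamma$ the induction rate
constant. The printed source form, read literally, decreases with $x$;
since the dose-response it describes is increasing, the rising sign
convention is the default and the literal falling form sits behind
`form = "falling"`. Fitting is Levenberg–Marquardt least squares with
data-quantile initialisation ($f_{max}$ from the max signal, $x_{1/2}$ from
the half-max point, $\gamma$ from a tenth of the range), bounded below so
$f_{max} \ge 0$ and $\gamma > 0$; an all-zero response short-circuits to
$f_{max} = 0$ rather than presenting the optimiser a singular problem.

Per-cell fluorescence is fitted by a two-parameter gamma distribution via
maximum likelihood. The shape parameter predicts the expression noise,
$CV = 1/\sqrt{shape}$; shape 25 corresponds to the CV ≈ 0.2 regime seen in
the promoter's linear induction range. Exponential dilution after inducer
withdrawal is fitted as `log(y) ~ t`; with stable proteins the half-life
equals the culture doubling time (32 min in the reference growth
condition), which is what `decay_halflife()` reports on noiseless halving
data. Slopes below 1e-12 in magnitude are treated as flat (rate 0, infinite
half-life) to keep machine-noise regressions out of the rate.

## What the synthetic fixtures emulate — and what they do not

`make_genome()` produces a uniform-random ACGT background with
non-overlapping forward-strand ORFs (NTG starts, proper stops; requested
invalid ORFs violate exactly one rule), and plants PAM-prefixed sites with
exact mismatch structure relative to a reference spacer, in gene interiors
or intergenic gaps, never touching terminal codons and never overlapping
each other. `make_expression()` draws log-normal baseline abundances
(sdlog 1.5 around 100, spanning the several-decade dynamic range of a
bacterial transcriptome), applies multiplicative log-normal noise of chosen
CV, and divides the target by the knockdown fold — 32 by default, the
strongest repression observed for a non-essential target.
`make_dose_response()` spans two concentration decades (0.001–0.1 % w/v,
the published induction range) with defaults $f_{max}=100$, $x_{1/2}=0.03$,
$\gamma=0.01$.

Deliberately **not** emulated: codon usage, GC content, operon structure,
reverse-strand genes by default, transcriptional coupling (polarity) and
regulatory feedback (an autoregulated target gene partially cancels its own
knockdown — visible in real data, absent here). Passing tests therefore
demonstrate the algorithmic contracts — tier counting, filtering, ranking,
calibration of the statistics under a clean null — not performance on real
transcriptomes, where fold-change distributions are heavier-tailed and
subsets are correlated by regulons. All generators take explicit seeds and
restore the caller's RNG state (`withr::with_seed`), so identical seeds give
byte-identical files.

## Problem sizes and numerical choices

The test and acceptance workloads use genomes of 0.8–12 kb, 2–12 ORFs,
expression tables of 200–4000 genes, 100–1000 statistical replicates and
10⁴ draws for distribution fits — sizes at which the brute-force oracles
(naive double-strand scans and enumeration) remain exactly computable, so
every tier count can be checked against an independent implementation
rather than against itself. Ties in ranking are always broken by offset,
then document order; output tables are fully ordered so repeated runs are
byte-identical. Window scans skip any window containing `N` (consistent
with the index's skip rule) rather than attempting ambiguity-aware
matching, which the screen never defined.

## Known limitations

* No on-target efficacy model (thermodynamics or learned scores): ranking
  is purely by region I abundance, as in the original screen.
* The genome-wide screen is exact but O(genome × candidates) in the
  mismatch tiers; for a 4.6 Mb genome with ~4000 genes the full
  `design_genome()` run is minutes-scale, not seconds-scale.
* GenBank parsing covers simple and `complement()` CDS locations only;
  `join()` features are skipped by design.
* The expression audit consumes abundances as given; normalisation,
  alignment and differential-expression modelling are upstream concerns.
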