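---
title: "Methods: integrated small RNA, degradome and coexpression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated small RNA, degradome and coexpression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdegnet)
```

# Scope and design

`mirdegnet` implements the analysis backbone used by integrated plant
miRNA studies of stress time courses: an experiment samples a plant at k
time points (S1..Sk, default k = 8, S1 the untreated control), sequences
small-RNA libraries per time point, one pooled degradome (PARE) library,
and per-time-point expression counts against an assembled transcript set.
The package covers the downstream analysis: tag cataloguing, precursor
validation, degradome-guided target calling, threshold-based differential
expression, miRNA-target anti-correlation, and a weighted coexpression
network. Upstream steps (read trimming, de novo assembly, homology
annotation) are out of scope; the transcript set and count tables are
inputs.

Because real deposited libraries are large and accession-specific, the
package ships a first-class synthetic-data generator
(`simulate_experiment()`) that plants known miRNAs, cleavage sites,
expression trajectories and correlation structure, and records them in a
truth manifest. Every downstream stage is validated against that truth.

# The small-RNA catalog

Reads are collapsed to distinct tags with per-library counts
(`collapse_reads()`), restricted to the 17-25 nt window that brackets
plant Dicer products (`filter_by_length()`; bounds inclusive), and purged
of rRNA/tRNA/snRNA/snoRNA fragments by exact substring matching against a
contaminant set on both strands (`remove_contaminants()`). Exact matching
replaces the similarity search a production pipeline would use: at desk
scale it is deterministic, and the partition it produces is easy to
verify against a quadratic scan.

Tags are then matched to a reference mature-miRNA set (`match_known()`)
under a constrained variant grammar: at most 2 substitutions and end
shifts of at most 2 nt per end. The winning reference minimizes
(substitutions, total shift), with remaining ties broken by reference id
so results are reproducible. Matched tags are named
`<ref>[_L±n][R±n][_kss<pos><ref><alt>...]` - for example
`miR156a_R+1_1ss15GA` is the reference extended by one base on the 3'
end with a G-to-A change at reference position 15 (positions 1-based on
the reference mature). Rendering and parsing are exact inverses on this
grammar, which the tests exercise by sampling variants, applying them to
a reference and re-deriving the name.

Expression tiers follow the abundance convention of miRNA catalogues:
`low` below 10 total reads, `high` strictly above the catalog mean,
`middle` between (a total exactly at the mean is middle, since "high"
means over average). The generator draws background tag lengths with a
mode at 24 nt - the heterochromatic siRNA class that dominates angiosperm
libraries - with a secondary 21 nt class, so the catalog's redundant
length histogram reproduces the canonical plant profile.

# Hairpin discovery

Candidate precursors are excised around a tag's locus
(`excise_candidates()`): for each window w in {80, 150, 250} nt (covering
typical plant precursor lengths) the tag is placed on the 5' arm
(extended w downstream) and on the 3' arm (extended w upstream),
truncated at transcript bounds. A `slack` of 20 nt is additionally taken
on the tag-proximal side: real precursors carry a short flank outside
the mature arm, and cutting exactly at the tag boundary would clip the
fold. Setting `slack = 0` recovers the strict tag-boundary cut.

Folding is an injected engine. The default shells out to RNAfold
(nearest-neighbour thermodynamic model); `fold_engine_maxpair` is a
base-pair-maximization stub for structure-only work whose pseudo-energy
is not in kcal/mol - energy statistics always require the thermodynamic
engine, and its absence is a configuration error rather than a silent
fallback. From the fold we report MFE, AMFE = |MFE|/length x 100 and
MFEI = AMFE / GC%, the standard hairpin-quality index. MFEI is reported,
not gated: published precursor sets describe their MFEI range rather
than filtering on it, so a `min_mfei` option exists but defaults to off.

`validate_hairpin()` passes a candidate when (a) at least 75% of mature
bases are paired, (b) every pairing partner lies on the opposite arm
(pairing into the mature span itself, or partners on both sides of it,
is a loop-spanning failure), and (c) at least 80% of precursor-mapped
reads start within +/-2 nt of the mature or star 5' ends. The 75% duplex
and +/-2 nt read-stack windows follow the community's plant-miRNA
annotation criteria. The star span is inferred from the pairing partners
with the canonical 2-nt 3' overhang of a Dicer duplex. Discrimination is
checked against dinucleotide-preserving shuffles (Altschul-Erikson
Eulerian-path shuffling): shuffled precursors keep composition but lose
the arm-to-arm duplex and overwhelmingly fail validation.

# Degradome target calling

miRNA-guided cleavage leaves the 5' end of the 3' decay fragment at the
target base paired to miRNA position 10; degradome tags are therefore
20-21 nt sequences whose 5' ends pile up at cleavage sites.
`map_degradome()` places tags on the sense strand by exact match
(multi-mapping tags count at every locus - de novo assemblies are
redundant, and dropping multi-mappers would silently lose true sites)
and accumulates per-position 5'-end counts.

Complementarity is scored with the standard plant rubric
(`align_mirna()`): Watson-Crick 0, G:U wobble 0.5, mismatch 1, gap 2,
all penalties doubled at miRNA positions 2-13; at most one gap (a bulged
transcript base or an unpaired miRNA base) per duplex; sites at score
<= 4 are reported, 4 being the conventional cutoff. The scanner
evaluates every offset and gap placement with vectorized prefix sums;
for long transcripts an edit-distance prescreen (radius `2 x max_score`
errors, which provably contains every admissible site since each scored
penalty is at least 0.5 per error) selects windows that are rescored
exhaustively, so both paths return identical results.

The canonical cleavage position of a gap-free site ending at transcript
base t1 (the base paired to miRNA position 1 - the duplex is
antiparallel) is t1 - 9; a gap 5' of miRNA position 10 shifts this by
one, and an unpaired miRNA position 10 itself is assigned the 5'
fragment boundary t1 - 9 by convention.

A target hit requires at least one degradome read at the canonical
position (exact by default; `cleave_window` up to +/-1). Each signature
is classified into the five confidence categories: 4 = single raw read;
0 = above one read and the transcript's unique maximum; 1 = a tied
maximum; 2 = below the maximum but above the median; 3 = at or below the
median. "Over one raw read" is read as strictly more than one -
otherwise category 4 would be unreachable. The median is computed over
positions carrying at least one read (`median_mode = "nonzero"`): a
transcript-length median of a sparse profile is ~0, which would make
category 3 unreachable; `median_mode = "all"` implements the alternative
reading. All categories are retained in the output - low-confidence
single-read sites are reported, not discarded. `tplot_data()` exports
the per-position profile with the cleavage site flagged, the data behind
a target plot.

# Differential expression

Expression is normalized as RPKM; tests run on raw counts. Two tag
counts x, y from libraries of sizes N1, N2 are compared with the
Audic-Claverie exact test, the standard digital-expression test:
conditional on x, y follows a negative binomial,
P(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1)). The two-sided
p-value doubles the smaller of P(Y <= y) and P(Y > y) and caps at 1.
This tail convention is chosen deliberately: it makes the test exactly
exchange-symmetric (p(x,y,N1,N2) = p(y,x,N2,N1)) and gives p = 1 for
x = y at equal library sizes, and it calibrates to an empirical type-I
rate of 0.050 at the 0.05 level on null Poisson pairs. Everything is
computed through the negative-binomial CDF, so large counts are
overflow-safe.

Gene significance is the conjunction p < 0.005, BH-FDR <= 0.001 and
|log2 ratio| >= 1, with FDR adjusted per pairwise comparison (each
treatment sample against the control) and log2 ratios taken on RPKM with
a 0.01 pseudocount (zero handling is otherwise undefined). miRNAs use a
looser per-comparison p < 0.05 ("loose" set) plus a stricter gate of
total raw abundance > 10 reads across libraries ("strict" set); the
abundance gate is applied to raw summed counts, as no normalization is
specified for it. Note that the exact test assumes Poisson sampling:
on overdispersed counts it overcalls nulls (the synthetic runs make
this visible), which is a faithful property of this class of
threshold-based DGE pipelines rather than a defect of the
implementation - dispersion-modelling tests are deliberately out of
scope.

Heatmap-style presentation uses per-feature Z-scores; constant profiles
map to zero.

# Integration

`pair_de()` joins strict DE miRNAs with their degradome-validated
targets that are themselves DE by the gene thresholds. `correlate_pairs()`
computes Pearson's r over the Z-scored k-point profiles (Z-scoring does
not change r; it mirrors the heatmap presentation) and classifies the
direction with a threshold of -0.5: r <= -0.5 negative, r >= 0.5
positive, otherwise uncorrelated; constant profiles are defined as r = 0.
The numeric threshold is a package choice - published integrations
typically report "reversed patterns" without a statistic - and is
exposed as `negative_threshold` because it genuinely requires user
judgement. Term enrichment of target sets is the one-sided
hypergeometric upper tail per term (identical to one-sided Fisher),
flagged at raw p < 0.05 with a BH column reported but not gating,
against a background of all annotated genes by default.

# Coexpression network

Genes with more than four zero values across the samples are removed
(the filtering sentence in this literature is ambiguous between
"selected" and "excluded"; removal matches the stated goal of excluding
non/lowly expressed genes) and survivors are log2(x+1)-transformed.
The unsigned adjacency is |cor|^6 - power 6, the conventional default
for unsigned networks (a signed option exists) - and the topological
overlap matrix is
TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij).
Modules are average-linkage clusters of 1 - TOM under a static cut at
0.95 with minimum size 30, unassigned genes labelled "grey" and labels
ranked by size. A static cut approximates the dynamic tree cut of the
reference implementation while staying deterministic and
dependency-light at desk scale; both knobs are exposed. Eigengenes are
the first principal component of the standardized module submatrix,
sign-oriented to correlate positively with the module mean profile.
`hub_subnetwork()` exports hub-centred edge lists at an adjacency
threshold (default 0.1, a common export default) plus the neighbour set
shared by all hubs.

The planted-partition generator draws each block gene as
sqrt(rho) z_b + sqrt(1-rho) e with rho = 0.8 and one hub per block at
rho = 0.95 over 8 samples. Two constructions make the benchmark
well-posed at this sample size: block factors are orthogonalized so the
realized inter-block factor correlation is exactly 0, and each gene's
noise is projected orthogonal to its block factor so realized loadings
equal sqrt(rho) exactly. Without the second step, a member's chance
loading at n = 8 frequently exceeds the hub's 0.95 and "the hub has
maximal within-module connectivity" would hold only in expectation.

# Synthetic data: what it emulates, and what it does not

The generator emulates: 17-25 nt tag libraries with a 24-nt redundant
mode; hairpin precursors with mature/star read stacks (star with the
2-nt 3' overhang); degradome tags of 20-21 nt with planted peaks (5
reads by default) at canonical cleavage sites over distinct count-1
background positions (~2/kb), so decoy transcripts carry only
single-read signatures; negative-binomial trajectories over 8 samples
(dispersion 0.05, gene base mean 200, miRNA base mean 50) with an
8-fold planted rise peaking at S6 and its exact mirror for planted
anti-correlated pairs (10 negative and 5 positive pairs among 30
planted interactions against 30 decoys); and the orthogonal block
design above. Peaks use perfect-complement sites (score 0), so planted
recovery probes coordinate arithmetic and profile logic, not scoring
tolerance - scoring tolerance is probed separately against brute-force
oracles.

It does not emulate sequencing error, adapters, quality scores,
expression-dependent capture bias, paralogous gene families, or
partially complementary true sites. Passing the planted-truth tests
therefore demonstrates correctness of the pipeline's logic under its
own model, not performance on real libraries.

# Numerical choices and degenerate inputs

* All generators take an explicit seed, save and restore the global RNG
  state, and are byte-reproducible for identical (parameters, seed);
  the seed is recorded in the truth and run manifests and in stage logs.
* Sequences are held in the DNA alphabet internally (U -> T on input).
* Ties: reference matching breaks ties by (substitutions, shift,
  left offset); module labels by size then cluster index; target hits
  deduplicate per (miRNA, transcript, site) keeping the best score.
* Degenerate cases are defined, not crashed: empty catalogs and
  libraries propagate as empty tables; constant profiles get r = 0 and
  Z-score 0; a degenerate module falls back to its standardized mean
  profile; a zero-GC precursor or a missing folding engine is an
  explicit error.
* Problem sizes in the tests (30 planted interactions over 60
  transcripts of 0.6-1.2 kb, 800-feature DE runs, 400-gene network
  benchmarks, 10^4-replicate oracle comparisons) were chosen as the
  smallest sizes at which every planted signal is unambiguous.

# Known limitations

* Contaminant removal is exact-substring; true Rfam-style covariance
  scanning is out of scope.
* The exact test ignores biological overdispersion (see above).
* Target scoring handles at most one gap per duplex and no G:U-aware
  seed weighting beyond the doubled 2-13 window.
* Static-cut module detection can split elongated modules that a
  dynamic cut would keep whole; the cut height and minimum size are the
  two knobs to adjust.
* The paper-style MFEI range (~0.9-1.1 for genuine precursors) is
  descriptive; no MFEI filter is applied by default.
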