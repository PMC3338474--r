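---
title: "Characterizing a congenic strain's donor segment and the evolution of its candidate signal genes"
author: "congenicScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: congenic segment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(congenicScope)
```

# The problem

A congenic mouse strain is built by crossing a donor strain onto a recipient
background and then backcrossing for many generations while selecting
carriers of one donor allele — here, an allele of the salivary
androgen-binding protein gene *Abpa27* moved from DBA/2J onto C3H/HeJ over
16 backcross generations. Selection drags along flanking donor chromatin,
so any phenotype attributed to the selected locus could instead come from a
linked passenger gene. This package implements the full inference chain for
interrogating such a strain:

1. how much donor chromatin is *expected* to remain around the selected
   locus (`expectedFlankingLength()`, `simulateBackcross()`,
   `sizeBoundsMb()`);
2. where the transferred segment actually sits, from strain SNP haplotypes
   and subspecies-ancestry tracks (`callOrigins()`, `inferSegment()`,
   `functionalSize()`);
3. which genes inside it could encode a salivary signal
   (`triageCandidates()` and the individual filters);
4. how diverged the surviving genes' alleles are (`countSubstitutions()`,
   Grantham classification);
5. whether their gene trees match the species tree (`njTree()`,
   `checkCongruence()`); and
6. whether they carry site-level signatures of positive selection
   (`fitSiteModel()`, `testSelection()`, `bebSites()`).

`runPipeline()` chains the stages from one configuration list or YAML file;
every input class can be produced with known ground truth by the
`gen*()` generators and `abpExampleBundle()`.

# Backcross retention model

Under Haldane's model (crossovers as a Poisson process at 1 per 100 cM per
meiosis, no interference), the donor chromatin retained on one side of the
selected locus after $t$ backcross meioses is $\min(X_1,\dots,X_t, D)$,
where $X_i \sim \text{Exp}(1/100\ \text{cM})$ is the distance to the
nearest crossover in meiosis $i$ on the transmitted (donor-carrying)
chromatid and $D$ is the map distance to the chromosome end. The minimum of
$t$ exponentials is exponential with rate $r = t/100$ per cM, so with
censoring at $D$,

$$E[L] = \frac{1 - e^{-rD}}{r}, \qquad
  E[L^2] = \frac{2}{r^2}\left(1 - e^{-rD}(1 + rD)\right),$$

where the second expression already contains the $D^2 e^{-rD}$ censoring
atom. The two sides are independent, and the combined flank is their sum.
Both moments are verified in the test suite against numerical integration,
and the Monte-Carlo twin (`simulateBackcross()`) agrees with the closed
form within three standard errors at $2\times10^4$ replicates.

For the design analysed here — 16 generations, an 80 cM chromosome, locus
17 cM from the proximal end — the model gives a mean combined flank of
about 12 cM with a standard deviation of about 8 cM, i.e. 8–40 Mb at the
mouse-genome conversion of ~2 Mb per cM. The default chromosome-7 geometry
(80 cM, locus at 17 cM) follows from that conversion and the locus's ~34 Mb
physical position; all parameters are arguments of `backcrossDesign()`.
This min-of-exponentials model is an approximation to the exact
finite-chromosome derivation the literature reads from plots, which is why
downstream checks carry ±1 cM (mean) and ±1.5 cM (SD) tolerances. Kosambi
interference and marker-assisted breeding schemes are out of scope.

# Segment inference and the "functional" size

Markers are whole SNP haplotypes: the congenic strain is called `donor` at
a marker only when it matches the donor haplotype at every site where the
parents differ; one discordant informative site makes the call `ambiguous`
rather than triggering a majority vote. The outermost donor calls bound the
*minimal* interval; the innermost flanking recipient calls (or the region
ends) bound the *maximal* interval; each donor-to-recipient transition is a
crossover interval. Coordinates are Mb on half-open intervals.

Two refinements mirror the biology:

* **IBD masking.** Where the two parent strains inherited the same
  subspecies haplotype, donor and recipient are indistinguishable and the
  segment boundary cannot be placed. The *functional* size is therefore the
  length, inside the maximal interval, where the parents' ancestry tracks
  assign different subspecies; `unknown` ancestry is conservatively treated
  as "not differing". When the proximal flank runs into IBD with no
  recipient-called marker, the report sets `unboundedLeft` instead of
  fabricating a coordinate.
* **Assembly gaps** overlapping a crossover interval are reported as
  resolution limits in the notes, never subtracted from the size.

On the marker layout of the analysed strain (shipped as labelled-synthetic
TSVs under `extdata/`), the functional size evaluates to 33.6 Mb,
reported as ~34 Mb, with the distal crossover confined to (38.8, 50.9) Mb
by the *Ccne1*/*Siglece* calls and the 39.5–46 Mb assembly gap noted.

# Candidate triage

The staged filters are deliberately simple set operations with recorded
provenance: region overlap (half-open interval intersection), an inclusive
intensity floor of 10 (the microarray noise floor; intensities ranged up to
250–400), gland-pattern profiling (a gene counts as expressed in a gland if
any retained probe in either sex supports it; percentages are rounded
half-up against the post-region gene count), protein localization (strictly
intracellular or membrane-bound products cannot be salivary signals;
`unknown` is retained), allele divergence (drop genes with no
nonsynonymous substitution, or only one or two that are all conservative),
and proteome confirmation restricted to the region. The final candidate set
is, by construction and by validity check, exactly the conjunction of
recorded passes. Since the source data never define "conservative", the
package uses Grantham distance ≤ 100, computed from the published
physicochemical formula rather than a transcribed table; the threshold is
an argument. Probable cross-hybridization artifacts are handled by an
exclusion-list argument, not hard-coded gene names.

# Divergence counting

`countSubstitutions()` compares two in-frame allelic sequences site by
site: a nucleotide difference is nonsynonymous if exchanging that single
site — the other two codon positions held at the *first* sequence's state —
changes the amino acid. This observed-difference convention matches how
allele comparisons are tallied in the source literature; Nei–Gojobori-style
pathway averaging is available as an option. Two consequences are
documented rather than hidden: the convention is asymmetric for a few
multi-hit codons, and an amino acid replacement can occasionally arise from
individually-synonymous exchanges (CTA→TTT is Leu→Phe although both single
swaps are synonymous), so no ordering between nucleotide and amino acid
counts is enforced. Terminal stop codons are excluded; indels are rejected
rather than aligned — alignment is an input, not a task, of this module.

# Gene trees and congruence

Distances (K2P by default, the classic choice of the PAUP* era; p-distance
selectable) and Saitou–Nei neighbor-joining come from `ape`, with negative
branch lengths clamped to zero and rooting on the *M. spretus* outgroup.
The congruence test is the package's own: a gene tree is congruent with the
species tree iff every non-trivial split of the gene tree is pairwise
compatible (Buneman's criterion) with every species-tree split — a
polytomy in the species tree therefore accepts any of its resolutions. The
reported distance counts incompatible gene-tree splits, and the displaced
taxa are found by greedily removing the leaf whose deletion most reduces
that count (ties broken alphabetically). The test suite checks all 15
unrooted five-taxon topologies against a brute-force enumeration of the
polytomy's resolutions.

# Codon site models

The selection engine implements the Goldman–Yang codon model: a 61×61
reversible generator with zero rate for multi-nucleotide exchanges, factor
$\kappa$ for transitions, $\omega$ for nonsynonymous exchanges, and target
codon frequency $\pi_j$ (F3x4 from the alignment by default, floored at
$10^{-6}$ and renormalized). Site-to-site variation in $\omega$ follows the
M8/M8A pair: a Beta$(p,q)$ class on $(0,1)$ discretized into $K = 10$
equal-probability bins (bin-midpoint ratios) with weight $p_0$, plus one
extra class at $\omega_s$ with weight $1-p_0$ — free with $\omega_s \ge 1$
under M8, pinned at 1 under M8A. Likelihoods are computed by Felsenstein
pruning over unique site patterns in compiled code, with transition
matrices from the symmetric eigendecomposition of the reversible generator;
gaps are missing data and species-tree polytomies are resolved with
zero-length branches. Pruning is verified to $10^{-8}$ in log space against
exhaustive enumeration over internal states on small trees, and the
generator satisfies detailed balance with unit mean rate by construction.

**Fitting strategy.** $\kappa$ and branch lengths are estimated once under
M0 (single-ratio) by bounded quasi-Newton; the mixture parameters
$(p_0, p, q, \omega_s)$ plus a global branch-scale $\tau$ are then
maximized with Nelder–Mead from three fixed, spread starting points on a
cached per-site log-likelihood surface — a grid over
$(\omega, \tau) \in [0, 50] \times [0.2, 8]$ with bilinear interpolation —
followed by an exact-likelihood polish; the reported log-likelihood is
always an exact evaluation at the optimum. `testSelection()` shares the
anchor between the two models and additionally starts M8 from the fitted
M8A solution, so the nested-model inequality
$\ell_{M8} \ge \ell_{M8A}$ holds to optimizer tolerance. The $\tau$
parameter absorbs the branch-length freedom the mixture would otherwise
re-estimate; a full joint refit of every branch under the mixture is not
offered. Everything is deterministic: no randomized restarts, fixed
tie-breaks, identical output for identical input.

The LRT uses $2\Delta\ell$ against a one-sided $\chi^2_1$ (the common
choice for M8-vs-M8A; the mixture-boundary 50:50 null would be more
conservative and can be emulated by halving the p-value). Calibration under
these small-sample conditions is checked by simulation in the test suite:
at 5 taxa and 300 neutral codons the empirical size at nominal 0.05 stays
at or below 0.10, and power at $\omega_s = 8$ in 10% of 500 codons exceeds
80% over 50 replicates.

**BEB.** Site detection integrates over uncertainty in $(p_0, \omega_s)$ on
a uniform 10×10 grid ($p_0$ at bin midpoints of $(0,1)$, $\omega_s$ at bin
midpoints of $(1, 25)$), weighting each grid point by its full-data
likelihood with the beta shapes, $\kappa$ and branch lengths held at their
MLEs. This is faithful in spirit, not line-by-line, to the CODEML BEB
procedure: tier membership (posterior > 0.90 / 0.95 / 0.99), not exact
posterior digits, is the contract, and false-positive behaviour is
simulation-checked (tier-0.95 calls stay below 5% of codons on neutral data
in ≥ 90% of replicates). Sites are labelled with the residue of a chosen
reference taxon and a configurable numbering offset, so positions can be
reported within the mature, signal-peptide-removed protein as structural
work requires.

# Synthetic data: what it emulates, and what it does not

`genCongenicPanel()`, `genExpressionTable()`, `genAllelePair()`,
`genCodonAlignment()` and `genProteomeHits()` generate every input class
with recorded ground truth; one seed drives deterministic sub-streams.
Intensities follow a lognormal body over the floor plus a sub-floor noise
mass (the sources give only the observed range, so these are the package's
chosen defaults). Codon alignments are evolved by sampling from the exact
transition kernels of the generator with per-site $\omega$ drawn from the
requested regime, scaled so branch lengths read as expected substitutions
per codon.

`abpExampleBundle()` assembles a complete stand-in for the published
configuration: the marker panel and ancestry layout of the congenic strain,
an expression table partitioning 26 region genes 10/7/1/0 across gland
categories, filter inputs that eliminate all EST-derived genes while
confirming the three cDNA-supported *Abp* paralogs, allele pairs with the
published substitution counts planted (40/32, 5/4, 3/3), and 5-taxon codon
alignments evolved on the published tree topologies under the published
mixture point estimates ($\omega_s = 11.9$ in 14.6% of codons for *a27*,
with the four reported sites planted and the reference residues pinned;
$\omega_s = 12$ in 4.6% for *bg26*; neutral for *bg27*). Gene-tree branch
lengths are the package's choice (tip depths 0.07–0.40 expected
substitutions per codon), set to give the five murid taxa realistic,
informative divergence. Because the bundle is synthetic, passing tests
demonstrate that the machinery recovers planted truth under realistic
conditions — not that it reproduces the original supplementary sequences,
which are not redistributed here. A single gene-length alignment (~100
codons) pins down the selected-class size well but $\omega_s$ only loosely;
parameter-recovery guarantees are therefore stated as medians over
replicates at 300 codons (median $|\hat\omega_s - \omega_s|/\omega_s \le
25\%$ over 20 replicates in the suite).

# Problem sizes and numerical choices

Test and example workloads use 5-taxon trees, 90–500 codons, $2\times10^4$
backcross replicates, and 50-replicate calibration loops — sizes chosen so
the whole suite exercises every claim in minutes on a single core while
keeping Monte-Carlo standard errors well inside the asserted tolerances.
Other conventions: codon frequencies floored at $10^{-6}$; site
likelihoods floored at $10^{-300}$ before logs; negative NJ branch lengths
clamped to 0; $\omega_s$ capped at 50 (25 on the BEB grid); report
percentages rounded half-up; JSON reports carry no timestamps so identical
configurations reproduce byte-identical output.

# Known limitations

* The retention model ignores crossover interference and the possibility
  of regaining donor chromatin beyond the first flanking crossover; both
  effects are small at 16 generations but real.
* Origin calling assumes error-free haplotypes; there is no probabilistic
  ancestry HMM or genotype-error model.
* The M8/M8A engine fixes $\kappa$ and relative branch lengths at their
  M0 estimates (with a free global scale); exact numeric replication of
  CODEML internals is a non-goal, and branch-site models are not
  implemented.
* BEB averages over two parameters only, as described; with very short
  alignments its tiers are conservative rather than exact.
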