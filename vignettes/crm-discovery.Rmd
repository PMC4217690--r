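---
title: "Alignment-free CRM discovery: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free CRM discovery: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmscout)
```

# The problem

Cis-regulatory modules (CRMs, enhancers) diverge in sequence far faster
than the genes they regulate. Between insect orders separated by
250--350 Myr, orthologous enhancers typically cannot be aligned at the
nucleotide level at all, yet they often retain a recognisable
*composition*: clustered binding sites for the same transcription
factors, at similar densities. `crmscout` implements a supervised,
alignment-free approach built on that observation:

1. **k-mer scorers** rate how similar a 500-bp window's word composition
   is to a training set of functionally related CRMs versus background;
2. a **genome scan** turns the scorer into a score profile, and windows
   are called candidate CRMs by global and local score rank near genes of
   a homology-mapped expression gene set;
3. a **hypergeometric evaluation** asks whether the genes nearest the
   top-scoring windows are enriched in that expression gene set;
4. **Regulus** scores the motif-composition similarity of two individual,
   unalignable sequences with a probabilistic model, so a newly found CRM
   can be mapped back to the gene locus likely to harbour its homolog.

# The three window scorers

All three are trained on a positive CRM set $C$ and a background set,
count overlapping words on both strands, and score a window as the mean
of its forward and reverse-complement scores, making every score
strand-invariant (enhancers work in either orientation; the training
literature does not fix an orientation convention).

**msHexMCD.** Hexamer counts $N_w$ from $C$ are smoothed with
single-mismatch neighbours, $\tilde N_w = N_w + 0.25\sum_{w'} N_{w'}$
(the sum over the $3k = 18$ one-mismatch words), and the smoothed table
trains a fifth-order Markov chain $M^+$; an analogous chain $M^-$ is
trained on background. The window score is the log-likelihood ratio
$\log \Pr[S\mid M^+] / \Pr[S\mid M^-]$. Conditionals carry a pseudocount
(default 0.01) so no window scores $-\infty$; the smoothing weight 0.25
and word length 6 are arguments with these defaults.

**msIMM.** The same likelihood ratio with interpolated Markov models: at
each context the order-$j$ conditional is blended with the order-$(j-1)$
one, with weight 1 when the context was seen at least 400 times and
otherwise proportional to a $\chi^2$ confidence that the two
distributions differ (weight zero below confidence 0.5). Both thresholds
are arguments. The first `order` bases of a window are scored with the
corresponding lower-order conditionals in both model types, so a
window's likelihood is well defined without dropping bases.

Per-order count tables for *both* model types are trailing-base
marginalisations of a single top-order table. This keeps the orders
mutually consistent and has a useful analytic consequence: when every
context is saturated (count $\ge 400$), the IMM collapses exactly onto
the fixed-order maximum-likelihood chain, which the test suite checks to
$10^{-9}$.

**PAC-rc.** For every hexamer $w$, $n_w$ is its count in $C$ and
$\lambda_w$ its background count scaled by the ratio of total training
to background length (a deterministic emulation of a size-matched
background; equivalent in expectation to resampling, and reproducible).
The window score is
$$\mathrm{PACrc}(S) = \frac{1}{|W|}\sum_{w\in W} F(\lambda_w,\,n_w-1),$$
with $F$ the Poisson CDF and $F(\lambda, -1) = 0$. $W$ is taken to be
the set of distinct reverse-complement-collapsed words occurring in the
scored window $S$ -- the score has no other dependence on $S$, and the
distinct-word reading follows the additive word-count score this
statistic descends from. $\lambda_w$ is floored at $10^{-6}$ so absent
background words cannot divide by zero.

# Scanning, ranking, and candidate calling

The genome is scanned in 500-bp windows at a 250-bp step (the window
width is the published operating point; the step is not stated anywhere
we could find, and 250 bp -- half a window -- is the natural overlap
choice; both are arguments). Windows with more than 10% N are masked and
excluded from scoring and ranking. Soft-masked lowercase bases are
treated as ordinary sequence.

A window is a **candidate CRM** when all four criteria hold:

1. the dataset/model pair is *amenable* (evaluation P value
   $\le 10^{-5}$);
2. the window lies within 20 kb (edge-to-edge, 0 when overlapping) of a
   gene of the expression gene set;
3. its global score rank is within the top 0.5% of all windows;
4. its local rank within $\pm 50$ kb of that gene is at most 2.

Global ties are broken by (contig, start) so ranking is a deterministic
total order. Before local ranking, overlapping windows are merged by
non-maximum suppression (best window of a peak survives): a single score
peak spans two overlapping windows at a 250-bp step, and without
suppression one peak would occupy both of the top-2 local slots. Whether
the original analysis ranked before or after merging is not derivable
from the published window counts; suppression is the reading under which
"local rank $\le 2$" means "one of the top two *peaks*", which is the
stated intent. Gene distance is measured to the gene *body* rather than
the TSS, matching the intergenic framing of the 20-kb criterion.

# The evaluation P value

Walking windows in global rank order, each window's nearest gene in the
universe $U$ (all genes with a homolog) is collected until the set $P$
holds 200 distinct genes; with $n = |P \cap G|$ the evaluation P value
is the upper-tail hypergeometric probability of drawing at least $n$
members of $G$ in $|P|$ draws from $U$. The tail includes $n$ itself
(the standard enrichment convention; the source text says only
"hypergeometric test", and the inclusive tail is the conservative
choice). Genes outside $U$ are invisible to the nearest-gene step, so
windows near non-universe genes do not distort the sample. Reported
percentages from the confusion matrix are rounded half-up (so
$5/8 \to 63\%$), not banker's-rounded.

# Regulus

Two sequences $x, y$ are modelled as emissions of a zeroth-order HMM
with one state per motif (emitting a whole PWM-distributed site) and a
background state (emitting one base). Transition probabilities depend
only on the state being entered. Per-motif densities are estimated by
Baum--Welch on a training CRM set (initial density $10^{-3}$,
convergence at $10^{-6}$ log-likelihood improvement, 200-iteration cap)
and then rescaled by one constant so their mean is 0.001 -- with $k$
motifs the motif transitions sum to $k \times 0.001$ -- and the
remaining mass enters the background state. Background emissions are the
base frequencies of the supplied sequences (with a +1 Laplace count so
no base has probability zero on small inputs).

Under the null model both sequences are generated independently by this
HMM; under the homology model the probability of a joint hidden path $T$
is reweighted by $\varphi(T) = \varphi^{\sum_m \min(n_m^x, n_m^y)}$ with
$\varphi = 5$ by default -- paths in which the two sequences share sites
of the same motifs are up-weighted exponentially in the number of shared
sites. Both models condition on the observed sequence lengths (the
generative process runs until the predetermined length is emitted), so
the score reduces to
$$\mathrm{LLR} = \log \frac{E_{\text{emission}}[\varphi(T)]}
                           {E_{\text{path}}[\varphi(T)]},$$
expectations over the length-conditioned path distribution with and
without the sequence emissions. Setting $\varphi = 1$ makes both
expectations equal and the score identically zero, a property the tests
verify to machine precision.

**Computation.** Per-motif site-count distributions are computed by a
positional dynamic program over (position, count), in scaled linear
space with per-row offsets so long sequences cannot underflow. With at
most 3 motifs the expectations are evaluated *exactly* over the joint
count-vector distribution; with more motifs a per-motif factorisation is
used (exact for one motif, and treating motif-count marginals as
independent otherwise). The mode is recorded in every score object.
Counts are capped at 8 per motif (at the calibrated density of 0.001 a
500-bp window expects ~0.5 sites per motif, so the pooled tail is
negligible; a warning fires if it exceeds $10^{-3}$ of the mass). Each
motif state emits either orientation of a site with probability 1/2. A
brute-force path-enumeration oracle (`regulus_brute_force()`) implements
the literal model definition for short sequences and anchors the test
suite.

`map_crm_to_loci()` slides a CRM-length window (step = half a window)
across each candidate gene locus and ranks genes by their best window
score; the locus-side path distributions depend only on window length
and are cached, as are the CRM-side distributions.

# Binding-site annotation and MoCS

Sites are annotated where the LLR of a $k$-bp window against a uniform
background strictly exceeds 0.5 times the LLR of the motif's optimal
site ("greater than" is implemented as a strict inequality, as printed);
site strength is $10 \times \mathrm{LLR}/\mathrm{maxLLR}$. PWMs are read
as 4-row count matrices with a per-cell pseudocount of 0.5 (the upstream
motif databases do not publish their pseudocounts). The 1-kb flanking
convention for annotating CRMs in genomic context is available as the
`--extend` flag of the `annotate` subcommand. MoCS casts a sequence as
the vector of thresholded site counts per motif and reports the cosine
of two such vectors; the precise vectorisation behind the original
cosine score is not published, and site counts are the documented choice
here.

# The synthetic benchmark

`build_benchmark()` generates the package's fully synthetic study
conditions: a 1-Mb i.i.d. uniform-composition genome carrying 80 genes
(2-kb bodies, evenly spaced), of which every 8th is flagged as an
expression-set gene; 20 planted 500-bp CRMs placed 0.5--4 kb from
flagged genes (so the flagged gene is each CRM's nearest gene); 50
training CRMs from the same generative process; and a 100 x 1-kb
background set. CRMs carry 14 sites sampled from 5 synthetic PWMs
(consensus dominance 0.95, length 8) at random positions and strands --
a site density comparable to densely annotated blastoderm enhancers, and
the density at which the package's prescribed generator calibration
(truth-CRM scores at least 3 background standard deviations above
background, AUC > 0.9, for all three scorers) holds with margin. Flagged
genes are spaced ~100 kb apart so each local-rank neighbourhood contains
only its own gene's CRMs. Bundles are byte-identical for identical
seeds.

Because the synthetic genome carries 80 genes, benchmark-scale
evaluations use $|P| = 20$ instead of the genome-scale default 200
($|P|$ must be well below $|U|$); the function default remains 200.

What the generator does *not* emulate: real genome base composition,
repeats, GC heterogeneity, gene structure (introns/UTRs), ortholog
phylogeny, or expression-pattern structure. Passing tests on this
benchmark demonstrate that the machinery is correct and that the method
recovers signal under its own model assumptions -- not that real
genomes, where background k-mer structure is far richer, will behave as
cleanly. An order-2 Markov background mode would narrow that gap and is
a natural extension.

# Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at the
benchmark scale above (a 1-Mb scan is ~4,000 windows) and Regulus
locus mapping at 20 trials of 10 x 1.5-kb loci against a 400-bp CRM --
sizes chosen so the whole suite completes in a few minutes on one CPU
while still exercising every code path at meaningful depth. All
likelihood arithmetic is in log space or scaled linear space;
k-mer tables are dense vectors indexed by 2-bit-packed word codes;
chain scanning uses rolling sums over precomputed per-position
log-ratios, which the tests pin to the per-window scorer to $10^{-9}$.
Degenerate inputs are defined rather than left to chance: empty
profiles, all-N windows (an error in PAC-rc, exclusion upstream),
unseen contexts (uniform fallback at pseudocount 0), absent background
words (the $\lambda$ floor), and zero-motif HMMs (background-only
chain rule) all have tested behaviour.

# Known limitations

- The factorised Regulus mode ignores cross-motif coupling induced by
  $\varphi$; it is exact for one motif and an approximation otherwise
  (the exact joint DP is used automatically up to 3 motifs).
- PAC-rc separates planted CRMs from background more weakly than the two
  likelihood-ratio scorers on the uniform background; it relies on
  strong word overrepresentation, which the i.i.d. background provides
  only through the planted sites.
- Amenability at the genome-scale $10^{-5}$ threshold is not reachable
  on very small gene universes; scale $|P|$ and the threshold together
  when working with miniature fixtures.
- No multiple-testing correction is applied across training sets; the
  fixed $10^{-5}$ threshold is the published operating point.
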