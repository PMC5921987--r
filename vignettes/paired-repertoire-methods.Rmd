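---
title: "Models and methods behind pairem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pairem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairem)
```

pairem simulates and analyses natively paired antibody heavy/light-chain
(HC-LC) repertoires produced by emulsion overlap-extension RT-PCR of rough-ER
microsomes. This vignette is the package's account of the underlying models,
the parameters that matter, the numerical choices, and what the simulator does
and does not capture about real data.

## The generative model

**Clonal repertoire.** A repertoire of $n$ clones gets rank power-law cell
fractions $f_i \propto i^{-a}$ (default $a = 1.2$, chosen so that with ~1,000
clones the ten most abundant pairs carry roughly half of the reads, the
regime repertoire studies of this design describe as "skewed"). Each clone
also receives a log-normal *secretion weight* (default sdlog 0.5) that scales
its expected microsome yield: the encapsulated unit is antibody mRNA mass,
not the cell, so cells with a larger secretory ER contribute more templates.
Each clone is one heavy and one kappa rearrangement built from a toy germline
reference: the full V segment up to its conserved cysteine codon, a random
in-frame junction (heavy CDR3 of 11-13 codons, kappa 9-11, drawn from the 61
sense codons), the J segment from its conserved Trp/Phe codon onward, and a
60-nt constant-region tag (IgM or IgG for heavy, IgK for kappa). Junctions
are anchor-inclusive, so every CDR3 translation starts with C and ends with
W or F, and all simulated clones are productive.

**Toy germline reference.** `build_toy_reference()` makes VH1..VH7 and
VK1..VK6 families (one segment each, 50 codons), two J segments and the three
constant tags per locus. Families split into two superfamilies per chain;
members of a superfamily derive from one ancestor, keep a fixed 48-nt
exact-match window (nt 49-96) and diverge 10% per nt elsewhere. This makes
two properties controllable and testable: pairwise identity within a
superfamily strictly exceeds identity across superfamilies, and
within-superfamily V genes always share an exact window longer than the
default 30-nt chimera-formation window while cross-superfamily V genes
essentially never do. Anchors travel with the FASTA headers as pipe-delimited
`key=value` fields (0-based codon indices, half-open conventions internally;
1-based only at I/O boundaries).

**Encapsulation.** `simulate_emulsion()` draws cells per clone
(multinomial), microsomes per cell (Poisson with the clone's secretion
scale), then assigns each of the $M$ microsomes uniformly to one of
$M/\lambda$ droplets, giving Poisson($\lambda$) occupancy. One assembly is
produced per microsome: the heavy template is the microsome's own, the light
template is drawn uniformly from the occupants of the same droplet
(including itself). Co-encapsulated microsomes of the *same* clone therefore
never mispair, matching the biology (same-cell templates pair correctly).
Conditioning on a microsome, its co-occupants are Poisson($\lambda$), so the
expected mispaired fraction is

$$\mathrm{E}[\text{mispair}] \;=\; \sum_{j\ge 1} \mathrm{Pois}(j;\lambda)\,
\frac{j}{j+1}\,\Bigl(1-\sum_c w_c^2\Bigr),$$

with $w_c$ the clone fractions of the microsome pool
(`expected_mispair_fraction()`, truncated at six co-occupants; the truncation
error is below $10^{-4}$ for $\lambda \le 1$). The tests verify the simulator
against an independent enumeration of droplet compositions at
$\lambda \in \{0.01, 0.05, 0.2\}$ and check monotonicity in $\lambda$. Two
switches support controlled experiments: `force_single_occupancy` (one
microsome per droplet, the zero-mispair limit) and
`ambient_contamination_rate` (an assembly's light template is replaced from
the pooled marginal with probability $c$, modelling free-mRNA carry-over; it
is the knob behind the spike-in accuracy checks at $1-c$). *Open mode*
removes the compartments entirely: heavy and light are drawn independently
from the pooled clone marginals, the independence null that emulsification is
supposed to beat.

**Amplicon layout and reads.** An assembly is
`LC(V->C) + 30-nt overlap linker + reverse-complemented HC(V->C)`, ~570-580 nt
in total, so read 1 (250 nt from the 5' end) covers the light V, CDR3 and
~40 nt of the IgK tag, while read 2 (reverse complement of the 3' end) covers
the heavy chain in sense orientation. The pipeline never assumes this layout
-- orientation is recovered per read from the constant-region scan, and
annotation is invariant under swapping or reverse-complementing mates.
Substitution errors land uniformly at `seq_error_rate` (default 0.1%,
MiSeq-like); qualities follow a mean Phred profile declining linearly 35 to
25 across the read with Gaussian jitter (sd 3), enough to exercise the
quality filter without modelling a real instrument. Indel errors are not
simulated. Ground truth (source clones, droplet, chimera flag) rides in the
read headers as `key=value` tokens.

**Nested-PCR chimeras.** `apply_nested_pcr_chimeras()` models template
switching as a light-partner swap: each amplicon recombines with probability
`chimera_base_rate` when at least one amplicon from a *different* clone
shares an exact `chimera_identity_window` (default 30 nt) between the two
heavy V genes, and at `base/30` otherwise; the recombinant takes the light
cassette of a partner drawn uniformly from that pool (one round, pre-swap
state). Drawing partners from different clones only is deliberate: a swap
between same-clone amplicons is unobservable, and the model's planted rate
then equals the observable chimeric fraction, which keeps the simulator's
truth tags exactly interpretable. The defaults reproduce the qualitative
finding the model is built around -- same-superfamily amplicons form chimeras
at the planted base rate while the cross-superfamily amplicon stays near the
residual floor -- with the rates themselves config-driven, not calibrated to
any measured value.

## The analysis pipeline

**Quality filter.** A pair is kept when, in *each mate separately*, at least
50% of bases reach Phred 10, boundaries inclusive (125 of 250 passing bases
passes). The per-mate reading is the strictest interpretation of a
"50% of all nucleotides" rule; both the threshold and fraction are
parameters.

**Constant-region scan and structure filter.** Seed-and-extend Hamming
search of both strands for the 20-nt prefix of each constant tag, tolerating
2 substitutions (configurable). Constant tags are primer-adjacent invariant
sequence, so full alignment would add nothing. Ties break by fewest
mismatches, then earliest position, then isotype order IgM, IgG, IgK. Pairs
classify as HC_LC / HC_HC / LC_LC / NO_CONSTANT; only HC_LC survives, and
the report satisfies the accounting identity
`input = fail_quality + sum(classes)` on every run.

**V/J assignment and CDR3 extraction.** Local alignment with match +1,
mismatch -1, gap -2; the best-scoring candidate wins, ties going to the
lexicographically smallest segment id; calls below `min_v_score = 60` /
`min_j_score = 20` are no-calls. `align_segment()` scores every candidate
exhaustively. The batch driver first shortlists candidates by exact 24-nt
seed hits (Aho-Corasick across all candidate seeds) and aligns only the
shortlist, falling back to exhaustive scoring for reads without any seed hit;
a property test checks the batch path against the exhaustive path on
simulated reads. CDR3 = the nucleotides from the projected V cysteine codon
through the projected J Trp/Phe codon inclusive; anchors are projected
through the alignment, and reads whose winning alignment contains indels or
does not cover an anchor codon are rejected rather than guessed (at the
simulated error rates this costs well under 1% of reads). Frame comes from
the V anchor. `translate_and_check()` flags a junction unproductive iff its
length is not a multiple of three or the translation contains a stop; the
anchor-residue property (starts with C, ends with W/F) is tracked separately
as `anchored` so that the productivity rule stays exactly the stated one.

**Clonotypes.** Reads collapse into exact groups keyed by (V family, J gene,
CDR3 nt). Absorption then merges a minor group into a major when the CDR3s
have equal length, differ by at most 1 substitution, the key agrees and the
major:minor ratio is at least 10:1 -- a standard UMI-free PCR-error
heuristic; the parameters are defaults, not measured values, and are
configurable. Absorption is a single pass in descending original-count order
(ties by sequence), a minor joins the first qualifying major, absorbed groups
never absorb others, and counts are conserved by construction; the pass is
order-insensitive because ordering depends only on counts and sequences. The
read-support filter (>= 2 reads, both chains productive) applies at the
*pair* level after chain-level clustering, resolving the order the two
filtering statements leave open; frequencies renormalize over retained pairs.

**Statistics.** Pairing matrices are *read-level* percentages (the heat maps
are captioned as percentages of reads, so read weighting is the faithful
choice); light-chain promiscuity is counted at nucleotide-CDR3 clonotype
level over filtered pairs with an amino-acid option; longitudinal LC
concordance compares each shared heavy CDR3's single most frequent light
partner per sample at amino-acid level (the top-1 framing; nt identity is
stricter than the data support). The chimera report gives both the
read-weighted aggregate (total chimeric / total assigned) and the unweighted
mean over ordered amplicon pairs, since an aggregate like "average chimera
formation" admits both readings; the per-pair matrix is always emitted so any
other aggregation is computable. Source assignment for the defined-amplicon
experiment uses nearest Levenshtein distance with ties excluded and a
threshold of 25% of the CDR3 length, which separates four designed clones
robustly at MiSeq-like error rates.

## What the simulator does not capture

No indels, no position- or context-dependent error spectrum, no quality-error
coupling, no primer or amplification bias beyond the secretion weight, no
somatic hypermutation or allelic variation, no D segments (folded into the
random junction), no UMI handling, and a toy germline far smaller than IMGT.
Passing tests therefore demonstrate that the pipeline's logic is correct
under the stated generative assumptions -- filter accounting, anchor
projection, clustering conservation, Poisson mispairing, identity-dependent
chimerism -- not that it matches any particular instrument's error process or
a full human germline.

## Problem sizes and determinism

The shipped checks run at desk scale, chosen to keep each scenario's
binomial 3-sigma bands tight enough to be informative: ~10,000 microsomes for
the three-clone emulsion scenario, 50,000 assemblies per lambda for the
mispairing-recovery checks, 90,000 open-mode assemblies for the independence
null, 4 x 1,500 reads for the chimera experiment, and ~20,000 microsomes for
the spike-in scenarios. Every stochastic stage derives its RNG stream from
the single run seed (stage offsets keep streams independent and below
$2^{31}$), so a rerun with one seed is byte-identical, including the FASTQ
output -- which is written uncompressed by default precisely so that
byte-identity is directly checkable.
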