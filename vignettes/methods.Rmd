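---
title: "Methods: transcriptome annotation and color-morph expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome annotation and color-morph expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymorphome)
```

`polymorphome` implements the computational stages that sit downstream of a
de novo transcriptome assembly of a non-model arthropod — here motivated by
color-polymorphic theridiid spiders, where whole-body RNA of pooled Yellow
(unpatterned) and Colored (patterned) morphs is sequenced for two species.
The package covers five analyses: coding-potential classification of
contigs, lowest-common-ancestor (LCA) filtering of contaminant
("meta-transcriptome") sequences, reciprocal-best-hit (RBH) detection of
pigment-pathway homologues, housekeeping-gene-anchored differential
expression between morphs, and Dollo-parsimony reconstruction of
gene-family gains and losses. A seeded synthetic-data generator produces
inputs with recorded ground truth for every stage, so the whole pipeline is
testable without any sequencing data.

## Coding-potential classification

Protein-coding sequence has biased hexamer composition; non-coding sequence
does not. The classifier exploits this with a 5th-order nucleotide Markov
chain (a "hexamer model"): 6-mer counts over a training set give the
conditional probability of each base given its preceding 5-mer, with
additive smoothing `(count + c) / (total + 4c)` (default pseudocount
`c = 1`), so unseen contexts fall back to the uniform 0.25. Windows
containing `N` are skipped during both training and scoring.

Training is unsupervised: the 500 longest complete open reading frames
(ORFs) found in all six reading frames of the dataset — long ORFs are very
unlikely to arise by chance, so they are almost surely genuine genes — are
used to fit the coding model. The same ORFs, each shuffled by a seeded
permutation of its bases (which preserves mononucleotide composition
exactly while destroying hexamer structure), train the null model. Each
transcript's candidate ORF is the one maximizing the log-likelihood ratio
(LLR) of coding versus null model, summed over every position from the 6th
base on.

An ORF here runs from the first ATG after a stop codon (or the frame
start) to the next in-frame stop, stop included; codons containing `N` are
never treated as start or stop but do not break the frame. Only complete
ORFs are used by default — a transcript truncated before its stop codon can
be admitted with `allow_partial = TRUE`, but complete ORFs are the
conservative default for training material. The minimum ORF length is 100
aa (about 300 bp), below which random open frames become common.

The coding call requires (i) a positive LLR and (ii) that the candidate's
reading of the span strictly out-score the reverse-complement reading.
A six-way frame comparison is *not* used, deliberately: for a
sliding-window 5th-order model the three same-strand frames of a span score
identically apart from one or two boundary windows, so they carry no frame
information and comparing against them would reject true ORFs essentially
at random (in development this halved the true-positive rate). The two
strands, by contrast, present genuinely different hexamers. Ties are broken
deterministically everywhere (LLR, then ORF length, then coordinate).

One property of the synthetic benchmark deserves emphasis. With
`coding_bias = 0` the generator's coding and non-coding hexamer sources are
identical, and the LLRs of independently generated coding batches are
exchangeable — the composition signal is at chance. Classification accuracy
does *not* fall to 0.5, however, because the planted ORFs are structurally
real: an intact 100+ aa reading frame implies in-frame stop-codon
depletion, which the hexamer model legitimately learns from its training
ORFs. Long open frames are evidence of coding in their own right, with or
without composition bias.

## LCA filtering of the meta-transcriptome

Whole-body RNA from wild-caught spiders contains transcripts of parasites,
commensals and surface contaminants. Queries are assigned to taxa from
their homology hits in the MEGAN style with the standard parameters:
minimum bitscore 35; a top-percent window of 10 (hits scoring below 90% of
the query's best bitscore are ignored); minimum query complexity 0.3; and
minimum support 5. The assignment is the lowest common ancestor of the
retained hit taxa. Support is enforced bottom-up: any taxon whose subtree
collects fewer than 5 queries passes its queries to its parent, so each
query settles at its nearest sufficiently supported ancestor and the result
is order-independent; queries that reach the root unsupported become
unassigned.

Sequence complexity is implemented as the Shannon entropy of the
mononucleotide composition divided by log 4 (so 0 for homopolymers, 1 for
uniform composition, `N` ignored). MEGAN's internal complexity measure is
not documented precisely; what is preserved here is the threshold's
semantics — drop low-complexity queries before assignment — and the
default 0.3 cutoff. The top-percent window operates on bitscores, not
E-values, matching MEGAN convention.

Host ("spider") sequences are those assigned within Metazoa but not within
Nematoda — the nematode carve-out exists because these spiders are commonly
parasitized by mermithid nematodes, so metazoan assignments inside Nematoda
are parasites, not host. Everything else assigned is the
meta-transcriptome. The three output sets (spider, meta, unassigned)
partition the queries.

## Homology: reciprocal best hits and fragmentation

Candidate pigment-pathway genes are found by searching reference proteins
(e.g. the *Drosophila* pigment gene set) against the assembly and keeping
reciprocal best hits at E ≤ 1e-5: (a, b) is a pair only if b is a's best
hit and a is b's best hit. Best hits are deterministic: maximum bitscore,
ties by minimum E-value, then smallest subject id. Genes detected only
forward are reported `ONE_WAY`; undetected genes `NOT_DETECTED` — the
three-state notation of pigment-panel survey tables. A case-insensitive
substring keyword search over annotation descriptions ("pterin", "sepia",
"white", ...) backstops genes the RBH step misses.

Assembly fragmentation is indexed by the unique-best-hit fraction: among
contigs with hits at a length cutoff, the share whose best-hit protein is
not the best hit of any other contig. The protein-sharing reading is used —
a contig is non-unique when another contig shares its best subject — since
several fragments of one gene all land on that gene's protein. Comparing
the fraction at 100 bp and 200 bp cutoffs shows how much of the short tail
is fragments.

## Housekeeping-anchored differential expression

The pooled design has no biological replicates, so variance cannot be
estimated from the data at large. The package instead anchors everything to
a housekeeping (HK) set: candidate HK proteins are kept only if their hits
fall in exactly one component (gene) per species, appear in both species,
and are RBH-verified — genes with one unambiguous, shared counterpart.

*Normalization.* Per-sample factors are proportional to the sample's total
HK count, rescaled to geometric mean 1; dividing by them equalizes HK
totals across samples. This is deliberate HK-total scaling rather than TMM:
the HK set is the stated equal-expression anchor, and the factors are
swappable if a different scheme is wanted.

*Dispersion.* A single negative-binomial dispersion `phi`
(variance = mu + phi mu^2) is estimated from the HK genes by maximizing the
NB conditional log-likelihood of the within-class counts given their class
totals, on factor-equalized counts, with a bounded one-dimensional search
of `phi` in [1e-6, 10]. Degenerate inputs (identical counts) drive the
estimate to the lower bound; Poisson data yield estimates below 0.01, and
simulations at `phi = 0.2` with 200 HK genes at mean 500 recover the value
within [0.1, 0.3] in over 90% of runs. Numerical agreement with any
particular edgeR version is not a goal; the estimator is the package's own.

*Testing.* Each panel gene gets an exact conditional NB test: class sums
(the two species act as replicates within Yellow and within Colored) are
modelled as NB with mean proportional to effective class size and size
`n/phi`; conditional on the total, the two-sided p-value sums the
probabilities of all splits no more probable than the observed one
(the "small-p" construction, which is deterministic and checkable against
full enumeration; `phi = 0` reduces to the conditional binomial).
Benjamini–Hochberg FDR is applied within the panel.

*The ±2 SD band.* Fold-changes are `log2((mean Colored + 0.5) /
(mean Yellow + 0.5))` on normalized counts; the 0.5 prior keeps
zero-count genes finite and symmetric. Because p-values from two
pseudo-replicates have little power, effect sizes are read against the HK
fold-change distribution: mean and SD (n−1 denominator) of the HK log2
fold-changes define the band mean ± 2 SD, and a panel fold-change outside
it is taken as likely meaningful. The band classifier reports five classes:
`WITHIN` (inside ±2 SD), `UP`/`DOWN` (2–3 SD beyond the mean) and
`UP_BEYOND_BAND`/`DOWN_BEYOND_BAND` (more than 3 SD), so summaries can
distinguish marginal from decisive departures; "meaningfully regulated" in
the 2 SD sense is the union of the non-`WITHIN` classes on a side. With a
null panel (true fold-change 0) about 95% of genes land `WITHIN`, as the
normal approximation predicts.

## Gene-family evolution

Families are built from an all-vs-all similarity graph (edge weight = the
larger of the two directed bitscores at E ≤ 1e-5; one sequence per
component, the longest isoform) by Markov clustering with inflation 2.0,
the standard setting for protein families. Self-loops are set to each
node's maximum incident weight — the usual regularization — and the
expansion/inflation iteration runs to a 1e-8 column-change tolerance, with
entries below 1e-14 pruned for numerical stability. Clusters are the
attractor systems of the limit matrix; in the rare overlapping case a node
goes to its highest-probability attractor, ties lexicographic, so the
output is always a partition and never crosses connected components.

Family presence/absence profiles across taxa are reconstructed under Dollo
parsimony: a family is gained exactly once and can only be lost afterwards.
The gain branch is the branch above the most recent common ancestor of the
taxa carrying the family (the root edge when that ancestor is the root);
losses are the maximal branches inside the gain clade whose entire leaf set
lacks the family. Any higher gain placement only adds losses, so this is
the minimum-loss single-gain scenario — verified in the tests against
exhaustive search over all gain placements. Per-branch tallies satisfy the
conservation identity `count(child) = count(parent) + gains(child) −
losses(child)` along every edge.

## The synthetic-data generator

Every stage is exercised on generated data whose ground truth is recorded
at generation time. One master seed drives independent per-generator
substreams, so outputs are byte-reproducible and adding a generator never
perturbs another.

* **Transcripts** — coding records embed one complete ORF (peptide length
  uniform in 100–300 aa) whose interior is drawn from a hexamer-biased
  source, flanked by 50–200 nt of uniform sequence; non-coding records are
  uniform sequence at matched lengths. The bias is a per-context mixture of
  the uniform distribution with a Dirichlet(1,1,1,1) draw, weighted
  `bias/(1 + bias)`: at the default `coding_bias = 1` the conditional is an
  even mixture, which produces LLRs comparable to real coding/non-coding
  contrast; at 0 the source is exactly uniform.
* **Hit tables** — 60 mutual-best ortholog pairs with weaker secondary
  hits, 20 one-way decoys, 10 fragment groups of three short (100–199 bp)
  contigs sharing one subject, and 60 plain queries; each query is tagged
  contaminant with probability 0.2, sending its hits to bacterial, fungal
  or nematode taxa of a bundled toy taxonomy.
* **Counts** — four pooled samples (Yellow/Colored × two species); 196 HK
  and 200 background genes at log2 fold-change 0, a 40-gene pigment panel
  with per-gene log2 fold-changes uniform in [1, 3] applied to Colored;
  gene means log-uniform in [100, 2000], sample factors log-normal (sd
  0.2), counts NB with common dispersion 0.2 (Poisson at 0). These mirror
  the replicate-free two-species design and a moderately overdispersed
  pooled library.
* **Family profiles** — per family a uniform gain branch, then independent
  per-branch losses (probability 0.2) below it, lost clades going entirely
  absent; draws that would empty a profile are redrawn, since an all-absent
  family is unobservable.

What the generator does **not** emulate: isoform structure and multi-contig
genes, real codon usage and GC heterogeneity, E-value/bitscore dependence
on alignment length, read-level sampling (counts are drawn at the gene
level), correlated contamination (contaminants are independent across
queries), and family-size-dependent loss rates. Passing tests therefore
demonstrate correctness of the algorithms under the stated models, not
performance on any particular real assembly, whose headline numbers depend
on the sequenced libraries and reference databases.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest sizes
chosen to make the statistical checks sharp but quick: 200 + 200
transcripts for classifier accuracy (training on up to 500 ORFs), 500
random sequences for the ORF-finder oracle, exact-test enumeration to
totals of 200, 20 seeded simulations of 200 HK genes at mean 500 for
dispersion recovery, 500 random profiles on trees of up to 8 leaves for
the Dollo oracle. Tolerances: hexamer conditionals normalize to 1e-9;
normalization-factor geometric mean to 1e-12; exact-test oracle agreement
to 1e-10; the dispersion search tolerance is 1e-8 on the log scale.

## Known limitations

The complexity filter approximates MEGAN's undocumented measure; the
dispersion estimator targets the conditional-likelihood construction, not
bit-compatibility with any edgeR release; the exact test rounds equalized
class sums to integers, which matters only for tiny counts; MCL is a dense
implementation suitable for the graph sizes of a two-species comparison,
not for millions of sequences; and the band classifier's 2 SD edge is a
descriptive device, not a significance statement — with two pooled
pseudo-replicates no procedure here can deliver real statistical power,
which is precisely why the band exists.
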