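---
title: "The online run-sampling model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The online run-sampling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srasampler)
```

## The problem

Public read archives hold orders of magnitude more RNA-Seq than a genome
annotation project can download or align. The runs are heterogeneous:
expression is tissue- and condition-specific, some libraries are mislabeled
genomic DNA, some barely align. Choosing a subset by reading metadata does
not work well — the data itself has to be examined. `srasampler` implements
an online algorithm that alternates between downloading a small batch of
reads from one run, aligning and scoring it, and using everything seen so
far to decide which run to sample next, so that a fixed budget of batches
covers as many transcribed regions as possible.

## Objective and greedy rule

Because the true set of transcripts is unknown in this setting, transcribed
units are approximated by fixed-size genome tiles (default 5 kb windows,
`tile_index()`). With $c_j$ the number of uniquely aligned spots (reads or
read pairs) whose representative alignment starts in tile $j$, the objective
is

$$S(\mathbf c) = \sum_{j=1}^{T} \ln(1 + c_j).$$

The logarithm encodes diminishing returns: the tenth read on an empty tile
is worth more than the thousandth on a covered one, which is what pushes the
sampler towards runs complementary to what it already has. One step of the
algorithm chooses the run

$$r^{*} = \arg\max_{r} \; S(\mathbf c + b\,\hat q_r\,\hat{\mathbf p}_r),$$

the run maximizing the score of the *expected* count vector after one more
batch of $b$ spots. $\hat{\mathbf p}_r$ estimates where a random read of run
$r$ aligns and $\hat q_r$ estimates how much of a batch aligns usefully. The
expected counts are real-valued; $\ln(1+x)$ is applied to reals, no rounding.

The profile estimate smooths the run's own observed tile counts $c^r_j$
with pseudocounts towards the archive-wide tile frequency $\bar p_j$
(relative frequency of tile $j$ over all sampled batches of all runs):

$$\hat p_r[j] \propto c^r_j + \lambda\,T\,\bar p_j + a,$$

normalized to sum to one. With the defaults $\lambda = 10 \gg a = 1$, a run
with few sampled reads is assumed to look like the archive average, and its
estimate moves towards its own empirical profile as evidence accumulates.
When nothing has been aligned anywhere, $\bar p$ is taken uniform — the only
symmetric choice.

$\hat q_r$ is a weighted sum of the run's cumulative fractions of uniquely
aligned and spliced spots, pooled over all its batches (never a mean of
per-batch fractions). The weighting is configurable; the default
`q_weights = c(unique = 0.9, spliced = 0.1)` reflects that unique
alignability dominates a run's usefulness while the spliced fraction is a
smaller, genome-dependent signal — the exact weighting used by the original
C++ tool is unpublished, so it is exposed as a parameter rather than
hard-coded.

### Ties and exploration

Runs never sampled share one profile estimate and the optimistic initial
quality $\hat q = 1$, so their expected scores tie exactly and the sampler
explores them before re-sampling known runs. Ties (within a relative
tolerance of $10^{-12}$ — exact floating-point equality would be
meaningless) are broken by a categorical draw with probability proportional
to average read length, biasing towards longer reads; the functional form of
that bias is a design choice here, since only its direction is documented
for the original. Missing read lengths are imputed as the catalogue median.
Runs with identical estimates are evaluated once per class, not per run.

## Accounting rules

One *spot* (read, or read pair) is classified exactly once per batch as
uniquely aligned, multi-mapped, or unmapped — the three counts always sum to
the spots downloaded. Uniqueness is the `NH` tag equal to 1 where present,
with a mapping-quality ≥ 30 fallback for aligners that do not emit `NH`.
Only uniquely aligned spots enter coverage: multi-mapper placement is
unreliable and low-unique runs are already down-weighted through
$\hat q_r$. A paired spot counts once, through its leftmost-mapping uniquely
aligned mate, and a spot spanning a tile boundary counts only for the tile
of its leftmost aligned base — tiles are a coarse proxy, and single-count
conservation keeps the per-tile increments summing to the unique count.
Secondary and supplementary records are ignored; malformed CIGAR strings and
out-of-reference positions degrade to unmapped with a warning.

A run whose *first* batch has fewer than 5% uniquely aligning spots is
permanently blacklisted; a run at exactly 5% is kept (the threshold is a
minimum requirement). This catches mislabeled genomic libraries and
unalignable chemistry early, at the cost of one batch. A zero-spot first
batch also blacklists. Independently, three *consecutive* fetch failures
blacklist a run so that dead accessions cannot stall the loop.

Downloaded spot ranges are tracked per run as disjoint half-open intervals;
the next batch always starts at the lowest spot not yet downloaded, so no
spot is fetched twice and, with unlimited budget, every spot is requested
exactly once. A range request truncated at the run's end is committed at its
actual size and marks the run exhausted.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `tile_size` | 5000 bp | tile width; proxy granularity for transcribed units |
| `batch_size` (b) | 50 000 spots | spots per downloaded batch |
| `lambda` | 10 | pull of the profile estimate towards the archive profile |
| `pseudocount` (a) | 1 | floor making every tile possible for every run |
| `max_batches` | 1000 | total batch budget of one execution |
| `q_weights` | (0.9, 0.1) | weight of unique vs spliced fraction in \(\hat q\) |
| `q_init` | 1 | optimistic quality of never-sampled runs (drives exploration) |
| `blacklist_threshold` | 0.05 | minimum unique fraction of a first batch |
| `tie_rel_tol` | 1e-12 | relative tolerance for score ties |
| `mapq_unique` | 30 | MAPQ cutoff when no NH tag is present |
| `max_failures` | 3 | consecutive fetch failures before blacklisting |

## Intron-level evaluation

The usefulness of the sampled alignments for annotation is measured on
introns. The reference is the set of introns between consecutive CDS parts
of each transcript of a GFF3 annotation (coding introns are annotated more
reliably than UTR or non-coding ones); the prediction is the set of introns
induced by `N` CIGAR operations of uniquely aligned spliced reads. Both are
sets over coordinate pairs — each intron counted once. Sensitivity is the
fraction of reference introns predicted; specificity the fraction of
predicted introns in the reference. Identity ignores strand by default,
because inferring the strand of a spliced alignment requires splice-site
sequence context that is out of scope here; a strand-aware mode exists where
predicted introns carry strand. `accuracy_curve()` recomputes both measures
after every batch in download order; since the predicted set only grows,
sensitivity is non-decreasing, while specificity typically decays once novel
false introns accumulate faster than new true ones.

## The simulator: what it emulates, what it does not

`build_archive()` materializes a deterministic archive: random
single-transcript gene models laid out across the configured genome, and
runs that express the genes under multinomial profiles drawn from a
symmetric Dirichlet (default concentration 0.1 — strongly skewed,
tissue-like). Defaults place about one gene per 5 kb tile on a 1 Mb genome
(200 genes, exons of 150–400 bp, introns of 60–200 bp, intergenic gaps of
0.5–4.5 kb), a density comparable to compact eukaryotic genomes. A
configurable fraction of runs is "bad": either 97% of spots unmapped or
multi-mapped (low-alignability chemistry), or uniquely aligned but placed
uniformly on the genome without splicing (a genomic library mislabeled as
transcriptomic). Reads are emitted as already-aligned records — spot picks a
gene from the run's profile, a start uniform along the spliced transcript,
and the CIGAR gets an `N` exactly where the read spans a true intron — so no
aligner is needed and every induced intron is true by construction.

Deliberately not modeled: sequencing errors and base qualities (the
algorithm only ever sees alignment outcomes, which the quality classes model
directly), isoforms and alternative splicing (one transcript per gene),
paired-end simulation (pair handling is exercised with constructed record
fixtures instead), and strand-specific read placement. Consequently, tests
passing on the simulator demonstrate the selection, accounting and
bookkeeping logic — not robustness to alignment artifacts of real data,
where specificity below 1 and ambiguous multi-mappers are the norm.

## Numerical and degenerate-input choices

Expected counts are kept in exact double arithmetic. Profile estimates with
`pseudocount = 0` and an empty archive fall back to uniform rather than
0/0. An empty reference intron set makes sensitivity `NA` with a warning; an
empty prediction makes specificity `NA` and sensitivity 0. Each simulated
`(run, spot range)` request derives its own RNG stream from the archive seed
and restores the caller's RNG state, so fetches never perturb tie-break
randomness — this is what makes whole executions replay bit-for-bit from one
seed.

## Problem sizes in the test suite

The suite validates the greedy rule against brute-force evaluation on 200
random instances (up to 10 runs, 50 tiles) and the profile estimate against
a scalar-loop oracle on 100 instances. End-to-end behaviour is exercised on
archives of 1–30 runs over 0.1–1 Mb genomes; the policy comparison runs 20
seeds of 100 batches × 1000 spots against 30 runs with Dirichlet(0.1)
profiles over 200 genes on 1 Mb, comparing greedy with uniform-random run
selection at equal budget. At that depth (10^5 reads against ~150 expressed
tiles) the final objective score consistently separates the policies, while
the binary fraction of expressed tiles touched saturates at 1 for both —
touching every tile once is easy at this budget; balancing depth across
tiles is what the objective rewards.

## Known limitations

* The network retrieval and external alignment layer is an adapter
  contract (`function(run_id, range)`), not a tested implementation; wiring
  `fastq-dump` and HISAT2/STAR into it is a thin shell exercise left to the
  deployment.
* Tile counts are kept dense per run; archives of tens of thousands of runs
  with large genomes would want a sparse per-run representation.
* The algorithm is one-step greedy by design: no lookahead, no bandit-style
  confidence bounds.
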