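---
title: "Recognizing splice junctions and cleaning spliced alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing splice junctions and cleaning spliced alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spliced aligners report introns as `N` operations in read CIGAR strings.
A sizeable fraction of those junctions are artifacts - misalignments around
repeats, or transcriptional noise - and they propagate into transcript
assemblies as false exons and transcripts.  `spliceguard` scores every
junction from genomic sequence alone and removes alignments whose junctions
look spurious, improving intron-level precision at a small recall cost.

The package covers the full workflow: junction extraction from SAM/BAM or
annotation, curation of labelled training sets, encoding, the neural network
itself, training, scoring, evaluation metrics, and alignment cleaning, plus
a seeded synthetic-data generator that makes the whole pipeline testable
offline.

## The model

The scoring model is a deep residual convolutional network that reads a
junction as a **pair**: 400nt centred on the donor site concatenated with
400nt centred on the acceptor site (800nt total).  This mirrors how the
spliceosome commits to both intron ends together, and it bounds the input
to the region where the biological signals live: the donor consensus, the
acceptor AG with its polypyrimidine tract, and a branch point 35-40nt
upstream of the acceptor.

Within the 800nt window (0-based coordinates) the donor site - the first
intronic base, the G of GT - sits at position 200, and the acceptor label
position - the first exonic base after the intron, just after the AG at
598-599 - at position 600.  Windows are always extracted in transcription
sense; for introns shorter than 400nt the two intronic flanks overlap, for
exactly 200nt they coincide, and for shorter introns each flank keeps the
whole intron, truncated at the opposite site and padded with Ns on the
intron side.  Sequence beyond a contig end is N-padded.  One-hot encoding
maps A, C, G, T to unit vectors and N to zeros.

The network stacks 20 residual units in five groups of four.  All
convolutions carry F = 64 filters; the units use grouped convolutions with
G = 4 (each output channel sees only its 16-channel group, dividing
parameters by four) and dilations, with per-group window sizes
W = (11, 11, 11, 21, 21) and dilation rates D = (1, 5, 10, 15, 20).  Each
unit applies twice the pre-activation sequence batch-norm, leaky ReLU
(negative slope 0.1), convolution, and adds an identity shortcut.  Every
output position therefore integrates a neighbourhood of
S = sum over units of 2 D (W - 1) = 6,880 positions.

Auxiliary 1x1 convolutions knit the stack together: a stem (4 to 64
channels), a skip projection of the stem output, one projection of each
residual group's output accumulated into the skip sum, one further 64 to 64
convolution on the accumulated skip, and a 3-channel output convolution
followed by a per-position softmax over (neither, acceptor, donor).  The
figure-level description of the architecture leaves the auxiliary layers
unenumerated; the arrangement above is the one whose trainable-parameter
count equals the published total, 651,715, which `count_parameters()`
verifies exactly.  Batch-norm scale/shift pairs count as parameters; running
statistics do not.

## Training objective and schedule

Training minimises the focal loss
`-sum I_c (1 - P_c)^gamma log P_c` with gamma = 2, which down-weights
confidently-correct positions - essential here, since 798 of 800 positions
of every window are "neither".  At gamma = 0 it reduces to cross-entropy
(`cross_entropy()`, `focal_loss()`).  Positive windows carry a 3x loss
weight, compensating the 1:3 positive:negative example ratio of the
curated training sets.  Probabilities are clamped at 1e-12 inside
logarithms.  The loss is averaged over batch and window positions; the
published description does not fix the reduction, and the mean keeps the
loss scale independent of batch size.  The 3:1 weight is likewise applied
per window (not per position or channel), the most direct reading of the
example-level imbalance it compensates.

The optimizer is AdamW with peak learning rate 0.03, a 1000-step linear
warmup and a cosine decay to zero (`lr_at_step()`), batch size 100, and 15
epochs - the published recipe, preserved as the `train_config()` defaults.
Weight decay is unstated in the recipe; the optimizer's conventional 0.01
is used and recorded in the config.  Training is bit-reproducible for a
fixed seed with single-threaded numerics: all randomness (initialisation,
shuffling) flows from R's RNG, and the C++ engine is deterministic.

The engine is hand-written C++ (float32, im2col + BLAS sgemm in a
positions-first layout) with an analytically derived backward pass; tests
check it against finite differences and against a brute-force implementation
of the dilated-convolution sum.

## Dataset curation

Positive junctions come from spliced alignments supported by at least 100
alignments (`filter_by_support()`; the source descriptions waver between
"more than 100" and "a minimum of 100" - the inclusive reading is the
default and the threshold is an argument) and are split into a main class
(present in the single-canonical-isoform annotation) and an alternative
class (present only in the fuller annotation).  Negatives come in two
flavours: Negative-1, junctions with exactly one supporting alignment lying
antisense to a protein-coding locus, and Negative-Random, random canonical
GT-AG pairs antisense to coding loci (`build_negative_one()`,
`build_negative_random()`).  "Antisense to a locus" is evaluated against
every overlapping locus, so junctions inside overlapping genes on both
strands are excluded.

The pseudo-junction generator (`generate_pseudo_junctions()`) implements
the cross-species negative recipe: per locus, up to 20 attempts; each
attempt draws a random start inside the locus, scans forward for the
donor-side dinucleotide (GT on a + target strand, CT on -), draws an intron
length uniformly from [200, 20000], jumps forward, and scans for the
acceptor-side dinucleotide (AG / AC).  The length jump is interpreted as
"the acceptor scan begins at donor + length", so final intron lengths can
exceed the drawn value but never fall below it.

`split_and_sample()` performs the chromosome-held-out split (default:
chr1 and chr9 form the test partition), accepts an externally produced
exclusion list for paralogs (paralog detection itself requires a
whole-genome aligner and is out of scope), and downsamples training
negatives to three per positive with a seeded RNG.

## Scoring, metrics and cleaning

`score_junctions()` encodes and scores junction BEDs; the donor score is
the donor-channel output at position 200, the acceptor score the
acceptor-channel output at 600, and the junction score their minimum - a
junction is only as believable as its weaker site.  A junction is called
positive when its score reaches the threshold (inclusive, so the min rule
coincides with requiring both sites to clear the threshold).
`threshold_sweep()` reports precision/recall/F1 over a threshold grid with
the F1-optimal threshold (ties to the smallest); `curves_and_auc()`
computes rank-based ROC and PR curves with trapezoid areas; when no
junction is called positive, precision is reported as 0 with a degeneracy
flag so sweeps stay plottable.

`clean_bam()` ties the pipeline together: extract junctions from the
alignments, score them, and remove every alignment containing a junction
scoring below the threshold (default 0.1, the cutoff used in the
published filtering analyses; exposed as an argument).  Removal uses exact
(contig, start, end) matching, ignoring strand, because an N operation may
carry no strand tag.  For a removed paired read the surviving mate is
unpaired: flag bits 0x1/0x2/0x8/0x20/0x40/0x80 are cleared and mate
pointers reset - a deliberate, documented reading of "update the flags to
unpair", the minimal self-consistent one.  For a removed multi-mapped read
the NH tag of each surviving alignment of that read end is decremented by
the number of its removed alignments.  `intron_compare()` evaluates
alignment files against an annotation at the unique-intron level:
precision = TP/(TP+FP), recall = TP/(TP+FN) with exact
(contig, start, end, strand) matching.

SAM text handling and CIGAR walking are implemented natively because no
installed R package can rewrite alignment records with modified flags and
tags; BAM input/output goes through `Rsamtools`.

## The synthetic-data generator

`generate_genome()` plants multi-exon genes on both strands of uniform
ACGT background contigs.  Every intron is canonical GT..AG with a
GTAAGT-consensus donor (15% per-position substitution beyond the invariant
GT), a 15-25nt polypyrimidine tract (85% pyrimidine) before the AG, and a
CTAAC-like branch-point motif whose adenosine lies 35-40nt upstream of the
acceptor.  Intron lengths mix the three window-edge regimes (10% in 80-199,
20% in 200-400, 70% in 401-2500).  Decoys are antisense GT-AG pairs found
by the pseudo-junction generator, with no planted signal beyond their
terminal dinucleotides, and never coincide with planted junctions.
Because the background is i.i.d. uniform, decoy density is predictable
(each dinucleotide occurs at rate 1/16) and motif enrichment statistics
have known baselines.

`simulate_spliced_alignments()` writes spliced reads (M-N-M CIGARs) at a
configured coverage per true junction, pairs a fraction of them (reciprocal
mate pointers, proper-pair flags), multi-maps a fraction (secondary
alignment elsewhere, NH = 2), and adds support-1 noise junctions (antisense
decoys and shifted-boundary variants) at a configured rate - the inputs the
cleaning workflow is designed to fix.

What the generator does **not** emulate: realistic base composition,
sequencing errors and quality strings, expression-level variation,
non-canonical splice sites, alternative branch points, or genuine paralogy.
Tests passing on these fixtures therefore demonstrate that the machinery is
implemented correctly and that the network can learn strongly localised
splice signals; they do not certify accuracy on real genomes, which depends
on full-scale training data.

## Desk-scale training demonstration

The full published training regime (hundreds of thousands of windows, 15
epochs, batch 100) is far beyond a test suite.  The package's desk-scale
demonstration instead uses the default training fixture: 2,000 planted
positive windows and 6,000 negatives (antisense decoys plus 8%
shifted-boundary noise), with the last two of four contigs held out, giving
roughly 4,000 training and 4,000 held-out windows.  With only a few
thousand windows, a batch of 100 would allow just a few dozen optimizer
steps - too few for the label-sparse objective to escape the trivial
all-"neither" solution regardless of how separable the fixture is.  The
demonstration therefore shrinks the batch to 16 to keep the number of
optimizer steps in the hundreds, lowers the peak learning rate to 1e-3
(the published 0.03 assumes a ~10^5-step schedule and is unstable over a
few hundred steps - at desk scale it collapses the network into the
degenerate solution, while at 1e-3 an overfitting check learns ten windows
to donor probability 0.998 within 50 steps), uses a warmup of a tenth of
the run, trains a single epoch, and evaluates the min-rule junction score
on a seeded 1,600-window subsample of the held-out contigs, where it is
expected to reach AUC-PR at least 0.95 and near-1 precision across a wide
threshold band.  The `train_config()` defaults keep the full published
recipe.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; GFF (1-based,
  inclusive) is converted at the parser boundary; BED is written 0-based.
  A junction's `start` is the first intronic base and `end` the first base
  after the intron.
* Lowercase genome sequence is uppercased on load; ambiguity codes other
  than N become N (the encoder defines exactly five symbols).
* Channel order is (neither, acceptor, donor) internally; the two published
  descriptions of the label encoding disagree with each other, so all code
  uses the named accessors `channel_index()`/`channel_names()` and nothing
  depends on raw indices.
* Batch-norm uses biased variance for both batch statistics and running
  averages (momentum 0.1, eps 1e-5); at desk-scale batch sizes the
  unbiased correction is negligible.
* Transcripts whose exons overlap are dropped at annotation parsing, with a
  count reported.  Alignments whose CIGAR begins or ends with an N are
  skipped with a warning.  Empty inputs yield empty outputs rather than
  errors wherever a sensible empty value exists.
* Ties in F1 across thresholds resolve to the smallest threshold; AUC uses
  one curve point per distinct score so tied scores are handled exactly.

## Known limitations

* The network engine is specialised to the 3-channel output head; other
  output arities would need a small extension.
* BAM reading keeps the NH and XS tags and drops other optional tags;
  SAM reading preserves all tags verbatim.
* Translation-equivariance of the full stack cannot be observed on 800nt
  inputs because the receptive span (6,880) exceeds the window, so the
  property is verified at the level of individual convolution layers.
* The CLI (`inst/cli/spliceguard`) is a thin wrapper for shell use; the R
  functions are the primary interface.
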