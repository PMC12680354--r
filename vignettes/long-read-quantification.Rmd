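---
title: "Long-read isoform quantification with lrquant: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-read isoform quantification with lrquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrquant)
```

# The problem

Long sequencing reads (Oxford Nanopore, PacBio) often span entire
transcripts, which makes them ideal for isoform-level quantification — but
their per-base error rates (1–10%, with technology-specific mixes of
deletions, substitutions and insertions) defeat the exact k-mer matching
that makes short-read pseudoalignment fast. `lrquant` addresses this with
three coupled changes relative to the short-read recipe: a much longer
k-mer (63 instead of 31), a classification cascade that degrades gracefully
when exact matching fails, and an EM variant that treats uniquely mapping
reads differently from ambiguous ones.

# The index

The transcriptome de Bruijn graph has canonical k-mers as nodes, each
labelled with its transcript compatibility class (TCC) — the set of
transcripts (as 0-based ordinals in reference order) containing the k-mer.
Maximal non-branching runs of identically labelled nodes are compacted into
unitigs; `build_index()` performs this compaction by walking oriented
k-mers from every branch point, and stores a hash from both orientations of
every k-mer to its (unitig, offset, strand) triple.

Why k = 63? Long k-mers simplify the graph: a repeat shorter than k cannot
create a shared node, so fewer unitigs touch and the connected components
shrink (`graph_stats()` reports node/edge counts and the bp fraction of the
largest component; the package's tests assert the node and edge counts at
k = 63 never exceed those at k = 31 on repeat-bearing fixtures). A hit of a
63-mer is also far stronger evidence of origin than a 31-mer hit. The cost
is sensitivity: a single error corrupts up to k consecutive k-mers, so at
10% uniform error most individual k-mers miss — which is exactly the regime
the cascade below is built for.

Conventions worth noting:

* **Canonical k-mers.** Every k-mer is stored as the lexicographic minimum
  of itself and its reverse complement, with per-hit orientation, so
  reverse-strand reads are first-class. k is required to be odd, which
  rules out self-reverse-complementary k-mers.
* **N handling.** k-mers containing `N` are never indexed and never counted
  as mapped; this avoids spurious compatibility classes at the price of a
  small blind spot around ambiguous bases.
* **Transcripts shorter than k** contribute no k-mers but stay in the
  output table with zero counts, so result files always cover the full
  reference.
* **d-list.** Distinguishing k-mers — present in user-supplied flanking
  sequence (e.g. introns) but absent from the transcriptome — act as
  certificates of non-transcriptomic origin: a read touching any one of
  them is vetoed outright. Whole-read veto is deliberately simpler than
  positional masking; a read containing intronic sequence should not be
  apportioned among mature transcripts at all.

# Read classification

The cascade, evaluated over the multiset of TCCs of the read's k-mers:

1. any k-mer on the d-list → `dlist_veto`;
2. no hits → `unmapped`;
3. non-empty intersection of all hit TCCs → `intersection`;
4. otherwise, if any k-mer maps uniquely to a single transcript → the most
   frequent singleton TCC (`unique_mode`); ties between equally long
   uniquely mapping stretches go to the smallest transcript ordinal, i.e.
   the transcript occurring first in the reference;
5. otherwise → the most frequent TCC with at least one occurrence
   (`mode`); ties go first to the TCC with the smallest minimum ordinal,
   then lexicographically on the sorted ordinal vector.

The intersection is the transcript set the read is compatible with along
its entire mappable extent. Errors (or real variants) can produce an
isolated stretch of compatibility with a disjoint class, emptying the
intersection; the mode then recovers the class supported by the longest
stretches of the read. "Most frequent with at least one occurrence" is
interpreted as minimum multiplicity one — i.e. an ordinary mode; nothing in
the cascade requires a higher support threshold, and a stricter reading
would only re-introduce unmapped reads that branch (5) exists to rescue.
The full tie-break order (count, then minimum ordinal, then lexicographic)
exists purely to make classification a total deterministic function; only
the first tie-break rule affects results on realistic data.

**Contig skipping.** Checking every k-mer of a long read is wasteful when
the read agrees with the graph over long stretches. `classify_read()`
hashes one k-mer, finds its unitig, and then extends the match by direct
base-to-base comparison between read and unitig sequence. Every position
inside the verified stretch provably carries the unitig's TCC (its k-mer
*is* the unitig's k-mer at that offset, and k-mers map uniquely), so the
collected TCC multiset is exactly what an exhaustive per-k-mer scan would
produce, while hash lookups scale with the number of stretches plus
mismatching positions. This is a deliberate refinement of checking only
the first/middle/last k-mer per contig stretch: sampling three positions
can miss an error strictly between them and silently credit corrupted
positions, making results depend on where errors fall relative to the
checkpoints. Verified extension costs the same asymptotically and makes
the skipping path bit-identical to the exhaustive definition — a property
the test suite asserts read-for-read against a brute-force oracle on 100
random fixtures at error rates up to 10%.

Reads shorter than k classify as `unmapped` rather than erroring — long
read data contains fragments, and a quantifier should not abort on them.

# Effective lengths

Short-read effective lengths integrate an insert-size distribution; long
reads have none, so the package estimates, per transcript,

  l_e(t) = (Σ_r l_r · 1_rt) / (Σ_r 1_rt) − k

over the first `cap` mapped reads (default one million — enough to touch
every expressed transcript in human-scale data while bounding the pass),
where 1_rt indicates that transcript t belongs to read r's TCC. Because
pseudoalignment never assigns a read to a single transcript, TCC
membership is the natural reading of "a read aligning to t". Transcripts
seen in no read fall back to max(annotated length − k, 1); all values are
clamped to ≥ 1.

Length normalization is **off by default** (`length_norm = FALSE`, all
l_e = 1): with uniform sequencing error the mapping probability of a read
is largely independent of transcript length once the read is full-length,
and empirically the correction helps only at low, uniform error rates
while hurting at high ones. The switch is exposed (`--length-norm` in the
CLI) for the low-error regime.

# The EM step

With class counts n_c, both EM variants iterate

  α_t ← Σ_{c ∋ t} n_c · (α_t/l_e(t)) / (Σ_{u∈c} α_u/l_e(u)).

This is the textbook EM for the model in which a read arises from
transcript t with probability θ_t/l_e(t) (up to normalization), θ = α/N;
the observed-data log-likelihood Σ_c n_c log Σ_{t∈c} α_t/l_e(t) − N log Σα
is computed every iteration and asserted non-decreasing in the tests.

* **default**: EM over all classes, α initialized to unique counts plus an
  equal share of each multi-mapping class.
* **longread** (the default mode): EM over classes of size ≥ 2 only,
  initialized uniformly over the transcripts those classes touch; unique
  counts are added after convergence. Keeping unique counts out of the
  iteration stops a highly covered transcript from absorbing ambiguous
  reads purely by mass — the behavior that suits indel-heavy uniform error
  profiles.

Both variants conserve the total mapped count exactly (a final rescale
removes accumulated floating-point drift, at most ~1e-12 relative).
Convergence is declared when the maximum relative change of α, over
transcripts with α > 1e-8, falls below `tol` (default 1e-8), or after
`max_iters` (default 10,000). The α > 1e-8 floor matters: transcripts
driven to zero decay geometrically and would otherwise keep the relative
change at a constant, preventing termination without affecting estimates.
Classes whose members all reach zero abundance (possible only under
adversarial initialization) are re-seeded uniformly rather than dropped,
preserving count conservation.

Worked fixed points used as tests: classes {t1}:10, {t2}:10, {t1,t2}:10
with equal l_e give (15, 15) in both modes; {t1}:30, {t1,t2}:10 gives
(35, 5) in longread mode and (40, 0) in default mode (the default-mode
fixed point solves α₂ = 10·α₂/(α₁+α₂), forcing α₂ = 0).

# The simulator

The simulator generates the conditions the pipeline is meant to survive,
not a full error-physics model:

* **Transcriptomes**: uniform random sequences with optional planted
  shared blocks (the synthetic analogue of shared exons) to create
  multi-mapping structure.
* **Expression**: `uniform` (counts as equal as integer division allows,
  remainder to the lowest ordinals) or `lognormal` (multinomial over
  normalized lognormal weights).
* **Reads**: full-length by default — each read is its source transcript's
  whole sequence — or uniform fragments with a minimum length; strand
  flipped with probability 0.5 to exercise canonical-k-mer handling.
* **Errors**: per read, Binomial(read length, error rate) events, each
  independently typed by the profile fractions and placed uniformly;
  substitutions draw a different base uniformly, insertions insert a
  uniform base at a uniform position, deletions remove one base. The
  presets are ONT (38.5% deletions / 38.5% substitutions / 23% insertions)
  and PacBio (24.5% / 52.4% / 23.1%). Indel lengths are single-base — the
  minimal model consistent with specifying only rates, fractions and
  uniform position.

Every simulator function is a pure function of its inputs and seed, and
runs on an isolated RNG stream so it neither disturbs nor depends on the
caller's RNG state.

What the simulator deliberately does **not** model: homopolymer-dependent
error, quality scores, length-dependent error rates, chimeras/concatemers,
truncated reads from RNA degradation. Passing tests on this simulator
therefore demonstrate the algorithmic properties (error tolerance of the
cascade, EM correctness, calibration of the error mix) — not performance
on real ONT/PacBio data, whose error structure is friendlier in some ways
(errors cluster, leaving clean stretches) and harsher in others.

# Metrics

`evaluate_abundances()` joins truth and estimate on transcript id (outer
join, missing entries zero), applies the chosen transform — default
log2(x+1), which matches how expression agreement is usually plotted while
keeping zeros finite — to the correlation-type metrics (Lin's CCC,
Pearson, Spearman, NRMSE), and computes MRD and PET on untransformed
values. CCC and NRMSE use population (1/n) moments, following Lin's
original definition. Because the choice of transform genuinely changes the
numbers, it is recorded in every report rather than fixed. Degenerate
cases follow explicit conventions: two identical constant vectors have
CCC 1, a constant estimate against varying truth has CCC 0, constant truth
makes NRMSE an error rather than an arbitrary value.

# Problem sizes and numerical choices in the test suite

The oracle-equivalence suite runs 100 random fixtures of 3–10 transcripts
at k ∈ {15, 21, 31} with 30 fragment reads each at 0–10% error; the
robustness sweep uses a 200-transcript, lognormally expressed simulation
of 1,500 full-length reads per error rate — sizes chosen so each property
is exercised well past its edge cases while the whole suite stays
comfortably interactive. Spearman between estimated and true counts stays
≥ 0.95 through 3% error and drops, together with the mapping rate, at 10%
— the expected behavior of uniform errors against a 63-mer index, where
an error-free 63 bp window requires an inter-error gap that becomes
exponentially rare. Stochastic assertions (realized error-type fractions,
per-base rate) use 3-standard-error bounds at event counts of ~10⁵, and
all randomized tests run under fixed seeds.

# Known limitations

* The unitig-edge count treats any two consecutive offsets within one
  unitig as an internal link; a hairpin adjacency between the same two
  k-mers in the opposite orientation would be miscounted. This requires a
  near-palindromic junction (~4^-k probability per junction) and affects
  only `graph_stats()`, not classification.
* Published node/edge counts for T-DBGs elsewhere may count directed edges
  or self-loops differently; `graph_stats()` counts undirected,
  deduplicated edges with self-loops once, so cross-tool comparisons need
  that caveat.
* The index lives in memory (hash of both k-mer orientations); there is no
  on-disk or memory-mapped variant, which bounds practical transcriptome
  size to a few hundred Mbp on a typical machine.
* `classify_read` is single-threaded; batch classification is
  embarrassingly parallel and deterministic by construction, but no thread
  pool is provided.
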