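---
title: "Alignment-free sequence comparison with afkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free sequence comparison with afkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afkit)
```

# The problem

Sequence alignment assumes collinearity: homologous residues appear in the
same order in both sequences. Real genomes violate that assumption —
rearrangements, domain shuffling, lateral transfer — and below roughly
20–35% identity (the "twilight zone" of protein homology) alignment scores
stop discriminating homologs from noise. Alignment-free methods sidestep
both problems by comparing *statistics* of the sequences rather than
residue-by-residue correspondences. `afkit` implements the two classical
families of such methods — word (k-mer) frequency measures and
information-theoretic measures — together with the downstream machinery a
practitioner needs: distance matrices, distance-based trees, multi-method
consensus, and an AUC benchmark over a labelled homology hierarchy.

# Word-frequency measures

The pipeline has three steps.

1. **Word extraction.** Every window of width $k$ (step 1, strand-specific)
   is counted. For $x=\mathtt{ATGTGTG}$ at $k=3$ this gives
   $\{ \mathtt{ATG}{:}1, \mathtt{TGT}{:}2, \mathtt{GTG}{:}2 \}$. Windows
   containing an ambiguity symbol (N; X/B/Z for protein) are skipped, so
   counts stay integral and reproducible. There is no reverse-complement
   canonicalization: the worked counts above require strand-specific
   windows.
2. **Vectorization.** Profiles are laid out over the union vocabulary of
   the compared set, sorted in byte order for platform-independent
   determinism. With $y=\mathtt{CATGTG}$ the vocabulary is
   $\{\mathtt{ATG},\mathtt{CAT},\mathtt{GTG},\mathtt{TGT}\}$ and the count
   vectors are $c^x = (1,0,2,2)$ and $c^y = (1,1,1,1)$; frequency mode
   divides by the total.
3. **Distance.** Any registry measure is applied to the two vectors.

```{r}
s <- SequenceSet(c(x = "ATGTGTG", y = "CATGTG"))
cv <- countVectors(s, k = 3)
vectorEntries(cv$x)
wordDistance("euclidean", cv$x, cv$y)   # sqrt(3)
```

The registry (`listMetrics()`) holds Euclidean, squared Euclidean (whose
count-mode and frequency-mode invocations are two distinct benchmark
variants), Manhattan, Canberra (coordinates with $u_i+v_i=0$ contribute 0),
Bray–Curtis, binary Jaccard and Hamming (presence/absence only), Pearson
(1 − correlation; undefined for constant vectors), d2 as a raw inner
product plus its cosine dissimilarity, and a normalized Google distance
adapted to word mass:

$$\mathrm{NGD}(u,v) = \frac{\max(\ln f_u,\ln f_v) - \ln f_{uv}}
  {\ln(f_u{+}f_v) - \min(\ln f_u,\ln f_v)},\qquad
  f_u = \sum_i u_i,\; f_{uv} = \sum_i \min(u_i, v_i).$$

Several published adaptations of the Google distance to k-mer profiles
exist; this one was chosen so identical profiles score 0 and word-disjoint
profiles are maximal (infinite — `buildDistanceMatrix()` refuses to emit
such a matrix and suggests a smaller $k$). Tiny negative values from
floating-point cancellation (Pearson, cosine) are clamped to 0; anything
below $-10^{-9}$ is treated as an internal error.

**Choosing k.** Small word spaces saturate (every word occurs everywhere),
large ones are sparse and memory-hungry — the dense DNA space at $k=14$
already has $4^{14} = 268{,}435{,}456$ cells, which is why only the sparse
union vocabulary is ever materialized. The CLI defaults to $k=3$ for
protein and $k=6$ for nucleotide input, following the usual guidance
(2–6 residues for proteins, 8–10 for genes, longer for near-identical
genomes; smaller $k$ for very divergent sequences). Reduced alphabets
(`reduceAlphabet()`) trade resolution for sensitivity: the purine/pyrimidine
table (`ry`) and Murphy-style physico-chemical protein groupings of sizes
5/4/3/2 ship with the package; the literature contains several variants of
these groupings, so the shipped tables are package defaults and any
two-column TSV can be substituted.

# Information-theoretic measures

**LZ76 complexity** counts the components of the exhaustive-history parse:
scanning left to right, the current word extends while it occurs in the
prefix ending one symbol earlier (overlap allowed); the component includes
the first irreproducible symbol, and the final component counts even if
still reproducible. `ATGTGTG` parses as `A|T|G|TGTG`, complexity 4. The
parse is the worked-example anchor fixing this exact LZ variant.

**NCD** estimates shared information:
$\mathrm{NCD}(x,y) = [C_{pair} - \min(C(x),C(y))]/\max(C(x),C(y))$ with
$C_{pair} = \min(C(xy), C(yx))$ — the minimum over both concatenation
orders, because one-order LZ concatenation is asymmetric and a
dissimilarity should not be. Any function string → positive number can be
plugged in as the backend (a gzip-length estimator, say); only the LZ76
backend ships, because generic compressor output varies across versions
and would break reproducibility. Note `ncd(x, x)` with crude LZ76 on short
strings is about 0.25, not 0 — concatenating a string with itself still
costs one component; this is a property of the estimator, not a bug.

**Shannon entropy** (`shannonEntropy()`, bits) and the **symmetrized
Kullback–Leibler divergence** on word profiles complete the set. KL needs
strictly positive probabilities, so profiles are smoothed by add-$c$ over
the union vocabulary ($c = 1$ by default) and the two directions are
summed:
$p_i = (u_i + c)/(\sum u + cm)$,
$D = \mathrm{KL}(p\|q) + \mathrm{KL}(q\|p)$.
The smoothing constant matters only near zero counts; published procedures
rarely print theirs, so only values derived in-package are asserted
against.

# From distances to trees

`buildDistanceMatrix()` computes all pairwise dissimilarities over the
union vocabulary of the whole set (one vocabulary, computed once) and
returns a validated symmetric zero-diagonal `DistanceMatrix`, exportable as
square PHYLIP (`writePhylip()`: 10-character names, 6 decimals, collision
check after truncation). `njTree()` (Saitou–Nei, negative intermediate
branches clamped to 0) and `upgmaTree()` (average linkage, ultrametric)
produce `phylo` trees; `majorityConsensus()` summarizes a panel of
per-method trees by keeping exactly the non-trivial bipartitions present in
*strictly more than* a threshold (default 0.5 — classical majority rule,
which also guarantees the kept splits are mutually compatible) and
annotates each with its occurrence fraction as a 0–1 support, printed to 3
decimals. Unresolved regions collapse to multifurcations; consensus trees
carry no branch lengths. `robinsonFoulds()` counts the symmetric difference
of the non-trivial split sets. NJ and UPGMA tie-breaks follow the
underlying implementations deterministically: identical input always yields
identical output.

```{r}
fa <- SequenceSet(c(a = "ACGTACGTAC", b = "ACGTACGAAC",
                    c = "TTGCATGCAA", d = "TTGCATGGAA"))
trees <- lapply(c("euclidean", "braycurtis", "manhattan"), function(m)
  njTree(buildDistanceMatrix(fa, k = 2, metric = m)))
majorityConsensus(trees)$node.label
```

# The homology benchmark

Given sequences labelled with a path through an ordered hierarchy
(e.g. SCOP-style class/fold/superfamily/family), each level defines a
binary classification problem over the $n(n-1)/2$ sequence pairs: pairs
sharing the label at that level are related, all others are not. The
inclusive definition is used — positives at a coarse level include pairs
that are also related at finer levels — and is recorded in the result's
`pair_definition` attribute, since the alternative (excluding
finer-level positives) is also defensible. A measure is scored by the AUC:
the probability that a random related pair is *closer* than a random
unrelated pair, ties counted one half. It is computed as the Mann–Whitney
rank statistic with midranks, which equals the trapezoidal ROC area
exactly and involves no threshold sweep. `runBenchmark()` computes one
distance matrix per configuration and reuses it across levels;
`benchmarkRanking()` orders configurations by mean AUC.

# The synthetic hierarchy generator

No reference homology dataset is bundled; the generator produces labelled
families with controlled divergence so every stage is testable offline.

`evolveSequences()` implements neutral divergence along a guide topology:
per branch, each site is substituted with probability `pSub` (to a
uniformly chosen different symbol — a Jukes–Cantor-like choice made for
analyzable expectations, not realism), then indels strike with per-site
probability `pIndel` and geometric lengths (substitutions before indels,
in a fixed order, so a seed reproduces everything). Rearrangement
operators (`applyRearrangement()`: block shuffle, segment swap, lateral
transfer; 0-based half-open coordinates) model the order-breaking events
word statistics are famously robust to.

`makeHierarchy()` builds the nested, labelled dataset. Two design points
deserve explanation:

* **Compositional signatures.** Each lineage drifts toward its own
  "corner" of composition space: top-level roots are drawn from distinct
  skewed symbol distributions, and every finer branch substitutes with
  replacements drawn from a lineage-specific attractor (half uniform, half
  one symbol), with corner indices offset down the tree so sibling
  lineages never share a direction. This emulates genomic signatures —
  clade-specific composition bias such as GC content, the very property
  word-frequency methods exploit — and makes group separation a *mean
  shift* in frequency space, which concentrates as the root length grows.
  Divergence realized purely as uniformly-directed substitution counts
  cannot do this: the resulting distance fluctuations are a fixed fraction
  of the distance regardless of sequence length, and perfect
  discrimination is then unattainable at small $k$.
* **Nested magnitudes.** The per-level drift magnitudes — full-strength
  root signatures, then branch substitution probabilities 0.30 / 0.10 /
  0.03 and within-family divergence 0.01 — form a strict chain in which
  each level exceeds twice the sum of everything below it. Consequently
  within-group spread can never reach the between-group gap at any level,
  and Euclidean 2-mer distances classify all four levels perfectly
  (AUC 1.000) for the default root length of 4000 residues. Defaults of
  2 groups per level and 2 sequences per family give 32 sequences
  (496 pairs).

What the generator does **not** emulate: substitution-rate heterogeneity,
realistic amino-acid exchangeabilities, selection, or read-level noise.
Passing benchmarks on these data therefore demonstrate the correctness and
internal consistency of the measures — not their accuracy on real
proteins, which is an empirical question requiring curated references.

# Numerical choices and problem sizes

* Vocabulary order is byte (radix) order everywhere; ties in clustering
  follow deterministic library order — reruns are byte-identical.
* Frequency vectors of an empty profile (all windows ambiguous) are
  all-zero rather than an error; measures that cannot handle all-zero
  input say so explicitly.
* The test suite exercises the oracle equivalences at 1000 random vector
  pairs and 1000 random strings (length ≤ 64), tree reconstruction on
  random additive 4–8-taxon matrices, and the full benchmark on the
  32-sequence default hierarchy — sizes chosen to probe every code path
  thoroughly while keeping a full run inside a couple of minutes on one
  core.
* The NJ parameter-recovery exercise (8-leaf balanced topology,
  `pSub = 0.02`, root length 2000, Euclidean-frequency 3-mer distances)
  recovers the generating topology in roughly 80–85% of replicates. The
  limiting factor is the variance of the composition-distance estimator —
  the squared distance is a ~64-cell chi-square whose *relative* spread
  does not shrink with sequence length — as confirmed by the control in
  the test suite notes: neighbor joining on the true per-site mismatch
  distances of the same simulations recovers the topology every time.

# Limitations

Background-adjusted statistics (d2*, d2^S, Markov-model expectations),
spaced/inexact word matches, minimal absent words, MinHash sketches, and
graph-based measures are out of scope. The Google-distance adaptation is
one of several in the literature; cross-tool numeric agreement for that
measure should not be expected. LZ76 on short sequences is a crude
complexity proxy; compressor-grade backends can be plugged into `ncd()`
where cross-version reproducibility is not a concern.
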