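---
title: "Detecting and reconstructing the dominant IGH clone from paired-end RNA-seq"
author: "ighclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and reconstructing the dominant IGH clone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

B-cell malignancies such as mantle-cell lymphoma are clonal: one
lymphocyte population carrying a single immunoglobulin heavy-chain (IGH)
V(D)J rearrangement dominates the tissue.  Clinical clonality assays
amplify the rearranged locus with IG-specific primers; `ighclone` instead
extracts the same information from ordinary (primer-free) bulk RNA-seq —
short paired-end reads — by detecting reads that span the recombined
V(D)J junctions, ranking the implied rearrangements, and reconstructing
the exact nucleotide sequence of the dominant clone's junction region.

The difficulty is twofold.  First, the recombined transcript does not
exist in any reference: exonucleases trim the recombining ends of the V,
D and J segments, terminal deoxynucleotidyl transferase (TdT) inserts
non-templated N nucleotides at the VD and DJ junctions, and short
palindromic (P) additions appear at untrimmed ends.  Second, IGH germline
segments are highly homologous and polymorphic, so reads multimap across
alleles and genes, and naive counting overestimates support.

## Pipeline

`run_pipeline()` executes four stages, each independently exposed and
testable.

**Partition.**  Mates are placed end-to-end on a reference (a genome
slice, or simply the germline segments standing in for the locus) with at
most 2 mismatches, reporting at most 10 placements from the best mismatch
stratum; a mate with more than 10 best-stratum placements is suppressed
and treated as unaligned, which protects the downstream counts from
repeat-induced multimapping.  Pairs whose mates both fail to align form
the *vdj_unmapped* set (junction-spanning candidates); pairs with a
placement inside the locus intervals form the *vdj_mapped* set; the rest
are discarded.  The three sets are a disjoint cover, asserted on every
run.  Externally produced SAM/BAM alignments can substitute for the
internal aligner via `ingest_sam()`, with the same classification
contract.  Because the first aligner processes mates separately, the set
of individually unaligned *mates* is also retained; it is the natural
re-mapping substrate for reference scoring (below).

**VJ couple calling.**  Both datasets are aligned locally (ungapped, both
strands) against the germline V and J segments with an identity floor of
0.95 over at least 20 nt — thresholds chosen so that score ranking still
separates segments at 99% similarity, the discrimination level the IGH
allele repertoire requires.  A pair with one mate on a V and the other on
a J is a *VJ-encompassing read*, the unit of quantification.  Counting is
set-semantic: a read supporting the same (V, J) couple at several
positions counts once (homology within a segment must not inflate
support), while a read supporting several couples counts once in each
(polymorphism makes the correct assignment undecidable at this stage).
Couples are ranked by their supporting-read count; the top couple defines
the main clone, and the top-1/top-2 ratio is the monoclonality statistic.
Because multimapping across near-identical alleles is unavoidable,
results are also aggregated to subgroup level by *unioning* the
supporting-read sets (a sum would double-count multimapped reads; the sum
variant is available behind a flag for comparison).

**Score.**  Clone abundance is reported as
`count / total_reads * 1e9`, a library-size normalisation that
deliberately omits the per-length division of conventional RPKM: V, D and
J regions are comparable to or shorter than a single 100 nt mate and
encompassing reads do not tile them, so dividing by segment length would
distort comparisons between clones.

**D identification.**  For the top 5 couples, the mates of encompassing
reads that are *not* fully explained by their V or J alignment are
realigned to the D germline with a seeded contract: a hit requires an
exact common substring of at least 10 nt, and each mate reports at most
one alignment (highest-scoring ungapped extension of the seed).  The D
segment with the highest mate tally is assigned; ties break
lexicographically and are flagged, and absent evidence is flagged rather
than guessed.

**Reconstruction.**  Read pairs whose *both* mates carry a D hit bridge
the junctions.  From each bridging pair a *virtual reference* is
assembled: germline V up to the read-supported V end, the VD-junction
bases read between the V- and D-aligned intervals, the D-covered bases
(read-derived; germline-filled between the two mates when their D
intervals do not overlap), the DJ-junction bases, and germline J from the
read-supported J start onward.  Identical sequences are deduplicated.
Each reference is then scored by re-mapping the initially unmapped reads
onto it (same local-alignment floors; support is counted per pair, score
is the normalised form above), and the top reference is the main-clone
sequence.  Finally `annotate_junctions()` compares it against the naive
V+D+J concatenation and reports the trimmed base counts and inserted
junction strings (P and N additions are reported together, as they are
not distinguishable in sequence).

### Numerical and tie-breaking choices

* All coordinates are 0-based half-open; germline sequences are stored in
  transcript (sense) orientation, so junction arithmetic is strand-free.
* The alignment kernels are exact, not heuristic.  They scan only
  diagonals carrying a shared k-mer, with k chosen from the
  runs-between-mismatches bound (an end-to-end placement of an L-mer with
  at most v mismatches contains an exact run of at least
  `ceil((L-v)/(v+1))` bases; the local analogue minimises over window
  lengths), so the candidate set provably contains every qualifying
  placement.  Oracle-equivalence tests against exhaustive scans cover
  both kernels, including the suppression case.
* Equal-score local windows prefer the shorter (higher-identity) span;
  this stops alignments from creeping across junction breakpoints on a
  net-positive mismatch+match tail.  A V or J alignment that still
  overlaps a D hit on the read is clipped at the D boundary — hits are
  ungapped, so clipping is coordinate-consistent, and the disputed bases
  are read-derived either way.
* All remaining ties (couples, D segments, references) break
  lexicographically on formatted names or read ids and are flagged in
  the output, so runs are deterministic.
* The run manifest records the configuration, input digests and
  deterministic stage counters.  Wall-clock timings are deliberately not
  written: output bundles are byte-identical across reruns of the same
  seed and config, which is itself a tested property.

## The simulator

Every stage is validated against `simulate_sample()`, which generates a
truth-annotated sample: a synthetic germline, one dominant clone over a
polyclonal background, and paired-end reads with substitution errors.

**Germline.**  Segments follow the IMGT naming hierarchy
(`subgroup[-gene]*allele`), with genes carrying allele pairs at 98.5%
identity by default (per-base substitution at rate `divergence` = 0.015).
The allele pairs are essential: they reproduce the multimapping regime
that motivates the set-semantic counting and subgroup aggregation.
Default lengths are human-like: V 280–310 nt, D 16–37 nt (the realistic
IGHD spread, excluding the single 11 nt outlier gene), J 45–60 nt.

**Recombination.**  Trims at the four recombining ends are uniform on
0–6 nt; N insertions uniform on 0–6 nt per junction; P additions
(reverse complement of the terminal 1–3 bases) occur with probability
0.5 at each untrimmed end.  The composed transcript satisfies, by
construction and by test,

```
transcript = trimmedV + p_v + n1 + p_d5 + trimmedD + p_d3 + n2 + p_j + trimmedJ
```

One deliberate generator property: junction bases adjacent to a trimmed
germline boundary are rejection-sampled to differ from the germline
continuation base.  Without this the trim/insertion decomposition of a
transcript is formally non-identifiable (the classic V(D)J annotation
ambiguity), and "does annotation recover the truth?" would be an
ill-posed question.  With it, the maximal-match convention used by
`annotate_junctions()` recovers the generating event exactly.

**Reads.**  Pairs are allocated to clones by exact largest-remainder
rounding (no sampling noise in clone proportions).  Fragment lengths
follow a truncated normal, by default 240 ± 60 nt clipped to
`[read_length, transcript length]`, reflecting a short-insert cDNA
library fragmenting templates of a few hundred nucleotides.  The left
tail below two read lengths — mates that overlap each other — is not an
artefact but a requirement: on a ~360 nt V(D)J transcript, a pair can
only bridge a ≤37 nt D region if both mates sit within ~100 nt of it,
i.e. if the fragment is roughly 120–170 nt.  A fragment model without
that tail makes reconstruction structurally impossible, which is why the
mate-pair geometry here is anchored to the fragmentation physics of
short templates rather than to a genome aligner's inner-distance
setting.  Errors are substitutions only (the alignment contracts are
substitution-oriented); positions are recorded per mate in the truth
table.

**What the simulator does not model.**  Constant-region sequence
downstream of J, somatic hypermutation, indel sequencing errors, quality
score structure, and coverage biases are all absent.  Green tests
therefore demonstrate the pipeline's correctness under the stated
generative model — substitution noise, allele homology, polyclonal
background — not robustness to hypermutated or indel-rich real data.

## Study conditions and known limitations

The standard test condition is 20 samples of 5000 pairs, main-clone
fraction 0.7, 50 background clones, germline 30 V / 10 D / 6 J, at error
rate 0.005 for identification and 0 for reconstruction; these sizes keep
the whole suite within a few minutes on one CPU while leaving hundreds of
encompassing reads and tens of bridging reads per sample.

Two limitations are inherent rather than implementation artefacts:

* **Detectability floor.**  A clone whose trimmed D retains fewer than
  10 nt cannot produce a seeded D hit — the same 10 nt exact-seed
  contract any seeded aligner imposes.  Such events (about 5% of draws
  under the default trim and length distributions) yield
  `no_d_evidence` (or a weakly supported spurious D) and no bridging
  reads, so reconstruction is reported impossible with diagnostics
  instead of being guessed.
* **Allele-pair ambiguity.**  When allele pairs differ only at sites
  outside the read-covered span, the allele label of a couple or
  reference is a flagged lexicographic choice; and when a junction base
  coincides with a sibling allele's germline continuation at a site
  where the alleles diverge inside the trimmed region, the sibling
  explains the transcript with one fewer trimmed base and strictly
  better alignment score.  No method can recover the generating allele
  in these cases; comparisons are therefore most meaningful at the
  subgroup level for V/J and the gene level for D, which is how the
  clone table reports them.
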