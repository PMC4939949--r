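---
title: "Profile-HMM guided assembly of short peptide reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-HMM guided assembly of short peptide reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Metagenomic and metatranscriptomic sequencing yields fragmentary reads from
communities where most organisms lack reference genomes. After fragmentary
gene calling, each 100 bp read becomes a peptide of roughly 33 amino acids —
too short for confident profile-HMM classification on its own, and too
sparse for whole-community de novo assembly at low coverage. `profasm`
addresses the family-centric version of the problem: given a profile hidden
Markov model of a protein family, find the reads in a peptide-read database
that belong to that family, and reconstruct the family's gene products as
peptide contigs, by *simultaneous alignment and assembly* (SAA): contigs are
grown along read overlaps and re-aligned to the model after every extension,
so the model guides the assembly and the assembly amplifies the homology
signal of individual short reads.

The pipeline has seven stages: indexing, seeding, extension, (banded)
alignment, recalibration, full-model verification, and read mapping.

## The scoring model

A profile HMM with `L` match states is converted to log-odds form
(`to_scoring()`): match and insert emissions become bit scores
$\log_2 p(a \mid s) / q(a)$ against the background $q$ (the file's `COMPO`
line, else uniform — which background the original tooling uses is not
documented, so the file's own composition is preferred as the less arbitrary
choice), and the seven core transitions $\{M\!\to\!M, M\!\to\!I, M\!\to\!D,
I\!\to\!M, I\!\to\!I, D\!\to\!M, D\!\to\!D\}$ become $\log_2$ probabilities.
Zero probabilities map to a sentinel of $-10^{30}$, which is safe under
addition and makes any path through them unselectable.

### Alignment mode

All three scorers — `banded_viterbi()`, `full_viterbi()` and
`forward_score()` — compute *local-in-model, local-in-target* alignments:
a parse enters at any match state, follows the M/I/D recurrences

$$M[i,j] = e_M(i, a_j) + \max\{M[i\!-\!1,j\!-\!1] + t_{MM},\;
  I[i\!-\!1,j\!-\!1] + t_{IM},\; D[i\!-\!1,j\!-\!1] + t_{DM},\; 0\}$$
$$I[i,j] = e_I(i, a_j) + \max\{M[i,j\!-\!1] + t_{MI},\; I[i,j\!-\!1] + t_{II}\}$$
$$D[i,j] = \max\{M[i\!-\!1,j] + t_{MD},\; D[i\!-\!1,j] + t_{DD}\}$$

and exits at any match state. A single mode is used deliberately: the
banded extension aligner scores 33-residue reads anchored in the middle of
models hundreds of states long, where a glocal (whole-model) requirement is
unmeetable inside any reasonable band; and using the same mode for the
unbanded scorers makes the band a pure restriction, so the banded score is
monotone in the band width `d` and converges exactly to the unbanded score
once `d` covers the matrix. Note the delete predecessor of the match cell
is taken at column $j-1$: a match consumes $a_j$, so its predecessor —
whatever its state — must have consumed exactly $a_1..a_{j-1}$.

Banding restricts computation to cells with $|(i - j) - (i_0 - j_0)| \le d$
around the seed anchor $(i_0, j_0)$; the anchor centres the band but does
not pin the path, so weak seeds cannot inflate alignment scores. Extension
in both directions is handled by re-running one banded DP over the whole
current contig after each extension; contigs are short (hundreds of
residues), so this costs the same as mirrored directional extension and
keeps one code path. Ties in the max are broken M > I > D, making
tracebacks reproducible. `'X'` residues emit at a fixed $-2$ bits — an
unknown residue is mildly unfavourable, but does not veto an otherwise
solid contig.

## Seeding

Seeds anchor alignments at length-`k` windows of consecutive match states
(`k = 6` by default). The *maximum seed score* of a window is the sum of
its per-position best emission scores — the highest log-odds of any
sequence the window can emit; transition terms are excluded because
M→M transitions in seed-worthy windows are near-deterministic and a
transition-free maximum keeps the position-wise computation exact. A window
seeds a read k-gram when the k-gram's emission score reaches `theta` times
the window maximum (`theta = 0.8` by default: in a conserved 6-window this
admits one to two conservative substitutions). Windows whose maximum is not
positive never seed: a fractional cutoff below zero is meaningless (it
would grow *more* permissive as `theta` rises) and such windows cannot
anchor credible alignments.

Candidate k-grams are pre-filtered through the GBMR4 reduced alphabet —
classes {G}, {P}, {A,D,K,E,R,N,T,S,Q}, {Y,F,L,I,V,M,C,W,H} — by looking up
the window's consensus k-gram in reduced encoding. One lookup per window
keeps seeding linear in model length; substitutions within a class survive
the pre-filter and are then arbitrated by `theta` in the full alphabet.
Recall lost to the single-consensus lookup is a measurable property of the
heuristic, not hidden behaviour.

## Extension, redundancy and drop-off

The read database is indexed once: a k-gram table for seeding, and
*extension links* — maximal exact suffix–prefix overlaps of at least
`min_overlap = 10` residues between ordered read pairs, built by
suffix-keyed hashing. Exact overlaps keep the graph sound; divergence
between homologs is absorbed by the aligner, not the graph. Only the
maximal overlap per pair is stored (shorter sub-overlaps add paths, never
sequence), and a link must extend its successor by at least one residue.

Seeds are processed in descending score order, so strong anchors claim
reads first. Each seed's read becomes a contig that is alternately extended
C- and N-terminally along the links of its terminating reads, re-scoring
with the banded aligner after every extension and exploring all outgoing
links, subject to: (a) *drop-off* — a branch more than `dropoff = 10` bits
below its own best is abandoned (the value is the package's own default;
ten bits is a probability-odds factor of about a thousand, enough to stop
extensions that have clearly left the homologous region while tolerating a
few noisy steps); (b) *depth* — at most `max_depth = 5` successive
extensions per direction, bounding a contig at roughly the seed read plus
five read-lengths per side, the scale of a gene against 33-residue reads;
(c) *redundancy* — a read consumed at a nearby model position (anchored
position bucketed to 10 states) by an equal-or-better contig is not
re-used, and within one seed's exploration each read is expanded once
(this also makes cycles in the overlap graph harmless). The best-scoring
contig along each maximal path is emitted.

*Recalibration* then merges candidate contigs that share an exact overlap
of at least `min_overlap` (greedily, longest overlap first; constituent
reads are pooled, and a merge whose reads no longer tile the merged
sequence is skipped), collapses duplicates, removes substrings, and
re-scores merged contigs with the banded aligner so that the subsequent
significance filter sees current scores.

## Significance: P-values, E-values and their calibration

Banding and seeding break the compositional normalisation of the model, so
banded scores support ranking, not absolute statistics. The pipeline
therefore filters candidates with a calibrated P-value and anchors
precision in full-model verification:

- **P-values** (`score_pvalue()`): a Gumbel (extreme-value) distribution is
  fitted by the method of moments to the local Viterbi scores of
  `null_n = 200` background-sampled sequences. Below 30 calibration scores
  the fit is refused and an empirical rank P-value is used. The null is
  scored *unbanded*: null sequences have no seed to centre a band on, and
  the unbanded score dominates every banded score, making the null
  conservative.
- **Length correction**: the expected best local score against a fixed
  model grows with the logarithm of the target length (empirically the
  Gumbel location shifts by $\beta \ln(n/n_0)$ while the scale is stable),
  so scores of contigs of different lengths are judged against a
  length-shifted null rather than a mixed-length sample.
- **Verification** (`verify_contigs()`): surviving contigs are re-scored
  with the unbanded *forward* algorithm — summing over all parses, the
  statistically meaningful quantity — and assigned
  $E = N_\mathrm{eff} \cdot P$. The pipeline sets $N_\mathrm{eff}$ to the
  *database read count*, not the candidate count: candidates are the best
  survivors of a search over every read, and an E-value that ignores that
  selection admits the extreme tail of the decoys (in development this
  exact failure produced confidently "verified" single-read decoy
  contigs). Contigs with $E \le 0.01$ are trusted. A `verifier` hook
  allows an external HMMER-compatible search to replace the internal test.

## Mapping and abundance

Reads are recruited onto trusted contigs by exact ungapped scanning over
all offsets, including overhangs past contig ends: a read is recruited when
strictly more than 60% of it overlaps a contig with at most 3 substitutions
(`'X'` mismatches everything; the 60% boundary itself is rejected, and
3 mismatches are accepted, following the tool's parameter semantics rather
than its prose). Gapped placements are unnecessary because the mapper
recruits reads onto contigs assembled from such reads. A read recruited by
several families keeps the one whose contig has the smallest E-value, then
fewer mismatches, then the lexicographically first family name.

Per-family abundance is reported as raw recruited-read counts and RPKM.
The "kilobase" in RPKM is a nucleotide unit, so the model length in match
states is converted to nucleotide-equivalent length (×3) by default
(`basis = "nt"`); `basis = "aa"` is available for purely peptide-space
comparisons. Evaluation metrics follow the standard set definitions —
recall $TP/(TP+FN)$, precision $TP/(TP+FP)$, F their harmonic mean — and
assembly quality uses N50, N50 normalised by model length (×3 in
nucleotide space), and read-/contig-level precision (r.P., c.P.) with
strict length filters (contigs longer than 60 aa / 180 nt).

## The synthetic study conditions

`sim_metagenome()` defines the conditions under which the package validates
itself: 5 conserved toy families of 150–300 match states; 3 homolog
proteins per family sampled stochastically from the family model (so
divergence is governed by the model itself — a `conservation` of 0.9 on the
consensus residue gives homologs roughly 80% mutual identity, the
conserved-domain regime the seeding defaults are tuned for); 200 background
decoy proteins of 100–300 residues; fragmentation into full-length 33-aa
reads (the peptide image of 100 bp reads) at configurable coverage
(4X default; the validation suite contrasts 10X and 2X) with i.i.d.
substitution errors at rate 0.01; truth labels by the same >60% overlap
rule the mapper uses, recomputable from the stored proteins and regions.
Homologs are standalone domain proteins by default (`flank_len = 0`);
flanked embedding is available and is used in tests to exercise the
boundary behaviour of the truth rule.

What the generator deliberately does not emulate: indels in reads (the
upstream simulator regime is substitution-only), read-quality models,
chimeric reads, nucleotide-space artefacts of gene calling, and the deep
family divergence of real Pfam alignments. Passing tests therefore show
that the machinery is correct and well-calibrated under conserved-family
conditions; they do not predict sensitivity on highly divergent real
families, where recall is limited by seeding and by the biological spread
of the family itself.

## Problem sizes and numerical choices

The validation suite enumerates all parses exhaustively for models of up to
4 states against targets of up to 6 residues (hundreds of thousands of
parses), checks band convergence on models up to 10 states, compares
seeding and overlap indexes against brute-force scans on 50–100 read
fixtures, and runs the full study (about 13,000 reads at 10X) over five
simulation seeds at both coverages; the runtime-shape check contrasts
homolog lengths 150/300/600. These sizes were chosen so every oracle is
exact and the whole suite remains comfortably interactive. Determinism is
part of the contract: fixed seeds give byte-identical fixtures and
outputs, and all tie-breaks (DP states, seed ordering, merge order,
family resolution) are specified.

## Known limitations

- The P-value machinery is an internal calibration; it matches no external
  tool's numbers and is used only for ranking and pre-filtering, with
  precision anchored by forward-score verification.
- Single-consensus reduced-alphabet lookup can miss seeds whose residues
  are consensus-scoring but fall in a different GBMR4 class; `theta` does
  not recover these.
- The overlap graph stores exact overlaps only; sequencing errors landing
  in the overlap of two reads can disconnect them, which is why coverage
  drives assembly contiguity.
- Paired-read information, quality values and nucleotide-space assembly
  are out of scope; recruited reads are exported as FASTA for downstream
  assemblers.
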