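---
title: "Characterizing halovirus genomes and detecting induced proviruses"
author: "provirseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing halovirus genomes and detecting induced proviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provirseq)
```

## Scope

Small archaeal viruses and the proviruses of their hosts leave characteristic
signatures in sequence data that can be read without any homology searching:
motif avoidance shaped by host restriction–modification systems, strand-skew
inflections at the switch point of gene orientation, tightly packed and
overlapping coding sequences, programmed −1 frameshift sites in the tail
chaperone region, tRNA-anchored attachment (att) sites, and — when an
integrated element is induced — circular contigs, junction-spanning reads and
elevated read depth over the provirus region. `provirseq` implements this
tool set, together with a synthetic-data generator that reproduces the
statistical structure each analysis assumes, so every stage is testable
offline and end to end.

## Genome records and coordinates

All analyses consume a `genome_record`: a nucleotide sequence, a topology
(`circular` or `linear`), and an ordered feature table (`CDS`, `tRNA`,
`repeat_region`, `misc`). Coordinates are 1-based inclusive, the GenBank
convention; on circular records a feature may wrap the origin, encoded as
`start > stop`. `span_length()` implements the induced arithmetic: a
wrapping span covers `L - start + 1 + stop` bases. `N` bases are accepted in
host sequences (draft contigs), but any k-mer window containing `N` is
skipped from censuses, and att cores may not contain `N`.

GenBank flat files are read and written by a minimal parser covering exactly
this model (round-trip tested); FASTA/FASTQ go through Biostrings and GFF3
input through rtracklayer.

## Motif avoidance

Virus genomes replicating in restriction-proficient hosts are depleted of
endonuclease recognition motifs, most of which are 4–6 bp palindromes. The
census counts k-mers on the forward strand of the deposited sequence, with
`L` wrapping windows on a circular genome so counts conserve
(`sum = L` without `N`). Under-representation of a tetramer `w1w2w3w4` is
measured by the maximal-order (second-order) Markov odds ratio

$$\rho(w_1w_2w_3w_4) = \frac{N(w_1w_2w_3w_4)\,N(w_2w_3)}
{N(w_1w_2w_3)\,N(w_2w_3w_4)},$$

the observed count over its expectation from the (k−1)- and (k−2)-mer
composition of the same sequence. Values near 1 are unremarkable (on 1 Mb of
i.i.d. sequence the mean over all 256 tetramers is within 0.02 of 1, a
property the tests assert); values at or below the default threshold of 0.15
mark avoidance. The threshold sits above the strongest published
under-representation values (≈0.11) while staying far below the null.

The palindromic 6-mer stage enumerates the 64 self-complementary 6-mers and
excludes any containing an absent or under-represented tetramer as a
substring — their absence is already explained by the embedded core — before
reporting the zero-count remainder. Pairs that differ only at the central
complementary positions can optionally be collapsed into R/Y IUPAC families
(e.g. `CTGCAG`/`CTATAG` → `CTRYAG`); this is presentation only and the
concrete motifs are always returned.

Two conventions were genuinely open and are fixed as follows. Counting uses
the forward strand by default (`pool_strands = FALSE`): the headline
absences are palindromes and therefore strand-invariant, and at the depletion
levels of interest the non-palindromic odds agree to two decimals under
either convention. And the Markov order is maximal (second) order, the
standard choice for tetramer bias; the formula is stated so the convention
is testable rather than implicit.

## Skew profiles

`at_skew_profile()` tiles the genome with non-overlapping windows (45 bp by
default) and computes `(A − T)/(A + T)` per window; windows with no A or T
contribute 0 so the cumulative series remains a total order. Tiling rather
than sliding windows keeps one value per window and makes the cumulative sum
well-defined; the final partial window is discarded. The global maximum of
the cumulative series (`skew_inflection()`, ties to the smallest coordinate)
is reported descriptively — in small tailed-virus genomes it typically marks
the point toward which most genes are oriented — and no replication-origin
call is implied.

## Gene architecture, repeats, frameshifts, tail length

**Spacing.** For consecutive CDS pairs in coordinate order (including the
wrap-around pair on circular genomes) the gap is
`next_start − prev_stop − 1`, so stop/start codon fusions give negative
gaps. A gene is *overlapping* when it intersects either neighbour and
otherwise *close* when its nearest gap is 1–10 bp; each gene is counted
once. This per-gene rule reproduces the published architecture statistics of
a real 45 kb halovirus annotation (53 genes: 27 overlapping, 13 close) from
its printed CDS coordinate table, and the published "separated by only
11 bp" remark for one adjacent pair pins the gap convention.

**Repeats.** `find_direct_repeats()` reports all maximal exact direct
repeats above a minimum unit length, flagging tandem copies. Seeds of the
minimum length are hashed, seed pairs extended outward to maximality, and
duplicates collapsed; the result is property-tested against an \(O(n^2)\)
diagonal-scan oracle on kilobase inputs. Only exact repeats are reported;
approximate family detection is out of scope.

**Slippery sites.** A −1 programmed frameshift heptamer has the form
`X XXY YYZ` with the first three bases identical, the next three identical,
and `X ≠ Y`; `Z` is unconstrained because both published archaeal examples
(`GGGAAAT`, `GGGAAAG`) vary at that position and the stricter eukaryotic
constraints would add assumptions the data do not test. The scan covers the
3′-terminal 30 codons of a named CDS by default (the conserved position sits
a few codons before the stop) and reports plus-strand genome coordinates.

**Tail length.** Siphovirus tail length scales linearly with tape measure
protein (TMP) length. `tmp_tail_length()` evaluates
`floor(0.15 · aa − 20.7)` nm; the coefficients are arguments rather than
constants since published fits vary, and the default reproduces the
~84 nm prediction for a 703-residue TMP.

## att sites and the bridging CDS

Integrative elements of haloarchaea typically recombine at the 3′ end of a
host tRNA gene. `find_att_core()` returns the longest tRNA 3′-suffix that
occurs exactly in the circular element (searching across the origin),
flagging multiple equally long placements as ambiguous; the floor of 8 bp
bounds chance matches (a specific 8-mer occurs by chance once per ~65 kb)
and is tunable. `integrate_element()`/`excise_element()` implement the
coordinate arithmetic: integration duplicates the core (attL ends the tRNA,
attR closes the element), excision leaves one core (attB) and returns the
circular element in a canonical rotation with the att core as its final
bases, so the attP junction is the origin. The two operations are exact
inverses, asserted over 100 random lysogens.

`find_bridging_cds()` scans the integrase strand of a circular element for
ORFs (starts ATG/GTG/TTG — archaeal initiation — stops TAA/TAG/TGA, ≥150 nt)
that begin within 100 bp of the integrase stop, span the attP position, and
end within 100 bp of (or overlapping) the next annotated CDS, whose product
is expected to carry at least two CxxC motifs (a warning flag is set when it
does not). The longest qualifying ORF wins ties. Such a CDS is complete only
in the circular form: the reported `provirus_form` gives the two pieces it
is split into across attL/attR after integration, and on synthetic lysogens
the 5′ piece verifiably reaches the end of the provirus without meeting a
stop codon. Integrase and CxxC genes are located by annotation (product
strings or explicit locus tags); no profile or homology search is performed.

## Induction evidence from reads

Three signals are combined, all by exact string matching — the reads this
package targets are high-quality short reads and the decisive evidence is
presence/absence, so no aligner is involved:

1. **Circular contigs.** `detect_circular_contig()` recognises a terminal
   exact overlap of at least 20 bp and trims one copy to the unit sequence.
2. **Junction-spanning reads.** `junction_sequences()` builds the attP
   junction (the joined termini of the excised circle) and the attB junction
   (host–core–host after excision); `count_spanning_reads()` counts reads
   containing the exact 40-mer centred on the junction point (20 bp anchored
   on each side), in either orientation. The attP junction does not exist in
   the intact lysogen, so a single spanning read is already informative.
3. **Coverage ratio.** `coverage_ratio()` places one central 31-mer anchor
   per read onto the host, using only host 31-mers that occur uniquely —
   which sidesteps the att duplication — and excludes att-core bases from
   both means. When several candidate proviruses are screened together, each
   candidate's span is masked from the others' background so one strongly
   induced element does not hide another.

`classify_induction()` calls *induced* (junction reads ≥ 2 and ratio ≥ 5),
*excision-only* (junction evidence at low copy — the patchy-coverage
pattern), or *silent*. The published evidence for induction is qualitative,
so these thresholds are conventions, not reproductions: induced elements in
real stocks show coverage some 50–1400× the chromosomal background, making 5
conservative, and 2 junction reads suffice because the attP 40-mer cannot
arise from the intact chromosome.

## The synthetic-data generator

`make_genome()` draws i.i.d. bases at a target GC content;
`deplete_motifs()` breaks every occurrence of chosen motifs (both strands,
circular reading) by single substitutions and re-scans to a fixed point,
leaving length unchanged. `build_lysogen()` assembles the full study
geometry: a 20 kb host contig (the analyses are local to the integration
region, so contig-scale context substitutes for a full chromosome) carrying
a 72 bp synthetic tRNA whose 3′-terminal 13 bp (the published core length)
are duplicated as attL/attR around a 6 kb circular element at 60% GC —
the size class and composition of real pleolipoproviruses, scaled to desk
runtimes. The element carries an integrase CDS, an unannotated bridging ORF
spanning the attP junction, and a CDS encoding exactly two CxxC motifs, with
every planted coordinate recorded in a truth ledger. att cores and planted
ORF bodies are drawn from {A, C, G}: with no T, no reading frame across the
junction can contain a stop codon, which keeps the planted bridging ORF
well-defined. This is a synthetic simplification — real att cores contain T
— and tests that depend on it say nothing about base composition of real
cores.

`simulate_reads()` draws reads from weighted template mixtures in three
topology modes: `circular` (uniform start, wrapping the origin), `headful`
(a virion first cut at a uniform rotation with 5% terminal redundancy — the
accepted 2–10% range for headful packaging — then a uniform read from the
virion), and `linear`. Strands are uniform, qualities a Q40 placeholder, and
a substitution-error rate is exposed but defaults to 0, matching the
exact-matching detectors downstream. `simulate_stock()` mixes the integrated
host with free circular element copies; `copy_ratio` counts *episomal*
copies per chromosome copy, so the expected inside/outside coverage ratio is
`copy_ratio + 1` (the integrated copy always contributes once) and the
episome copy number is recovered as `ratio − 1`. Identical seeds give
byte-identical FASTA/FASTQ.

What the generator does **not** emulate: sequencing errors and quality-score
structure, indels, amplification bias, repeat-rich host backgrounds, and
partial or degraded elements. Passing the synthetic end-to-end screen
therefore demonstrates the detectors' logic and calibration under clean
conditions, not their robustness to noisy libraries — on real data the exact
junction matching will undercount reads containing errors in the 40-mer
window, a deliberate conservative bias.

## Numerical and degenerate-input choices

G+C percentages are rounded half-up to one decimal, the convention of genome
tables (`round()`'s banker's rounding would print 67.75 as 67.8 or 67.7
depending on representation). Skew windows with no A+T contribute 0 rather
than NaN. Cumulative series are plain prefix sums with no reordering, so
reports are byte-reproducible. Tie-breaks are deterministic everywhere: the
smallest coordinate for skew extrema, the longest ORF for bridging-CDS
candidates, descending unit length for repeats. Degenerate inputs error
early with named checks (all-N sequences, flank 0 junctions, excisions with
nothing between the cores, reads shorter than anchors).

## Problem sizes and runtime

The test and acceptance workloads run on one CPU in minutes: k-mer oracles
on 200 × 2 kb inputs, repeat oracles at ≤2 kb, 100 integrate/excise round
trips and a 50-seed induction screen at 50× chromosomal coverage over the
default 20 kb + 6 kb lysogen (~28,000 reads per stock). These sizes are the
package's chosen study conditions for its own verification; the functions
themselves handle megabase hosts (the coverage estimator is linear in host
length and read count).

## Known limitations

- No homology, taxonomy or phylogenetic functionality; integrase/CxxC genes
  come from annotations, and prophage discovery in unannotated hosts is out
  of scope.
- The GenBank parser covers single-record flat files with simple,
  complemented and origin-wrapping locations only.
- Exact-match junction counting undercounts on error-containing reads;
  coverage anchoring ignores reads whose central 31-mer is non-unique in the
  host.
- `find_att_core()` searches the forward strand of the element; elements
  deposited in the reverse orientation should be reverse-complemented first.
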