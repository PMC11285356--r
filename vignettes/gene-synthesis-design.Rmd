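---
title: "Methods: Tm-matched fragment design for PCR gene synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Tm-matched fragment design for PCR gene synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesynth)
```

## Scope and model

`genesynth` designs the synthetic DNA needed to build a gene by
overlap-extension PCR: a set of fragments of one fixed length whose
junction overlaps share a common melting temperature, terminal gene
primers, an assembly-block plan with block primers, and an in-silico
verification that the ordered material can only reassemble into the
intended gene. Codon optimization, secondary-structure screening and
hairpin/dimer checks are deliberately out of scope: they are performed
upstream (optimization) or by vendor QC, and the inputs here are
assumed to be already optimized coding sequences over A/C/G/T.

### Melting temperature

All temperatures come from the unified nearest-neighbor model
(Allawi & SantaLucia 1997): enthalpy and entropy are summed over
dinucleotide stacks plus terminal initiation terms, entropy receives
the sodium correction $\Delta S' = \Delta S + 0.368\,(N-1)\ln[\mathrm{Na^+}]$,
and

$$T_m = \frac{1000\,\Delta H}{\Delta S' + R \ln C_T} - 273.15$$

with $R = 1.987$ cal mol$^{-1}$K$^{-1}$ and
$C_T = c_1 - c_2/2$ the effective strand concentration. The defaults —
25 nM for each strand, 50 mM Na$^+$ — are the de-facto defaults of the
scripting ecosystem most oligo-design pipelines use, so Tm values (and
the deviations printed in the result files) are interchangeable with
those tools. They are held in one `tm_parameters()` object so a
different salt/concentration regime (or a sensitivity analysis) is a
one-argument change. Because the model is strand-symmetric, every
overlap Tm applies equally to sense and antisense oligo sets.

Sequences below 8 nt are rejected rather than estimated: nearest-neighbor
sums are unreliable there, and no legitimate overlap or primer in this
design space is that short. Note the absolute Tm scale depends on the
salt/concentration convention by roughly 0.1–1 °C; the design only ever
*compares* Tm values, so this affects reporting, not fragment choice.

### Partitioning and overlap selection

Parameters (units, defaults, rationale):

| parameter | default | why |
|---|---|---|
| `fragment_len` | 59 nt | below the usual vendor price step for column oligos, long enough that overlaps stay a minority of each fragment |
| `tm_screen_min/max` | 54, 69 °C | half-open screened range of integer candidate annealing temperatures, the practical span of PCR annealing |
| `overlap_len_min/max` | 15, 35 nt | 15 nt is a practical minimum for specific annealing near 54 °C; 35 keeps overlaps well inside a 59-nt fragment |
| `remainder_min` | 20 nt | a terminal fragment should contribute at least a primer-sized stretch of new sequence |
| `max_block_size` | 9 | the largest fragment count per block we consider reliably assemblable in one reaction |

The partition is greedy and deterministic: the first fragment is the
first `fragment_len` nt; each junction overlap is the suffix of the
current fragment whose Tm is closest to the candidate target, ties
going to the *shorter* suffix (same Tm fit, cheaper synthesis); the
next fragment starts at the overlap's 5′ end. The terminal case
follows the remainder rule: if overlap + remainder falls short of
`fragment_len`, the last fragment is just overlap + remainder, unless
the remainder is under `remainder_min` nt, in which case
`remainder_min` nt are borrowed from the 3′ end of the penultimate
fragment and the overlap is re-selected on the sequence immediately 5′
of the extended remainder.

Two consequences of the borrowing rule are worth stating precisely,
because they were genuine design choices. First, the borrowed bases
become part of the *last* fragment only; the penultimate fragment is
unchanged. Second, at a borrowed junction the reported overlap — the
Tm-selected k-mer that is the last fragment's 5′ prefix — ends
`remainder_min` nt before the penultimate fragment's 3′ end, so the
physically shared terminal region is `k + remainder_min` nt. The
alternative (declaring the whole shared region as "the overlap") would
report a 35–55-mer whose Tm sits 10–15 °C above every other junction,
which would both misstate what was optimized and wreck the screening
statistic below. The longer physical overlap only helps bridging, so
assembly is unaffected; the coordinate bookkeeping
(`start`, `end`, `overlap_len`) makes the geometry explicit in the
output, and reconstruction is defined coordinate-wise (drop the region
shared by coordinates), so it is lossless in every case.

Degenerate inputs: a gene no longer than `fragment_len` is returned as
a single fragment with gene primers only (and genes under ~100 nt
trigger a note that two annealed complementary strands are the cheaper
route). A gene shorter than `overlap_len_max` is an error — there is
nothing to search.

### Screening the annealing temperature

Every integer candidate in `[tm_screen_min, tm_screen_max)` is
partitioned independently, and the accepted design minimizes

$$\max_i \left| T_{m,i} - \overline{T_m} \right|$$

the worst junction deviation from the design's own mean junction Tm.
This quantity, rather than variance or mean absolute deviation, is the
selection criterion because it is exactly what limits a single shared
annealing temperature: one outlying junction is what makes an assembly
fail. Ties go to the lowest candidate (lower annealing temperatures
are more forgiving for A/T-rich overlaps). The gene primers are then
tuned to the winning design's $\overline{T_m}$ — not to the candidate
target — because what matters at the bench is that the primers anneal
together with the overlaps, and $\overline{T_m}$ is where the overlaps
actually landed. The primers are reported against $\overline{T_m}$ but
excluded from computing it: they are not junctions, and including them
would let primer choice shift the statistic the junctions are screened
on.

### Blocks and cycle counts

Fragments are grouped into $\lceil n / \texttt{max\_block\_size} \rceil$
consecutive blocks with sizes as equal as possible (pairwise within
one) and smaller blocks first; the remainder fragments go to later
blocks. Adjacent blocks share exactly one junction, so block primers
need no separate optimization: block 1's forward primer is the sense
gene primer, each interior boundary re-uses the sense overlap sequence
(forward) and its reverse complement (reverse), and the last block's
reverse primer is the antisense gene primer. Their Tm is reported but
not re-optimized — they *are* the Tm-matched overlaps.

Minimal PCR cycle counts follow the two assembly mechanisms: all-sense
(method A) assembly is linear — the first cycle copies the last
fragment off the antisense gene primer, then each cycle joins one more
fragment, $n$ cycles in total (the priming cycle is counted, a
convention fixed by the simulator below); alternating-strand (method
B) assembly merges every adjacent pair per cycle,
$\lceil \log_2 n \rceil$ cycles. One fragment needs zero cycles.

### In-silico verification

`simulate_assembly()` is a design-correctness oracle, not a kinetics
model: fragments bridge if and only if their terminal sequences share
an *exact* overlap of at least `overlap_len_min` nt. Every oligo is
treated as double-stranded (as it is after one extension cycle), so
any fragment may be supplied on either strand; the simulator tries
both orientations of both partners at each merge. If a neighboring
pair can join into more than one distinct product the outcome is
failure with a diagnostic — ambiguous bridging predicts mis-assembly
even though a thermodynamic model might still rank one product first;
this is deliberately conservative. The threshold choice (the design's
own minimum overlap length) avoids spurious short matches; what
overlap length suffices for bridging *in vitro* is a wet-lab question
the simulator does not answer. Success additionally requires both gene
primers to map to the product's ends, and the product is reported
sense-oriented (assembling every oligo reverse-complemented yields the
reverse-complement duplex, which is the same molecule).

`linear` mode merges strictly right-to-left, one fragment per round;
`pairwise` mode merges all disjoint adjacent pairs per round. On clean
designs the rounds used equal the closed-form cycle counts above,
which ties the planner's formulas to the mechanism they summarize.

## What the synthetic-data generator does and does not emulate

`random_gene()` draws bases i.i.d. with $P(G) = P(C) = \mathrm{gc}/2$.
That exercises the properties the algorithm actually depends on —
GC-dependent Tm spread along the sequence, arbitrary remainder lengths
(so the borrowing rule triggers in about a third of random lengths),
variable best-overlap lengths — while remaining reproducible from one
integer seed without touching the caller's RNG state. It does *not*
emulate codon structure, repeats, homopolymer runs, GC gradients or
secondary structure. Passing tests therefore demonstrate algorithmic
correctness (lossless partitioning, oracle-equal optimization,
reassembly from any strand mixture), not that every real gene yields
an experimentally easy design — a gene with long exact repeats can
still produce ambiguous bridging, which is exactly what the verifier
flags.

## Validation problem sizes

The shipped tests validate on: 50 random genes of 600–3000 nt at GC
0.35–0.65 (lossless partition, method A/B reassembly plus ten random
strand-flip variants each, and exhaustive-search agreement of both the
overlap selection and the temperature screening); constructed designs
of exactly 2–32 fragments for the cycle-count laws; and the worked
block-plan examples (20 fragments at ≤7 per block → 6+7+7, 22 → 5+5+6+6,
27 at ≤9 → 9+9+9). These sizes were chosen as representative of the
100 nt–5 kb genes the tool targets while keeping the suite quick on a
laptop. One further check runs only when the deposited example gene it
refers to (`beta_optimized.fasta`, from the original published design
run) is placed under `inst/extdata/`; it is not redistributed with the
package.

## Numerical and formatting choices

- All design steps are deterministic; identical inputs give identical
  designs, and the CLI's table output is byte-identical across runs.
- Coordinates are 1-based inclusive in every user-facing table
  (`start_pos-end_pos`), 0-based arithmetic only internally.
- Temperatures are printed to two decimals in the text tables; the
  JSON export keeps full double precision.
- Argmin searches resolve exact ties by order of enumeration: shortest
  overlap, shortest primer, lowest candidate temperature.

## Known limitations

- No mismatch tolerance in bridging: a vendor synthesis error that
  changes an overlap is outside the model.
- No hairpin/self-dimer screening of overlaps or primers; strongly
  structured genes should be sequence-optimized upstream.
- The Tm parameterization is fixed per design; comparing deviations
  across designs computed under different `tm_parameters()` is not
  meaningful.
- Block boundaries are fixed by count only, never re-optimized by Tm
  or GC of the boundary overlaps.
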