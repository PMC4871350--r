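---
title: "Selectivity analysis of phage display deep sequencing screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selectivity analysis of phage display deep sequencing screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selpep)
```

## The problem

Biopanning selects peptide-displaying phage against a target, but the
abundance of a clone after selection reflects three things at once: affinity
for the target, its (highly unequal) starting abundance in the naive
library, and how fast its host bacterium amplifies it between rounds —
so-called parasitic clones can dominate a screen without binding anything.
For targeting applications (drug delivery, molecular imaging) a fourth
dimension matters: a candidate must not only bind the target, it must
*avoid* the other cell types it will meet in vivo. Selectivity therefore has
to be estimated by comparing many independent screens — several replicates
against the target (positive screens), several against counter-targets
(negative screens) — rather than by inspecting any single screen.

`selpep` implements this comparison in two parts.

## Part one: from reads to peptide frequencies

Each demultiplexed FASTQ is processed independently
(`process_screen()`). The randomized insert is located by exact search for
the library's constant flanking signatures — for the NEB Ph.D.-7 library,
`TCT` on the 5' side and `GGAGGTGGA` on the 3' side of a 21-nt insert. The
search anchors on the longer, more specific 3' flank and then verifies the
5' flank immediately upstream of the insert window; the leftmost position
satisfying both conditions wins. Anchoring on `TCT` alone would be
hopeless: a random 70-mer contains it by chance more often than not.

Accepted inserts are checked against the library's degenerate-codon design.
NNK codons (any base, any base, G/T) cover all 20 amino acids while
excluding the ochre and opal stops; a read containing a codon outside the
design cannot derive from a real library member and is far more likely a
sequencing error or PCR artifact, so it is removed (32 of 64 codons pass,
which the test suite verifies by enumeration). The amber codon TAG is
*within* the NNK design and is translated as glutamine by default
(`amber_as_gln`): the commercial libraries are propagated in supE
amber-suppressor hosts, so TAG clones are genuine library members;
discarding them would silently delete a sixteenth of the sequence space.
Under unconstrained schemes, inserts containing terminating stops are
counted as stop-rejections, never translated to a stop symbol.

Every read lands in exactly one accounting bin — accepted, no qualifying
flank pair, ambiguous base (N) in the insert, codon outside the design, or
stop codon — and the partition `total = accepted + rejections` is asserted
as a class invariant. Quality scores are ignored entirely; the codon filter
and flank match do the error screening. Flank matching is exact: with a
per-base error rate around 10^-3^, roughly 1% of reads lose a 12-nt flank
pair to an error, a negligible and unbiased loss.

## Part two: normalization, imputation, ranking

Let $c_{ps}$ be the read count of peptide $p$ in screen $s$ and $N_s$ the
screen's **total** read count (all reads in the FASTQ, matching how run
summaries report depth, not accepted reads only). Two divisions produce the
normalized frequency:

$$ f_{ps} = \frac{c_{ps}/N_s}{c_{pR}/N_R} $$

where $R$ is the **reference library**: an aliquot of the unselected naive
library, amplified and sequenced alongside every run. Division by the
reference is what cancels the two non-affinity signals — naive-pool skew
and parasitic amplification both inflate numerator and denominator alike.
A peptide absent from the reference divides by the reference's *non-zero
mode* instead (`nonzero_mode()`): the most common strictly positive
depth-normalized frequency, which in real screens is the singleton class,
i.e. the natural "just detectable" level. Ties in the mode's multiplicity
break toward the smaller value, keeping imputation conservative.

The comparison matrix (`build_matrix()`) has one row per peptide observed
in *any* positive or negative screen and one column per screen. A peptide
absent from a screen takes that screen's non-zero mode of the fully
normalized values, flagged in a parallel imputation mask — never zero,
which would send ratios to 0 or infinity. Mode imputation is applied to the
fully normalized values (not the depth-normalized ones) because it is the
last step before the ratio. Each row's sort key is the **selectivity
ratio**

$$ r_p = \frac{\operatorname{mean}_{s \in P} f_{ps}}{\operatorname{mean}_{s \in N} f_{ps}}, $$

an arithmetic mean over positive screens divided by the arithmetic mean
over negative screens, including imputed cells. Rows sort by $r_p$
descending; ties break by mean positive value descending, then
lexicographically, so every run of the pipeline on the same inputs is
byte-identical. The reference column itself shows the reference's
depth-normalized frequencies (dividing the reference by itself would be a
constant 1); it provides the background context in the exported matrix and
takes no part in the ratio.

The matrix also carries `positive_support`, the number of *observed*
(non-imputed) positive cells per row. The ranking deliberately stops short
of automated candidate calling: the intended use is to inspect the top
fraction and favour peptides supported by two or more positive replicates,
which is what this column encodes.

### The designed worked example

`designed_test_library()` builds eight 7-mers whose frequencies in a
reference, two positive and two negative screens are coded absent (0), low
(10) or high (1000) at equal per-screen depth. The expected behaviour is
checked as a frozen golden test:

```{r golden}
g <- designed_test_library()
m <- build_matrix(normalize_screens(g$tables, g$assignment), g$assignment)
as.data.frame(m)
```

`GVTHKLQ` (high in both positives, absent elsewhere) tops the table at
ratio 100; `TPSIYFL` (high only in negatives) is last at 0.01; `RVSTPPQ`
(high in one positive but also one negative) sits mid-table at ratio 1.
`SSDAALH` is the instructive case: high in *every* screen, it is abundant
but not selective, and its ratio is exactly 1. Note that for a peptide
observed in all compared screens the per-peptide reference denominator
cancels out of the ratio, so no amount of reference abundance can move it —
such a clone can never be separated *below* the equally-flat background by
the ratio sort; what the sort guarantees, and what the test asserts, is
that it never enters the selective top fraction.

### Re-sorting and round-to-round enrichment

Because roles are metadata, the same normalized screens answer different
targeting questions: `resort_with_roles()` rebuilds the matrix under a new
assignment without touching FASTQ, and ubiquitous-binder mode ranks by each
row's minimum across all screens (descending) to surface pan-binders —
useful both for finding broad binders and for blacklisting sticky clones.
`round_enrichment()` reports mean round-two over mean round-one normalized
frequency across positive screens (each round normalized to its own
reference), a selection-trajectory signal that is independent of the
between-screen comparison.

## The synthetic-screen generator

The simulator exists so the full pipeline can be exercised against planted
truth. It emulates exactly the statistical structure the analysis assumes:

* **skewed naive pool** — `generate_naive_pool()` draws distinct
  codon-valid inserts with log-normal weights (default sigma 1.5, spanning
  roughly three orders of magnitude, a realistic skew for an amplified
  naive library);
* **selective enrichment** — multiplicative spike factors applied in
  positive screens only;
* **parasitic amplification** — multiplicative factors applied in *every*
  screen including the reference, which is what makes them cancellable;
* **sequencing error** — independent per-base substitutions (default
  10^-3^). Indels are deliberately excluded: an indel would break the flank
  anchor and fold into the no-flank bin, conflating error modes in tests.
  Quality lines are constant because the pipeline ignores them.

Reads embed `flank5 + insert + flank3` inside fixed primer-like padding so
extraction must genuinely search. `simulate_round2()` composes rounds
multiplicatively: a clone spiked at $e$ per round is enriched $e^2$ after
two.

What the simulator does *not* model: PCR-cycle stochasticity, phage growth
kinetics, chimeric reads, quality-correlated errors, and indels. Passing
the recovery benchmark therefore demonstrates that the analysis logic is
sound under its own model assumptions, not that every artifact of real
MiSeq data is handled.

### The recovery benchmark

`spiked_recovery_run()` is the package's standard end-to-end benchmark: a
10,000-clone pool at skew 1.5, seven screens (one reference, three
positive, three negative) of 100,000 reads each (mean coverage 10 reads per
clone), five selective clones spiked 50-fold in positives, five parasitic
clones amplified 20-fold everywhere, substitution error 10^-3^. Recovery is
counted as presence in the top 1% of matrix rows. Across the ten-seed test
protocol all spikes are recovered and no parasitic-only clone reaches the
top fraction.

The benchmark sits intentionally near the detection limit: under log-normal
skew, an occasional spiked clone has expected naive coverage below one read
per screen, and no analysis can recover a clone the sequencer effectively
never saw; conversely a rare parasitic clone that happens to draw zero
reads in all three negative screens can transiently cross the top-1%
boundary through imputation. Both behaviours argue for the paper-style
practice the matrix supports: require observed support in at least two
positive replicates (`positive_support`) before shortlisting.

## Numerical and design choices

* **Exact flank matching, forward strand by default.** Mismatch-tolerant
  flank search would trade a ~1% unbiased read loss for ambiguous anchor
  placement; `try_revcomp` retries failed reads on the reverse complement
  for protocols with mixed orientation.
* **Leftmost qualifying flank pair** when a read contains several `flank3`
  occurrences; deterministic and order-independent.
* **Arithmetic means** in the ratio (not geometric): imputed cells carry
  the mode, so no zero can enter, and the arithmetic mean matches the
  "average normalized frequency" semantics of the method.
* **Tie-breaks** (mean positive descending, then peptide lexicographic)
  exist purely for reproducibility; ties at identical ratios carry no
  selectivity information.
* **Unbounded screen counts**: any number of positives and negatives is
  accepted; one reference is mandatory, and configurations without it are
  rejected at validation.
* **Degenerate inputs**: empty FASTQ yields a valid all-zero screen with a
  warning; zero total reads is an error at normalization; an empty
  peptide union is an error at matrix construction.
* **Problem sizes in the test suite** (50 fixture FASTQs of up to 1,000
  reads; ten 7-screen recovery runs at 100k reads) are the package's
  standard desk-scale verification set, small enough to re-run routinely
  while giving the binomial checks three-sigma resolution.

## Limitations

The analysis ranks; it does not test. No p-values or error bars accompany
the ratio — with typical screen-to-screen variability the honest unit of
evidence is replication across independent screens, not a variance estimate
within one. Near-identical peptides are counted separately (no clustering
or error correction of reads into parent clones), motif discovery is out of
scope, and the final step of any real campaign remains inspection of the
top fraction against the imputation mask and support counts.
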