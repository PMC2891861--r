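---
title: "Methods: differential proteomics and ARE scanning with nrf2prot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential proteomics and ARE scanning with nrf2prot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrf2prot)
```

# The measurement model

iTRAQ reporter ratios are multiplicative: a protein's reporter intensity in
one animal is divided by the intensity in a designated reference wild-type
animal, so values scatter around their true relative abundance with
multiplicative, approximately log-normal error. Every summary in this package
therefore lives on the log scale:

* the per-genotype location estimate is the **geometric mean**
  $\mathrm{GM} = \exp\!\big(\tfrac1n\sum_i \ln r_i\big)$;
* its **95% confidence interval** is the normal-quantile interval on logs,
  $\exp\!\big(\overline{\ln r} \pm z\, s_{\ln r}/\sqrt n\big)$ with the
  sample ($n-1$) standard deviation and $z = 1.96$ by default
  (`lognormal_ci(..., z =)` keeps $z$ configurable);
* the **effect size** is the ratio of unrounded geometric means,
  $\mathrm{FC} = \mathrm{GM}_{KO}/\mathrm{GM}_{WT}$.

A $z$ rather than a $t$ quantile is used deliberately: with the interval
defined this way, the bundled per-animal expression values reproduce the
reference group summaries cell-for-cell at two decimals, whereas a
$t$-quantile interval does not. With $n = 4$ animals per genotype the
interval is anticonservative as a frequentist CI; it is reported as a
variance description, which is how it is used here.

Replicate runs are averaged within each animal **arithmetically** before any
group summary (`aggregate_runs()`, with a geometric option behind the
`method` flag, since "average" is ambiguous for ratios and the difference is
second-order at these noise levels). Only proteins carrying a value for
*every* animal in the design enter inference (`complete_case_filter()`),
mirroring the complete-data acceptance rule of multi-run reporter designs.

# Hypothesis testing and acceptance

Per protein, each genotype's values are checked for normality with
Shapiro–Wilk at $\alpha = 0.05$; if both groups pass, an unpaired Student
t-test is run, otherwise the Mann–Whitney rank test (`choose_test()`,
`raw_p()`). Choices a user may care about:

* **t-tests are run on ln-ratios** by default, coherent with the
  geometric-mean effect scale (raw-scale option retained; the underlying
  study does not state which was used, and no printed value lets us decide).
  The normality gate is applied on the same scale as the t-test.
* **Pooled variance** is the default (the design reports F-tests for
  variance equality alongside); Welch is available via `var_equal = FALSE`.
* The Mann–Whitney test uses exact enumeration for group sizes up to 8 and
  the tie-corrected normal approximation beyond, via `stats::wilcox.test`.
* Degenerate inputs are defined, not crashed on: zero variance in both
  groups under a t-test returns $p = 1$ with a warning, as does a
  complete-tie rank test; a constant group cannot be assessed by
  Shapiro–Wilk and is routed to the rank test.

Raw p-values are Benjamini–Hochberg adjusted (`bh_adjust()`, the standard
step-up) **across all quantified proteins**, and a protein is accepted when
both $p < 0.05$ and $\mathrm{BH} \le 0.2$ (`select_significant()`). The
permissive BH cut avoids discarding co-regulated proteins through an overly
stringent multiplicity correction; both thresholds are arguments.

The 2DE stage (`gel_de()`) applies the same testing machinery to spot
intensities normalized to percent of each gel's total matched intensity.
Normalization is defined on the full matched set only — re-normalizing a
subset is refused by construction since it would break the per-gel
conservation property. The inclusion rule (`spot_inclusion()`) demands a
spot be matched on every gel of at least one treatment group (`"any"`,
default) or of both (`"both"`).

Concordance across analyses (`concordance()`) is set intersection after
applying an explicit alias table, not fuzzy matching: the bundled map
records that major urinary protein 6 appears under two SwissProt accessions,
and any such identification must stay auditable.

# Promoter scanning

Promoters are handled 5'→3' with the base immediately upstream of the start
codon at offset −1 and a 2000-bp promoter starting at −2000; a W-mer
starting i bases into the sequence spans offsets $i-L-1$ to $i+W-L-2$. This
convention makes a 13-wide best hit print as, e.g., "−1935 to −1923".

The **consensus scanner** (`consensus_scan()`) tests every window
(overlaps allowed, no masking) against per-position allowed-base sets. The
default alphabet follows the classical ARE convention R = G/C, B = G/C/T —
*not* standard IUPAC — because that is how the consensus `RTGABNNNGCA` was
defined; `alphabet = "iupac"` switches to the standard code, and
`are_consensus()` ships the two published variant strings (`"tca"`,
`"perfect"`) without deciding between them. `N` in a sequence matches no
pattern letter.

The **PSSM scanner** (`build_pssm()`, `pssm_scan()`) forms natural-log
odds $w(b,i) = \ln\frac{f(b,i)+\varepsilon}{(1+4\varepsilon)\,p(b)}$ from a
position probability matrix and a background $p$, and scores a window by
summing weights. Windows scoring above 1 (natural-log units, the patser
convention) count as matrix matches; both strands are scanned by default,
minus-strand hits reported in plus-strand coordinates. The background
(`background_frequencies()`) pools counts over the whole promoter panel and
symmetrizes A/T and C/G, as appropriate for double-stranded DNA; on
genome-like mouse promoter panels this lands near A/T 0.26, C/G 0.24. The
pseudocount default is $\varepsilon = 0.001$, needed only when the matrix or
background contains zeros; $\varepsilon = 0$ with zeros is an error rather
than a silent −∞. Windows containing `N` are skipped and counted in a
message.

The probability matrix is a user input (a simple 4×W whitespace table). The
historically cited core-ARE matrix is not publicly printed, so the bundled
`are_pssm_synthetic.tsv` is a synthetic stand-in built from the consensus
pattern (0.88 shared across allowed bases per position); all numeric tests
use synthetic matrices, and no published matrix-score value is asserted
anywhere.

Gene-set over-representation (`hypergeom_enrich()`) is the literal sampling
model: the upper-tail hypergeometric probability of observing at least the
overlap seen, given the quantified universe. No multiplicity correction is
applied by default (pathway p-values are conventionally reported raw);
`bh_adjust()` composes if wanted.

# What the generators emulate — and what they do not

`simulate_itraq()` draws $\ln r = \ln(\text{fold}) + N(0, cv^2)$ per
(protein, animal, run), with the reference animal pinned at exactly 1 (it is
the denominator of the labelling scheme). Defaults mirror the study design:
4 animals per genotype, 4 replicate runs, cv 0.2 (a realistic log-scale
spread for reporter ratios of abundant liver proteins). Whole (protein, run)
blocks can be dropped (`missing_run_rate`) to mimic run-to-run coverage
differences; individual cells can be dropped (`missing_cell_rate`, default
0) to exercise the complete-case rule, which block dropout alone cannot.
`simulate_spot_table()` and `simulate_promoters()` plant known effects and
motifs the same way; `simulate_promoters()` defaults to 2000 bp and the
A/T 0.26, C/G 0.24 composition.

The generators deliberately do **not** emulate: peptide-level roll-up and
shared peptides, reporter-ion compression and label bias (the tag swap in a
replicate run is an experimental control, not a computation), correlated
missingness tied to abundance, gel warping or spot-boundary errors, or
promoter sequence structure (CpG islands, repeats). Passing tests therefore
demonstrate correctness of the statistical machinery under the stated noise
model, not robustness to those instrumental artefacts.

Every generator takes a mandatory single-integer seed and is bit-reproducible
given it; the caller's RNG state is left untouched.

# Numerical choices and test scale

Computations are double precision throughout; reports render two decimals to
match conventional tables, and tests compare at |Δ| ≤ 0.005 on that scale.
Some published fold-change cells derive from unrounded source data and
cannot be recomputed from the printed 2-dp per-animal values; the test suite
asserts the ~90% of rows that are recomputable and documents the rest rather
than loosening the tolerance. Ties in scanning are kept (all overlapping
matches counted); the best hit per gene is the maximum score with the first
position winning ties via `which.max`.

Test problem sizes were chosen so the full suite runs in about a minute:
type-I error on 1000 simulated null proteins (observed ≈ 0.045 against the
0.05 ± 0.02 band), realized false-discovery proportion over 200 seeded
replicates of 100 proteins with 10% true fold-2 effects (observed ≈ 0.18
against the ≤ 0.25 bound implied by BH at 0.2 plus Monte-Carlo error), and
scanner/oracle equivalence on 100 random 500-mers. Larger sizes change
nothing qualitatively.

# Known limitations

* The z-quantile CI is descriptive at $n = 4$; users wanting coverage
  guarantees should pass a $t$ quantile via `z = qt(0.975, n - 1)`.
* P-values recomputed from run-averaged 2-dp per-animal values (as in the
  bundled example tables) are only indicative; the original per-run data are
  not public.
* The hypergeometric model treats gene sets as fixed and genes as
  exchangeable; it does not reproduce proprietary curated-pathway scoring.
* Matrix scanning reports raw scores, not p-values; the score-distribution
  calibration of the original patser is out of scope.
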