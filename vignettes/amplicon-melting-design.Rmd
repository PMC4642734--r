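---
title: "Designing variant amplicons from DNA melting profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing variant amplicons from DNA melting profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltamp)
```

## The problem

Melting-based mutation detection — constant and cycling temperature capillary
electrophoresis (CDCE/CTCE) and high-resolution melting (HRM) — separates or
distinguishes alleles by the temperature at which a short PCR product
partially denatures. Designing a working assay for a given DNA variant means
solving four coupled problems at once:

1. pick a primer pair that brackets the variant in a 70–140 bp product;
2. make sure that pair amplifies exactly one region of the genome;
3. decide whether (and on which side) to extend the product with an
   artificial GC-rich high-melting domain (a *GC-clamp*) so the molecule
   opens progressively from one end instead of falling apart;
4. predict the per-base melting behaviour of both alleles and the
   temperature at which the instrument should run.

`meltamp` performs all four steps offline for batches of variants against any
FASTA genome, and ships a seeded synthetic-genome generator so the whole
pipeline is testable without a reference build.

## The melting model

The core of the package is an equilibrium statistical-mechanical model of
duplex DNA of the Poland–Scheraga type. A molecule of $n$ base pairs is in a
configuration in which every base is either *closed* (helical) or *open*
(denatured); a configuration's statistical weight is the product of

* a nearest-neighbor stacking weight $\exp[-(\Delta H_i - T\Delta S_i)/RT]$
  for every adjacent pair of closed bases, using the unified SantaLucia
  $\Delta H/\Delta S$ tables with the monovalent-salt entropy correction
  ($+0.368\,\ln[\mathrm{Na^+}]$ cal mol$^{-1}$K$^{-1}$ per stack);
* a loop weight $\sigma\, g(L)$, $g(L) = (L+d)^{-c}$, for every *internal*
  run of $L$ open bases, where $\sigma$ is the cooperativity parameter and
  $c$ the loop-closure exponent;
* unit weight for open runs at the molecule's ends (free tails); and
* one association weight per molecule,
  $\beta(T) = \frac{C_T}{4}\exp[-(\Delta H_{init} - T\Delta S_{init})/RT]$,
  carrying the duplex initiation terms of the two terminal base pairs and
  the translational entropy of bimolecular association at total strand
  concentration $C_T$. The fully dissociated state has weight 1.

The per-base closing probability is then
$p_i(T) = \beta F_i B_i / (1 + \beta Z)$, computed by forward/backward
partial-partition-function recursions. The power-law loop weight would make
these recursions quadratic; following Fixman and Freire, $g(L)$ is replaced
by a sum of exponentials $\sum_k a_k e^{-b_k L}$, restoring linear time. The
fit (14 exponentials, decay rates log-spaced over loop lengths
$10^{-0.5}$–$10^4$, amplitudes by relative-error-weighted least squares on
$L = 1\ldots10^4$) is performed at model construction and asserted to stay
within 1% relative error; its measured residual is about $8\times10^{-4}$.
The sum-of-exponentials *is* the loop function the model uses — the
enumeration tests in the test suite use the identical weight rules, so they
verify the recursion, while the fit quality is asserted separately.

The per-base melting temperature is the temperature at which $p_i$ crosses
0.5 (the conventional melting-map definition; the crossing is located by a
1 °C scan over 0–120 °C, auto-widened to −100…250 °C when needed, and
refined by bisection to 0.01 °C, taking the lowest crossing when there are
several). Defaults: $\sigma = 1.26\times10^{-4}$, $c = 2.15$, $d = 1$
(the Blossey–Carlon reparameterization of the loop entropy),
$[\mathrm{Na^+}] = 0.05$ M, $C_T = 5\times10^{-8}$ M. All are configuration
keys of `default_model()`; changing them changes numbers, never code paths.

```{r model}
m <- default_model()
m
```

Two limits anchor the model. With the cooperativity $\sigma \to 0$ internal
loops vanish and the 50%-helicity temperature of a short duplex approaches
the classical two-state nearest-neighbor melting temperature
$T_m = \Delta H/(\Delta S + R\ln(C_T/4))$ — the same formula `primer_tm()`
uses for primer annealing temperatures, so the two temperature scales in the
package are mutually consistent. And because every weight is strand
symmetric, the melting profile of a reverse-complemented amplicon is the
reversed profile.

```{r profile}
amp <- paste0(strrep("AT", 15), strrep("GCGT", 15), strrep("TA", 15))
prof <- melting_profile(amp, m)
plot(prof$tm_per_base, type = "l", xlab = "base", ylab = "Tm (deg C)")
```

### What the absolute temperatures mean

Absolute per-base Tm values depend on the salt and strand concentrations,
which are design choices here; profile *shape* (domain structure, which half
melts hotter, the local effect of a variant) is the robust, decision-driving
output. The analysis temperature reported for capillary electrophoresis
corrects the target's average melting temperature for the denaturant in the
matrix at −3 °C per molar urea, exactly linear:

```{r urea}
analysis_temperature(avg_tm = 75, urea_molar = 1)
```

## Primer selection

Primer pairs are enumerated exhaustively on the reference window under hard
constraints (length 18/20/27 bp, Tm 57/60/63 °C, GC 20–80%, product
70–140 bp for *both* alleles, 3'-anchored self/cross complementarity of at
most 4 bases, at least 5 bases between each primer's 3' end and the
variant) and ranked by the declared additive penalty
$$\mathrm{penalty} = |l_f - l_{opt}| + |l_r - l_{opt}| +
  |T_f - T_{opt}| + |T_r - T_{opt}| + |T_f - T_r|,$$
with deterministic tie-breaking (shorter product, then leftmost, then
lexicographic). This is a deliberately simplified, fully specified selector
in the spirit of Primer3's defaults rather than a re-implementation of its
objective: it is self-contained, reproducible, and the test suite verifies
the top pair against a brute-force argmin. The constraint defaults are
exposed in `primer_constraints()` because published screenshots of such
tools do not pin them; the 70–140 bp product window reflects the target size
range over which melting electrophoresis resolves point mutations.

The top-ranked pair is then checked by in-silico PCR: every genomic site of
either primer on either strand (exact match by default; the 3'-terminal base
must always match, because a 3' mismatch blocks extension), paired in
convergent orientation within 4000 bp. Exactly one product is required;
anything else rejects the assay with status "No primers found", because
multi-site amplification usually fails at the bench. By default only the top
candidate is tried — the paper-faithful stop-at-first-candidate behaviour —
with `retry_depth` available to walk deeper when a rejected assay is worth
rescuing.

## GC-clamp placement

The shipped clamp is the published 43-nt all-GC sequence
(`DEFAULT_CLAMP_SEQ`; often described as a 42-bp clamp — the printed
sequence is kept verbatim and is user-replaceable). Four placement modes
mirror the original menu: `none`, `automatic`, `five_prime`, `three_prime`.
Automatic mode splits the unclamped reference amplicon at `floor(len/2)` and
attaches the clamp to the half with the higher mean per-base Tm (ties go
5'), so the melting temperature decreases *away* from the clamp and the low
domain melts without dips; amplicons carrying insertions/deletions always
take the clamp at the 5' end, keeping the allele-length difference in the
low-melting domain. The half-split operationalizes "the side with the
highest average melting temperature", which the original description leaves
undefined; it is a config point (`choose_clamp_side()` is public) rather
than a hard-wired rule. On the sequence level the clamp is concatenated
verbatim on either end: the physical construct tails one primer, but the
melting model is strand-symmetric, so concatenation captures the
thermodynamics.

The reported "Avg Melt Temp" is the mean per-base Tm over the inter-primer
target of the *reference* allele, excluding primers and clamp (the stable
choice where the original tool is silent about the allele and the clamp).

## The synthetic-data generator

`make_fixture_genome()` emulates the study conditions the pipeline faces on
a real genome at desk scale: uniform-random chromosomes (4 × 50 kb by
default), planted substitution variants in unique ~1 kb contexts, and a
chosen fraction of loci whose ±250 bp context is copied verbatim elsewhere —
wide enough that *every* candidate amplicon (≤140 bp around the variant) is
duplicated, forcing the specificity check to reject the locus. The truth
table it emits (expected `ok` vs `no_primers_found` per locus) is what the
acceptance tests and `scripts/acceptance.R` score the pipeline against.

What it does not emulate: real base composition and repeat structure
(uniform random sequence has no Alu-type repeat families, so specificity is
*easier* than on a mammalian genome), ambiguity codes, near-duplicates that
differ by a few mismatches, and indel variants. Passing the fixture suite
therefore demonstrates the pipeline's logic — constraint handling,
specificity classification, clamp placement, temperature bookkeeping — not
its rejection rate on hg19-scale inputs (the published workflow reports
whole-genome rejection examples that require the actual reference build,
which this offline package deliberately does not bundle).

## Numerical choices and degenerate inputs

* Bisection tolerance 0.01 °C; profile values are midpoints of the final
  bracket, so two independent computations of the same crossing agree to
  0.01 °C.
* A base whose closing probability never crosses 0.5 inside −100…250 °C
  gets an `NA` sentinel and a warning rather than a fabricated value.
* Windows containing `N` are a hard error by default (`allow_n` keeps them,
  flagged `ambiguous`): the nearest-neighbor tables are undefined there.
* Unresolved rsIDs abort a batch by default, listing the offenders
  (mirroring "invalid rs numbers must be removed prior to execution");
  `skip_invalid` downgrades them to `invalid_input` rows.
* Coordinates are 1-based inclusive everywhere in the R API (the
  Bioconductor convention); BED exports are 0-based half-open per the BED
  spec; every output file states its convention in a header line.
* Duplicate representations of the same variant (rsID and coordinate spec)
  produce identical rows by construction; batch mode keeps both rows and
  logs the duplication rather than deduplicating silently.
* Everything is deterministic: there is no randomness anywhere in the
  design path, and repeated runs are byte-identical.

## Problem sizes used in the tests

The packaged test suite exercises the recursion against exhaustive
enumeration for all sequences up to length 6 plus random sequences to length
12 (the enumeration oracle is $O(2^n)$), strand symmetry on 60–140-mers,
and the full pipeline on five seeded fixture genomes of 4 × 50 kb with 20
loci each (30% duplicated). These sizes were chosen so the properties under
test are fully expressed — amplicon-scale profiles, genome-scale uniqueness
— while the suite stays comfortably runnable on a laptop.

## Limitations

* Equilibrium model only: no kinetics, no temperature-dependent heat
  capacity, no bubble-size statistics.
* Primer scoring omits hairpin/dimer thermodynamics and mispriming
  libraries; the 3'-complementarity screen is an exact-match run length.
* In-silico PCR matches exactly by default; permissiveness is a knob
  (`max_mismatch`), not an attempt to model polymerase tolerance.
* Absolute melting temperatures are condition-dependent (salt, strand
  concentration, the NN table choice); treat profile shape and temperature
  *differences* as the primary outputs.
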