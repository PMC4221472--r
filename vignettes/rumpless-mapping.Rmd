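---
title: "Mapping a dominant trait by segregation filtering and recombinant exclusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant trait by segregation filtering and recombinant exclusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumpmap)
```

## The problem

The rumpless (*Rp*) phenotype of the Araucana chicken — absence of the free
caudal vertebrae and pygostyle — is inherited as a fully penetrant
autosomal dominant trait that linkage work placed in a ~740 kb region of
chromosome 2 harbouring the *IRX1*/*IRX2* cluster. With whole-genome
sequence from a handful of birds of known genotype class, the causal
mutation can be cornered by purely combinatorial means:

1. **Segregation filtering.** Every small variant in the region is tested
   against the genotype pattern the dominant model forces: homozygous-alt
   in homozygous affected birds, heterozygous in heterozygous affected
   birds, and absent (homozygous reference) in unaffected birds.
2. **Known-variant exclusion.** Variants already catalogued in unrelated,
   unaffected populations cannot be causative and are subtracted by exact
   (chrom, pos, ref, alt) key.
3. **Recombinant exclusion mapping.** An unaffected bird that carries
   *part* of the founder affected haplotype excludes every sub-region
   where it carries that haplotype; diagnostic marker genotypes delimit a
   narrowed critical interval.
4. **Candidate characterisation.** Surviving variants inside the narrowed
   interval are annotated against gene models, validated by
   marker–phenotype concordance in a larger genotyping survey, and their
   flanking windows scored for cross-species conservation as evidence of
   regulatory constraint.

`rumpmap` implements each stage as a plain function over tibbles, plus a
synthetic-cohort generator so the whole funnel can be exercised and
validated end to end without any sequencing download.

## The filtering model and its assumptions

For a cohort design $D = \{(s_i, c_i)\}$ assigning each sample an expected
genotype class $c_i \in \{\mathrm{HOM\_ALT}, \mathrm{HET},
\mathrm{HOM\_REF}\}$, a variant $v$ with per-sample classes $g_i(v)$ is
retained iff $g_i(v) = c_i$ for every $i$. The filter is exact — no
penetrance parameter, no error tolerance — which is appropriate when the
trait is fully penetrant, the genotype classes of the sequenced birds are
known from pedigree, and genotyping error is handled upstream by the
caller. For the 3 hom-affected / 2 het-affected / 1 unaffected design,
exactly one of the $3^6 = 729$ possible class assignments passes, so a
non-segregating variant survives by chance only through genotyping error,
never through pattern collision.

Assumptions worth stating:

* **Single founder mutation.** All affected birds share one causal allele
  identical by descent; variants private to the affected haplotype
  segregate exactly like the causal one and can only be separated by
  recombination, not by filtering.
* **Missing genotypes.** The callers' half-calls and `./.` become the
  class `MISSING`. The default `missing_policy = "fail"` disqualifies such
  a variant (conservative: no false positives from no-calls, at the price
  of losing a true candidate whose genotype was masked). `"pass"` treats
  MISSING as compatible with any expectation; both are exposed because
  the right choice depends on call-rate upstream.
* **Multiallelic records** are split per alt; classification is relative
  to the retained alt, an allele of *another* alt counting as non-reference
  (so `1/2` is HET for either alt, and `2/2` is HOM_REF for alt 1 — the
  sample does not carry that alt).

## Coordinates and interval arithmetic

All positions are 1-based as in VCF. Interval span is defined as
`end − start`, **not** `end − start + 1`: the narrowed critical interval
86,476,559–86,601,705 spans 125,146 bp, and the 55 bp deletion occupies
86,830,975–86,831,030. This endpoint-difference convention is applied
uniformly so that all reported spans are reproducible by subtraction.

## Exclusion mapping: boundary and tie conventions

Marker origin calls are made from unphased genotypes under the
single-carrier assumption (at most one affected haplotype per
individual): a genotype containing the affected diagnostic allele is
`AFFECTED_HAP`, homozygous unaffected is `UNAFFECTED_HAP`, anything else
is `UNINFORMATIVE`.

The narrowed interval is computed from maximal runs of markers at which
no excluder shows `AFFECTED_HAP`:

* A marker where **any** excluder is `AFFECTED_HAP` blocks.
* Within a run, the retained interval is **closed at the outermost
  markers where every excluder has an informative `UNAFFECTED_HAP`
  call** — the conservative inner bound. The unobserved stretch between a
  supporting marker and the adjacent blocking marker is excluded, which is
  why the interval is reported by its flanking SNP coordinates.
* `UNINFORMATIVE` calls are transparent: they neither block nor support.
* A run reaching the edge of the marker ladder extends to the original
  interval boundary, because no marker evidence exists beyond the ladder;
  in particular an excluder that is `UNAFFECTED_HAP` everywhere excludes
  nothing, and with zero excluders the original interval is returned
  unchanged.
* Requiring *all* excluders (not *any*) for a supporting endpoint keeps
  the operation anti-monotone: adding an excluder can only shrink the
  retained union.

An interior-bounded run containing no supporting marker is dropped —
there is no informative coordinate at which to close it.

## Conservation scoring

The flanking window of a candidate SNP (default 300 bp: 149 bp left,
150 bp right of the focal base, clipped at sequence ends with a warning)
is aligned against pre-extracted orthologous windows by Needleman–Wunsch
global alignment with match +1, mismatch −1 and a linear gap penalty of
−2 per column. Identity is matches over aligned columns, gaps included.
Traceback ties are broken deterministically — diagonal, then up, then
left — so identities are bit-reproducible. A window is called conserved
when every species reaches the identity threshold (default 0.70, a
tunable heuristic rather than a calibrated value: at typical
galliform–passerine neutral divergence a constrained window sits well
above it and an unconstrained one well below). The scorer takes
orthologous windows as FASTA input rather than querying genome
alignments, keeping the pipeline download-free; it is a pairwise-identity
stand-in for whatever browser-track inspection a study might otherwise
use, not a phylogenetic conservation model.

In the test suite the aligner is validated two ways: exhaustive
enumeration of all alignments for short sequence pairs, and agreement of
optimal scores with an independent implementation
(`Biostrings::pairwiseAlignment` under the same scoring scheme) up to and
beyond window-scale lengths.

## What the synthetic generator emulates

`cohort_spec()` defaults encode the study conditions: a 740 kb region
(chr2:86,110,000–86,850,000), six diploid genomes (3 homozygous affected,
2 heterozygous affected, 1 unaffected), a causal SNP at 86,594,449 on the
founder haplotype, 315 linked private variants of which 24 are indels
(including a planted 55 bp deletion at 86,830,975), 18 linked SNPs also
present in the known-variant set, and 1776 noise variants — a
2092 → 316 → 298 funnel with 274 SNPs and 24 indels surviving. A
recombinant unaffected carrier (`RB1`) with breakpoints at
(86,476,558, 86,601,706) narrows the interval to 86,476,559–86,601,705,
which contains exactly two surviving SNPs, the causal one among them.

Generator conventions:

* **Noise patterns** are drawn uniformly from the $3^k - 1$ genotype-class
  assignments that differ from the segregating pattern (by index skipping,
  not rejection), so a noise variant can never collide with the causal
  pattern and expected funnel counts are exact by construction.
* **Marker ladder.** The two inner-flank markers at `breakpoint ± 1` pin
  the narrowed interval's endpoints; one anchor marker outside each
  breakpoint (midpoint of the remaining space) guarantees the run is
  delimited; remaining markers are drawn uniformly. Each marker gets two
  distinct diagnostic alleles; cohort genotypes follow carrier state and
  `RB1` is heterozygous-affected outside its breakpoints, homozygous
  unaffected inside.
* **Placement.** Variant positions are drawn without replacement;
  surviving variants other than the planted in-interval candidates are
  placed outside the narrowed interval, and linked variants avoid the
  planted gene spans (matching a study in which no surviving variant is
  genic). Two synthetic gene models (`IRX1like`, `IRX2like`, stand-ins
  for the real cluster, not its coordinates) are placed downstream of the
  narrowed interval, scaled to the free space.
* **Ortholog windows** are produced by mutating the query window at
  per-species substitution rates, default 0.03/0.05/0.08 per bp — chosen
  once as a realistic spread of avian divergence that leaves a
  constrained window above the 0.70 threshold.
* **Determinism.** One seeded RNG stream per study with a documented
  sampling order; the same spec yields byte-identical files.

What it does **not** emulate: read-level data (no FASTQ or coverage
model; genotype error appears only through the `missing_rate` masking
knob), linkage-disequilibrium decay or mutation-rate heterogeneity,
multi-allelic sites, and recombination beyond the single recombinant's
two breakpoints. Passing funnel counts on synthetic cohorts therefore
validates the *combinatorial logic* of the pipeline — the filter, the
subtraction, the interval arithmetic — not robustness to caller error or
to incomplete penetrance, which real data would add.

## Problem sizes and runtime choices

The validation suite runs the study-sized cohort (2092 variants, 6
samples) for funnel checks, and a scaled-down cohort (a 200 kb region, 40
linked + 150 noise variants, 7 markers, 120 bp windows) for the 100-seed
parameter-recovery sweeps, where only candidate recovery and interval
coverage are scored and the conservation stage is skipped. Recovery is
100/100 by construction whenever the causal position lies between the
recombinant's breakpoints and no causal genotype is masked; the sweep
verifies that the implementation achieves its construction.

## Known limitations

* The design table can express a recessive expectation per sample, but no
  dedicated recessive or compound-heterozygous mode exists.
* No statistical phasing, LD-based fine-mapping, or multi-family linkage;
  haplotype origin is called marker-by-marker under the single-carrier
  assumption.
* Known-variant subtraction is exact-key (optionally position-only);
  fuzzy indel matching (normalisation, left-alignment) is upstream
  territory.
* The concordance check treats genotyping as error-free; a discordant
  individual is interpreted as a recombinant, which is only one of the
  possible explanations in real data.
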