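---
title: "CRISPRi guide design in GC-rich bacterial genomes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPRi guide design in GC-rich bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(crispriguides)
library(dplyr)
```

## The problem

CRISPR interference (CRISPRi) silences a gene by parking a catalytically
dead Cas9 (dCas9), loaded with a single guide RNA (sgRNA), on the DNA
near a promoter, where it blocks transcription without cleaving. For
bacteria whose genomes are GC-rich — the motivating case is an
alphaproteobacterium such as *Caulobacter crescentus* — the commonly used
*S. pyogenes* system can perform poorly, and type IIA Cas9 orthologs with
different protospacer-adjacent motifs (PAMs) are used instead:

* **Sth3** (*S. thermophilus* CRISPR3), PAM `NGGNG` — abundant in GC-rich
  sequence;
* **Spa** (*S. pasteurianus*), consensus PAM `NNGTGA` — roughly an order
  of magnitude rarer.

Designing a genome-wide guide library for such a system reduces to four
questions, each answered by one module of this package:

1. *Where can dCas9 bind at all?* Every occurrence of the degenerate PAM
   on either genomic strand, with a full-length protospacer 5′ of it
   (`scan_pams()`, `extract_protospacers()`).
2. *Which candidates are specific?* dCas9 binding requires an exact match
   only over the PAM-proximal **seed** (12 nt of the 20-nt spacer), so a
   guide whose seed recurs next to another PAM anywhere in the genome has
   a credible off-target site (`build_seed_index()`, `filter_unique()`).
3. *Which candidates will actually repress?* CRISPRi works best when the
   sgRNA base-pairs with the **nontemplate** (coding) strand close to the
   transcription start site (TSS); candidates are restricted to a window
   around each annotated TSS and classified by strand
   (`design_guides()`).
4. *What fraction of the genome is coverable?* Per-system and
   union-of-systems gene/operon targetability (`summarize_targetability()`).

Two service modules round the toolkit out: sgRNA construct assembly
(`assemble_constructs()`) and an RNA-seq quantifier
(`fragment_coverage()`, `gene_rpkm()`, `log2_fold_change()`) for
validating knockdowns from paired-end alignments.

## The design procedure

### PAM enumeration

A PAM specification (`pam_spec()`) fixes the motif (IUPAC code), spacer
length (default 20), seed length (default 12) and optionally the sgRNA
scaffold. Scanning matches the motif on both strands; every window
matching the motif is one site, overlapping occurrences included, because
each is independently a potential dCas9 binding site. Matching is
performed with `Biostrings::matchPattern()` under IUPAC semantics, with
one deliberate restriction applied on top: a genome `N` satisfies **no**
motif letter, not even motif `N`. An ambiguous genome base cannot be
claimed as a determinate PAM or spacer base, so windows containing `N`
are excluded from sites, protospacers and seeds alike.

All three systems considered are type IIA, so PAM geometry is fixed to
"immediately 3′ of the protospacer"; the protospacer is the
`protospacer_len` bases ending 5′ of the PAM *on the site's strand*, and
the seed is its PAM-proximal suffix.

Coordinates are 1-based inclusive on the forward genomic axis everywhere
inside the package and in TSV output — the native convention of the
R/Bioconductor stack this package is built on — while BED output follows
the BED standard (0-based, half-open), so `start_bed = start_tsv - 1` and
`end_bed = end_tsv` for every record.

Contigs are linear by default. Topology can be declared circular per
contig, in which case scanning and protospacer extraction wrap the
origin; whether published genome-wide motif totals counted across the
origin is generally unstated, so the toggle exists and the difference is
at most a handful of sites.

```{r}
g <- genome_set(c(chr = "TTTTTTTTTTTTTTTTTTTTAGGCGTTT"))
scan_pams(g, crispri_systems()$Sth3) |>
  extract_protospacers(g, crispri_systems()$Sth3)
```

### Seed-uniqueness off-target filter

The filter's operational rule: a guide is kept iff its seed sequence
occurs **exactly once** in the genome immediately 5′-adjacent to a PAM of
the same system, counting both strands and counting the candidate's own
locus. (The equivalent phrasing "no perfect seed match next to another
PAM elsewhere" differs only in whether the self-locus is counted; with
the self-locus included, unique ⇔ count = 1.)

Two conservative choices widen the index relative to the candidate set:

* adjacency requires only `seed_len` N-free bases 5′ of a PAM — a PAM too
  close to a contig edge for a full 20-nt protospacer still contributes
  an off-target occurrence, because seed pairing alone can recruit dCas9;
* seeds are compared within one Cas9 system only (an `NGGNG`-adjacent
  seed is irrelevant to a Spa guide), since binding requires that
  system's PAM.

### TSS windows and strand classification

Each annotated TSS anchors a window on the transcript axis, by default
−50 to +100 (150 bp): offset 0 is the TSS base, the lower bound is
inclusive and the upper bound exclusive, and the window is oriented along
transcription and clipped to the contig. A candidate belongs to the
window when its **protospacer** is fully contained; the PAM may overhang
(the searched object is the targeting sequence). A stricter
`require_pam_in_window` toggle exists for sensitivity analysis.

Strand classification follows base-pairing bookkeeping: the sgRNA spacer
carries the protospacer's sequence, hence base-pairs with the strand
opposite the protospacer. Repression requires pairing with the
nontemplate (coding) strand, so an effective candidate's protospacer lies
on the gene's *template* strand — the genomic strand opposite the
annotated gene strand. The default class filter keeps nontemplate
candidates only; `class = "all"` retains template rows, flagged.

Remaining annotations: `tss_offset` is the signed transcript-axis
position of the protospacer base nearest the TSS (a stable, convention-
documented sort key; no published convention exists for it), and
`beyond_cds_start` flags protospacers reaching at/past the start codon —
an annotation only, never a filter, because guides in short 5′ UTRs can
overlap the CDS and their efficacy there is simply untested. Genes with
several TSS records are designed independently per TSS; gene-level
aggregation happens in the targetability report.

### Targetability accounting

A gene (or operon, when operon ids are annotated) is *targetable* under a
system set iff any of its TSSs has at least one unique nontemplate
candidate from any system in the set. Denominators count units with at
least one TSS record; percentages are rounded half-up to one decimal,
matching the precision such figures are reported at. Reports carry
provenance headers (genome id, window, rules) so that convention
mismatches against other implementations are attributable.

### Construct assembly

A full sgRNA sequence is `targeting_seq + scaffold`, 5′→3′, in DNA
alphabet (the object one clones); an RNA transliteration is display-only.
Scaffolds (crRNA direct repeat + tracrRNA with the dCas9 handle and
terminator) are plasmid-specific and are **configuration inputs, not
shipped constants** — hard-coding a sequence the toolkit cannot verify
would fabricate biology. Fixtures and tests use clearly synthetic
scaffolds.

## Expression quantification

The RNA-seq quantifier consumes SAM (alignment itself is out of scope —
any aligner produces the input) and computes:

* **Fractional fragment coverage**: each proper pair deposits total mass
  1, spread as `1/N` over the `N` positions from the 5′ end of the first
  mate to the 3′ end of the second (TLEN-based); unpaired mapped reads
  deposit `1/read-length` over the read span. Unmapped, secondary and
  supplementary records are ignored; malformed spans are skipped and
  tallied. Coverage is unstranded. Mass conservation (sum of coverage =
  fragments used) is asserted in the tests to 1e-6 relative.
* **RPKM**: gene mass (coverage summed over the annotated interval, so a
  boundary-straddling fragment contributes only its in-gene positions)
  divided by gene length in kb and library size in millions of fragments.
* **log2 ratios** of experimental to control RPKM.

The pseudocount that keeps log-ratios finite is under-specified in common
usage ("added to all positions"): a literal per-position constant makes
the floor scale with gene length, which is rarely intended. The default
mode therefore adds **1 fragment-equivalent of mass per gene**, a
length-independent floor; a literal `per_position` mode and `off` are
selectable, and the mode is recorded in output headers.

## Synthetic fixtures: what they do and do not show

`make_fixture_bundle()` generates deterministic, self-consistent study
sets — genome FASTA, TSS table, planting ledger, and for the RNA-seq
profile a pair of synthetic SAM libraries. All randomness flows through a
pinned RNG (Mersenne-Twister, rejection sampling), so a `(profile, seed)`
pair regenerates byte-identical files on any platform.

One choice deserves emphasis. Random GC-rich sequence is *saturated* with
`NGGNG`: at GC 0.67 a 150-bp window contains on the order of ten
background sites, so no planted-site expectation can be exact against
such a backbone. The design-oriented profiles (`minimal`,
`coverage-demo`) therefore use an **A/T-only backbone** with A/T-only
spacers, making each planted protospacer+PAM block provably the only
motif occurrence it introduces; ledger comparisons (coordinates, strand,
class, uniqueness) are then exact, with zero tolerance. The planting
routine additionally re-rolls the spacer until the genome-wide
PAM-adjacent count of its seed equals the intended multiplicity (1, or 2
for deliberately non-unique plants), so ledger uniqueness claims hold by
construction, not by chance. The GC-rich regime is exercised where
exactness is not required: the scanner's brute-force-oracle equivalence
and GC-monotonicity tests, and the `rnaseq-demo` profile, use GC 0.67
backbones.

Consequently, passing tests demonstrate the correctness of the
*procedure* — scanning, filtering, windowing, accounting, quantification
— on genomes whose structure is fully known. They do not demonstrate
anything about real annotation quality (TSS catalogs are incomplete and
condition-dependent), about real off-target biology beyond exact seed
matching, or about guide *efficacy*, which this toolkit deliberately does
not score.

## Numerical choices and degenerate inputs

* Ties in per-TSS candidate ordering (equal `|tss_offset|`) break by
  forward-axis start, then `+` before `-`; output tables are
  deterministic for fixed inputs.
* Windows falling entirely off a contig are empty results, not errors;
  empty candidate sets serialize to valid empty files.
* Percentages round half-up (base R's `round()` is banker's rounding).
* A library with zero usable fragments makes RPKM an error, not NaN.
* A candidate seed absent from its index is an error (it signals a
  genome/spec mismatch), as is querying an index from a different system.
* Problem sizes used by the test-suite properties: 200 random genomes of
  0.2–1.5 kb for scanner/oracle equivalence, 50 planted fixtures for
  mirror invariance, 100 genomes for seed-filter exactness, and
  10-gene/100-fragment libraries for quantification — sizes at which the
  brute-force oracles are exact and fast.

## Known limitations

* No guide-efficacy or PAM-strength scoring; candidate lists are meant
  for human or downstream selection.
* Off-target detection is exact-seed-adjacency only — no
  mismatch-tolerant search.
* The Spa system's reported tolerance for non-consensus PAMs is handled
  by configuring alternative motifs, not by fuzzy matching.
* Wrapped (origin-spanning) sites on circular contigs report forward-axis
  coordinates that may exceed the contig length (interpret modulo);
  TSS windows do not wrap the origin.
* SAM consumption assumes `@SQ` headers and mate-resolved TLEN; exotic
  alignments (supplementary chimeras) are skipped, not reconstructed.
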