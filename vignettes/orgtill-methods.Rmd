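---
title: "Methods: in silico mismatch-cleavage scanning of organelle genes"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay being modelled

EcoTILLING discovers natural DNA variants by hybridising a query amplicon
against a reference amplicon and digesting the resulting heteroduplex with
the single-strand-specific endonuclease CEL I, which nicks one strand 3′ of
each mismatch with partial efficiency. When the forward primer carries an
IRD700 label and the reverse primer an IRD800 label, each cleavage produces
one labelled fragment per channel, read out on a denaturing gel. For a
mismatch at position $p$ of a product of length $L$ the two fragments obey
the additivity constraint

$$\mathrm{size}_{700} = p, \qquad \mathrm{size}_{700} + \mathrm{size}_{800} = L,$$

so the band sizes locate the mutation. Applied to chloroplast and
mitochondrial genes (effectively haploid, non-recombining), the assay
screens a 96-sample panel per gel run; sequencing a single representative
of each band pattern then yields the allele.

`orgtill` implements the full in-silico counterpart: haplotype ↔ event
conversion, virtual digestion under an explicit detection model, recovery
of positions from band sizes, the screen's summary statistics, K2P + NJ
haplotype phylogenetics, and a seeded synthetic cohort generator.

## Coordinates and event normal form

All coordinates are 1-based and closed. Gene coordinates start at the first
base of the ATG; amplicon coordinates start at the 5′ end of the
IRD700-labelled forward strand and *include* unlabelled adaptor bases (19
bp M13F / 20 bp M13R in the two-step labelling scheme), because that is the
scale on which band sizes are measured. Whether a printed band table counts
adaptor bases is amplicon metadata, not a package constant — the primer
maps needed to fix it universally are generally not published, so
`amplicon_spec()` makes offsets explicit configuration.

Differences between two haplotypes are represented in a *normal form*:
maximal runs of adjacent substituted bases form one multi-nucleotide event
(so a TT→AA change is a single position, as band tables print it); runs of
deleted or inserted bases form one event; indels are placed leftmost in
repeat context. Each event weighs `max(nchar(ref), nchar(alt))` mutated
base pairs. Equal-length pairs are compared by a direct per-position scan;
unequal-length pairs are aligned globally (unit mismatch cost, affine gaps
open 2 / extend 1 — at the ≤ few-percent divergences in scope any sensible
scheme gives the same event set) and then re-normalized. Normal form makes
`enumerate_polymorphisms()` and `apply_events()` exact inverses, which the
test suite exercises as a property.

## The detection model

The ideal profile (`ideal_detection()`) shows every mismatch. The empirical
profile (`detection_model()` defaults) encodes two failure modes that
mismatch-cleavage screens exhibit:

* **terminal noise** — sites within `terminal_window_W = 80` bp of either
  product end survive with probability `terminal_detect_prob = 0.08`
  (observed recovery: one of thirteen sites in the first 80 bp);
* **cluster suppression** — when a window of `cluster_window_w = 27` bp
  holds more than `cluster_max_detect = 2` sites, only the outermost two
  are kept (observed: fourteen sites in 27 bases yielded two bands).
  Keeping the *outermost* sites is our deterministic choice; the
  underlying biochemistry (over-digestion diluting signal) suggests no
  particular survivor, and a fixed rule keeps runs reproducible;
* **size resolution** `size_resolution_r` merges same-channel bands closer
  than r bp (default 0: the printed tables distinguish 345 from 346 bp, so
  1-bp resolution is the stated world).

The stochastic terminal rule draws from a private seeded stream that never
touches R's global RNG state; identical seeds give identical lanes.

## Band calling

`pair_bands()` inverts the gel: it finds the maximum-cardinality pairing of
700-channel with 800-channel sizes in which each pair sums to $L$ within a
tolerance (default 1 bp — pairs like 346+481 sum exactly, so the tolerance
is conservative), minimising total deviation among maximal pairings, ties
broken toward pairing the smallest 700 size first. Instances are tiny, so
the assignment is solved exactly by depth-first search and checked in the
tests against brute-force enumeration of all pairings. Bands within
tolerance of $L$ are classified as uncleaved full-length product and kept
out of the pairing; leftovers are reported, never dropped. A physical
consequence: a mismatch within ~tol bp of the product end is inherently
uncallable, its fragment being indistinguishable from full length. In the
two-step labelling scheme the adaptors keep every templated base interior,
which is why the ideal-profile round trip (synthesise → digest → call) is
exact in the acceptance suite.

For indel heteroduplexes the called position is the leftmost affected base
and the 800-channel complement uses the reference-strand length.

## Statistics and counting conventions

Two units coexist and both are exposed by `tabulate_events()`:

* **base-weighted** — every mutated base pair counts (12 carriers of a 6-bp
  deletion contribute 72). This is the unit of screened-bp arithmetic:
  `screened_bp = n_samples × gene_length`, and the mutation frequency is
  screened bp per mutated base (reported in kb, 2 decimals).
* **occurrence** — each per-sample polymorphic position counts once. This
  is the unit of detection-rate bookkeeping: `rate = A1/A2` with A1 the
  gel-detected and A2 the sequencing-confirmed occurrences; the display
  rounds to whole percent (69/108 → 64%). Detected-but-unconfirmed
  positions are excluded from A1 and reported separately as false
  positives.

## Phylogenetics

Haplotypes are reconstructed from reference-anchored event tables: constant
positions are filled from the reference sequence when available and with an
arbitrary fixed base otherwise (the choice cannot affect any pairwise
distance), substituted positions carry each sample's allele, and deletion
carriers receive gap columns — no realignment is needed. Genes are
concatenated in a fixed order with partition bookkeeping.

Distances use Kimura's two-parameter model,
$D = -\tfrac12\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$, with gap/N sites deleted
pairwise; saturation ($1-2P-Q \le 0$) is an error rather than a silent NaN.
Trees are Saitou–Nei neighbour joining with two pinned details: Q-criterion
ties break on the lexicographically smallest taxon pair (each internal node
inherits the smallest member name for this purpose), and negative branch
estimates are clamped to zero with a warning. Bootstrap supports resample
alignment columns with replacement; the support of an internal bipartition
of the full-data tree is the number of replicate NJ trees containing it
(display threshold 750/1000 by convention). Site patterns are compressed
once and replicates drawn as site-index resamples, so cohorts with many
identical haplotypes — the common case in intraspecific organelle screens —
cost little; supports are invariant under taxon relabelling because pattern
identity is canonicalised over name-sorted taxa. Collapsing identical
haplotypes is available (`collapse_haplotypes()`) but optional, since how a
published tree collapsed its identical accessions is rarely stated.

## The synthetic cohort generator

`cohort_config()` defaults describe the screen the package emulates: 96
samples, chloroplast-sized genes (1470/1575/1440 bp), substitution density
1/1220 per bp per haplotype (the densest observed gene), a 5% + 5% admixture
of 2-bp MNPs and 2–6 bp deletions, and 10% recurrence of an existing
polymorphic position with a fresh alternate allele (multi-allelic sites).
Optional haplotype clusters share identical event sets, mirroring panels
where most accessions carry one of a few haplotypes; an optional burst
plants a dense cluster (e.g. 14 sites within 27 bp) using a minimum-gap-2
combinatorial placement, since isolated substitutions at that density admit
essentially one arrangement.

Two non-obvious guarantees: events are placed with a 1-bp guard so event
identity is unambiguous, and any event set containing indels is verified to
be its own re-enumeration (redrawn otherwise) — a drawn deletion whose
content matches nearby context can otherwise trade places with a
neighbouring substitution at equal alignment cost, which would break the
truth-table round trip.

What the generator does *not* emulate: realistic base composition or codon
structure, selection, coalescent genealogy, or heteroplasmy. A green
round-trip test therefore establishes the pipeline's internal consistency
(positions in → bands → positions out) and the statistics' arithmetic, not
biological realism of the sequences.

## Numerical and degenerate-input choices

* Pairing tolerance 1 bp; full-length recognition within the same
  tolerance; both configurable.
* Band sizes are integers (1-bp gel resolution).
* `detection_rate` with zero confirmed events is an error (undefined), as
  is mutation frequency with zero mutant bases and K2P at saturation.
* All stochastic components (terminal detection, bootstrap, generator)
  take explicit seeds and use isolated RNG streams; replicate r of a
  bootstrap consumes the r-th block of draws, so results are independent
  of evaluation order.
* The fixture tables shipped under `inst/extdata/` transcribe a published
  organelle screen of Brassica and related crucifers; each file was
  validated against its printed row/column totals at transcription time,
  and the acceptance suite recomputes all headline statistics from them.

## Known limitations

Insertions are supported by the event model and generator but not by
haplotype reconstruction for phylogenetics (reference-anchored screens of
this kind observe deletions only). Alignment beyond ~20% divergence or >50
bp length difference is out of scope. The virtual gel models band
*presence*, not intensity; double-cut fragments (two nicks on one strand)
are ignored, consistent with partial digestion at the enzyme concentrations
such screens use.
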