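---
title: "From DICOM headers to pseudonymized FHIR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From DICOM headers to pseudonymized FHIR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgstudy)
```

`imgstudy` models one recurring task in imaging informatics: moving the
*metadata* of clinical DICOM studies — never the pixel content — into a
research repository as standardized, pseudonymized FHIR R4 ImagingStudy
resources, and quantifying on the way how complete that metadata actually
is. This vignette records the methods, the assumptions behind them, and the
design decisions that were genuinely open.

## The processing model

The unit of work is the *study*, identified by its accession number. A
transfer manifest (accession → expected object count) stands in for the
archive's query interface; an inbox directory with one folder per study
stands in for a DICOM receive endpoint. `process_inbox()` runs the cycle
strictly sequentially: count the parseable objects of the next manifest
entry, wait (bounded by `wait_timeout`) until the count reaches the expected
number, convert the study to one ImagingStudy resource wrapped in a
transaction bundle, pseudonymize it, append it to an NDJSON sink, and delete
the study's files before touching the next study. Sequential processing plus
unconditional cleanup keeps the endpoint's storage bounded and prevents
objects of different studies from mixing; the cost is that throughput is not
a goal of this design.

A transfer is *incomplete* when the timeout elapses with fewer objects than
expected. Real endpoints cannot signal "study fully received" — that is why
counting against an expected number is the contract here. The default
`wait_timeout` of 2 s suits the synthetic corpora, where files either exist
or never will; against a live folder it should be set to minutes. An
optional SOP-class whitelist reproduces a classic failure mode: objects of
unaccepted classes are received-but-excluded, so the count never completes
and the study is (correctly) flagged rather than silently truncated.

## Header parsing

Only a fixed set of header elements is relevant (identity UIDs, modality,
BodyPartExamined, laterality, patient/accession identifiers, numbering,
date/time), so `read_instance()` walks the Part-10 element stream directly —
Explicit and Implicit VR little endian — and stops at PixelData. Values are
trimmed; empty strings count as absent; body part and laterality are
upper-cased before any mapping or counting. Headers are treated as the DICOM
default character repertoire; non-ASCII bytes pass through untranslated.

Laterality deserves a note: tag (0020,0060) only admits `L` and `R`, while
the bilateral (`B`) and unpaired (`U`) codes are legal in Image Laterality
(0020,0062). Observed `B`/`U` values must therefore come from the image-level
tag, so the reader uses (0020,0060) and falls back to (0020,0062). The
generator mirrors this: it writes `L`/`R` to the series-level tag and `B`/`U`
to the image-level one.

## Terminology

BodyPartExamined → SNOMED CT mapping uses a versioned CSV table derived from
the published DICOM correspondence; each row carries the edition interval in
which the raw value is defined. This matters in practice: `LEG` exists up to
edition 2022d and is then replaced by `LOWERLEG`, so the same corpus maps
differently under a 2022 and a 2024 table (`body_part_table(edition=)`).
The packaged table covers the values the generator produces plus roughly
fifty common ones; full coverage of the several hundred standard values is
deliberately out of scope. Unmapped values are recorded as events on the
terminology context but still count as *present* for completeness — coding
loss and missingness are different defects.

Laterality maps to the FHIR R4 example binding (left 419161000, right
419465000, bilateral 51440002). `U` has no concept there: it is treated as a
valid, present value that emits no coding. Modalities classify as
acquisition vs non-acquisition by membership in a configurable set
(default `SR, PR, KO, SEG, DOC, AU`); unknown codes default to
*acquisition* so that completeness denominators stay conservative.

## FHIR representation

Resources follow the R4 ImagingStudy shape: the study UID as a
`urn:dicom:uid` identifier, the accession number as an ACSN-typed
identifier, the patient ID on `subject.identifier`, distinct series
modalities at study level, and per-series body site / laterality codings.
`started` is composed from StudyDate + StudyTime in local time without a
zone designator, since the zone is unknowable from the header. Each series
additionally carries two small extensions with the raw BodyPartExamined and
laterality strings: the quality analysis is defined over raw pre-mapping
values (and `U` cannot round-trip through the binding at all), so the raw
strings must survive serialization. Bundles are `transaction` bundles whose
single entry is a conditional update keyed on the study-UID identifier,
making repeated submission idempotent. `validate_resource()` enforces the
count and uniqueness invariants; the builder's output always passes, and
the validator is re-applied after pseudonymization and before analysis.

## Pseudonymization

Hierarchy UIDs are replaced by `2.25.` + the decimal rendering of the low
128 bits of SHA-256(salt ‖ uid). The `2.25` arc is the OID namespace for
UUID-derived identifiers, so the result is a legal UID of at most 44
characters; equal inputs map to equal outputs corpus-wide, which preserves
cross-references without keeping a table. The salt makes dictionary
reversal of the (guessable) original UID space impractical and is never
written to outputs or logs. SOP *Class* UIDs are retained: they are
standard, non-identifying class designators, and hashing them would destroy
the only machine-readable object-type information. Patient IDs and
accession numbers get counter-based pseudonyms (`PSN-…`, `ACC-…`) from a
CSV-persisted single-writer map — a deliberate stand-in for an institutional
trustee service. Study dates are retained unshifted; that is a privacy
caveat callers must weigh, not a claim that dates are harmless.

## The synthetic corpus

The generator exists so that every pipeline stage can be exercised — and
every reported percentage re-derived — without access to clinical data. A
`corpus_profile` pins the composition; the builtin `uhe2022` profile
emulates a one-year, two-department university-hospital workload at desk
scale: 200 studies × 10 series (2,000 series), objects-per-study mixture
100 × 80 + 100 × 150 (mean 115), modality mix CT 0.40 / MR 0.33 / DX 0.12 /
XA 0.08 / SR 0.05 / PR 0.02, and a body-region distribution in which 32% of
series carry no value. The missing mass is structural where it can be: all
SR/PR series (documents have no body region) and all XA series (angiography
systems typically leave the tag empty) are missing by construction, with
the remaining 17 points of missingness spread over CT/MR/DX series.
Laterality splits over the paired regions (knee 0.46/0.29/0.25 missing/L/R,
hand 0.88/0.03/0.09, foot, ankle, shoulder accordingly) make laterality
scarce overall (≈5% of series valid) but much denser exactly where anatomy
predicts it.

Two percentages cannot coexist with the rest: a 24% missing-body-region
rate among acquisition series is arithmetically incompatible with 32%
overall missing, 93% acquisition share and 7% non-acquisition share
(0.32 − 0.07 = 0.25 of all series ⇒ 0.25/0.93 ≈ 27% of acquisition series).
The profile keeps the mutually consistent set {32, 93, 7, region and
laterality tables} and accepts 27% for the acquisition-only rate.

In deterministic mode every categorical assignment is an exact
largest-remainder apportionment applied in study-major series order; ties on
the fractional remainder go to the earlier-listed category. This makes
realized counts exact and the corpus byte-reproducible — the right regime
for acceptance checks. Stochastic mode replaces apportionment with seeded
per-series sampling for realistic variation. Fault injection withholds
exactly one object — the last instance of the last series — from each
faulted study while the manifest keeps the full count; faulted studies are
evenly spaced deterministic indices (sampled in stochastic mode). The
`uhe2022-faults` profile uses 100 single-series studies at `fault_fraction`
0.04; 10 objects per study keeps the orchestrator exercise fast while
leaving 9 objects on disk per faulted study. One patient per study, with
deterministic identifiers, is assumed throughout.

What the generator does *not* emulate: realistic pixel data, multi-frame or
compressed objects, private tags, inter-patient study linkage, protocol
names, or the long tail of free-text body-part spellings seen in routine
data. Tests passing on this corpus therefore demonstrate the pipeline's
bookkeeping, mapping and denominators — not robustness to every artifact of
clinical data entry.

## The quality report

The unit of analysis is the series. "Present modality" means a non-empty
code; "present body region" means any non-empty raw value; "present
laterality" means a raw value in {L, R, B, U}. The body-region distribution
(including its MISSING entry) uses all series as denominator, which keeps
the distribution's percentages and the overall missing rate mutually
consistent. The paired-region laterality table reports missing/L/R
percentages per region, with B and U tallied in the underlying counts but
not displayed. All percentages are kept as exact fractions in the report
object; displayed integers are rounded half-up (`round_half_up()`), the
convention that makes e.g. 94.7% print as 95%. Every displayed number's
numerator and denominator are recoverable from the exported counts.

## Problem sizes and verification

The test suite verifies each stage against independent references: header
parsing against a `pydicom` dump of sampled files, UID hashing against a
digest computed once with an independent SHA-256 implementation, SNOMED and
laterality codes against their pinned published values, and the analysis
stage against a brute-force tally of the generator's own assignment tables
on a 20-series corpus — a path that bypasses the DICOM and FHIR layers
entirely. End-to-end checks run the full 200-study / 2,000-series / 23,000-
object corpus through every stage (about a minute of wall time) and the
100-study fault corpus through the orchestrator; smaller property checks
use 2–5-study corpora. Pseudonymization is verified to be statistics-
preserving and leak-free by exhaustive substring scans of the serialized
output against every original identifier.

## Known limitations

* Only Explicit/Implicit VR little endian Part-10 files are read; no
  sequences, encapsulated transfer syntaxes, or DICOMDIR.
* The body-part table is partial by design; unmapped values lose coding.
* Dates are not shifted, and no pixel-level de-identification exists —
  the pseudonymization scope is UIDs, patient IDs, accession numbers.
* The orchestrator is single-threaded by contract; it trades throughput
  for ordering and storage guarantees.
* The pseudonym map is a single-writer CSV; concurrent writers would race.
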