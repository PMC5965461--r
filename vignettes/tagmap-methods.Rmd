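---
title: "Declarative TagMap export of radiotherapy archives: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declarative TagMap export of radiotherapy archives: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagmapr)
```

## The problem

Helical-tomotherapy treatment records accumulate in proprietary electronic
archives: XML master files holding treatment metadata, linked by DICOM UIDs
to raw little-endian binaries (`<UID>.img/.bin/.dpe`) that carry images,
voxel doses, planned fluence and detector signals.  Restoring these data
through vendor software is slow, interactive, and silently omits
information that the archive does contain — per-fraction positional
corrections, doses recalculated on daily image-guidance scans, and the
detector ("delivery") sinograms recorded during treatment.  For trials,
audit and radiomics one wants the whole archive translated, unattended,
into linked standard DICOM-RT objects.

`tagmapr` implements this translation declaratively.  Every exported
object type is described by a *TagMap*: a human-readable XML file listing
the object's DICOM tags, each holding either a literal value or a query
into the source storage.  The engine first materializes the TagMap as a
*query-bearing DICOM skeleton* — a dataset whose element values are still
queries — then evaluates the queries in document order against a
pluggable backend and overwrites the placeholders with the retrieved,
VR-coerced values.  Raw payloads (pixels, doses, sinograms) are attached
by per-type builder hooks that apply the numeric transformations described
below.  Changing what is exported means editing a text file, not code.

## The tomo-lite dialect

Real tomotherapy archives are proprietary and undocumented, so the package
defines and fully documents its own structurally faithful dialect,
`tomo-lite` (see `docs/tomo-lite.md`), and ships a generator that emits
archives in three storage-version variants together with a ground-truth
manifest.  This is a deliberate scope decision: the engine is
schema-agnostic — every query lives in a TagMap — so any fully documented
dialect exercises the machinery (version detection, UID resolution, lazy
payload loading, staged evaluation, all four reshaping scenarios, broken
correction links) exactly as a vendor schema would.  What the synthetic
archives do *not* emulate is clinical content: images are geometric
phantoms, dose grids are smooth Gaussian-sum fields, delivery sinograms
are random positive signals.  Passing tests therefore demonstrate the
correctness of the *mapping and transformations*, not anatomical realism,
and say nothing about idiosyncrasies of any real vendor's schema.

Storage versions are modelled as `V3 < V4_0 < V4_2PLUS`, detected from a
marker in the master document by prefix (`3.*`, `4.0*`, other `4.*`).  An
unknown marker is a hard error: defaulting silently would risk decoding a
sinogram with the wrong layout.

## Evaluation semantics

Evaluation is strictly in document order, so a later query can bind a
value resolved earlier (*staged evaluation*: patient, then study, then
series, then plan).  Two dialect extensions make this explicit and
testable, because "which text is a query" and "how `?` placeholders bind"
are not decidable from the mapping text alone:

* a payload is classified as a query if it starts with `SELECT `,
  contains `/`, or starts with `$` or `(`; an explicit
  `src="literal|query"` attribute overrides the heuristic;
* every SQL query with `?` placeholders must carry a `params` attribute
  listing its sources in order, each `input:<name>` (user input) or
  `tag:GGGGEEEE` (an earlier-resolved element).

DICOM sequences are modelled by a single template item; the item count
comes from a dedicated count query, and the 1-based index variable `$i`
is substituted into the copies' queries.  A count of zero yields an empty
(but present) sequence.

Mandatory-tag handling mirrors how incomplete historic archives must
behave in batch: an empty result for a Type-1 tag (per the shipped
conformance table in `R/conformance.R`) marks the dataset `INCOMPLETE`
and records the failing tag — and any later query that *binds* a failed
tag inherits the failure rather than crashing the object; an empty result
for any other tag only logs a warning.  Under the default lenient policy
INCOMPLETE objects are still written, with their status in the QA report;
the strict policy suppresses them.

### Backends

The XPath backend evaluates against one patient's master document via
libxml2.  The supported query language is the single-document
path/predicate subset (child paths, positional and value predicates,
attribute access, `count()`); unsupported constructs fail loudly with the
offending tag.  `$name` variables are substituted textually from the
binding context before evaluation.

The SQL backend serves the treatment-record use case (oncology
information systems store records relationally).  No R SQL engine is
available to this package, so it implements exactly the narrow SELECT
dialect its treatment-record TagMap uses — single `INNER JOIN`,
`AND`-connected equality conditions, positional `?` binding — over
CSV-backed data frames, and rejects everything else.  One dialect point
is worth spelling out: a bare column reference in an `ON` clause (e.g.
`ON P.Pat_ID1 AND ...`) is read as an equi-join on the same-named column
of the two joined tables.  In the relational fixture, DICOM UIDs serve as
the foreign keys so that staged evaluation can bind earlier-resolved
elements directly.  Multi-column results concatenate per VR: two name
columns `(FIRST, LAST)` form the person name `LAST^FIRST`; other VRs
treat extra columns as DICOM multi-values.

A core engine property, enforced by test, is backend-agnosticism: the
same records served through XPath and through SQL produce identical
datasets.

## Numeric transformations

### Dose quantization

Archived dose grids are float32 voxel doses in Gy.  DICOM RT-Dose stores
integers with a scale factor, so the builder computes

$$SF = \frac{\max D}{65535}, \qquad
  D_{16} = \mathrm{round}\!\left(\frac{D}{SF}\right)$$

with rounding half away from zero, unsigned 16-bit storage (doses are
non-negative), and `DoseGridScaling = SF` written alongside the pixels.
Division (not multiplication) by SF is forced by the definition: it maps
the hottest voxel to 65535.  Round-half-away was chosen over truncation
because it halves the worst-case error: reconstruction `D16 * SF` is then
within SF/2 everywhere, i.e. at most 1/131070 = 0.00076% of the maximum
dose — comfortably inside the 0.001% envelope expected from 16-bit
conversion.  An all-zero grid uses the sentinel SF = 1.  The identical
contract covers planned doses, per-fraction adaptive (QA) doses, and — via
`RescaleSlope` — delivery sinograms.  Note that scale factors travel as
10-significant-digit decimal strings in the file, which adds a relative
~1e-9 on top of the quantization bound when reconstructing from a written
file.

### Plan sinograms

A treatment's planned fluence is a sinogram over a binary 64-leaf MLC:
for every projection (control point) and leaf, the fraction of the
projection duration the leaf is open.  The early storage generation keeps
exactly that matrix as float32.  The later generation instead records,
as float64 and only for the leaves that ever open, cumulative opening and
closing times in seconds since beam-on — two interleaved rows per open
leaf — preceded by a beam warm-up interval (10 s by default).  Layout is
detected from the blob dtype and cross-checked against the archive's
declared version; a mismatch is an error, never a guess.

Decoding the event form assigns projection `k` the half-open window
`[warmup + (k-1)·tau, warmup + k·tau)` and computes each open leaf's
fraction as its intervals' overlap with the window divided by `tau`;
leaves absent from the open-leaf list are closed throughout and emit
zeros, so the output always carries all 64 leaves.  Projection count and
`tau` come from plan metadata, never inferred from the blob.  Two
conventions are under-determined by the storage itself and fixed here:
projection windows are half-open (so an event on a boundary belongs to
exactly one projection), and event clocks *include* the warm-up.  Events
beyond the treatment end and overlapping open intervals are hard errors.

The finished per-projection fractions are serialized row-major as float32
into the private element (300D,10A7) of the RT-Plan, reserved under the
private creator `TAGMAP-TOMO`.

### Plan-CT reshaping

During planning the diagnostic scanner's couch in the CT is replaced by
the treatment couch, which may require enlarging the canvas: columns grow
to a target width (padding split equally, extra column to the right) and
couch rows are appended below, with the isocenter pixel tracked and
required to stay inside the result.  This *insertion* step happens on the
generator side — tomo-lite stores the post-insertion image (e.g.
384 x 284 from a 256 x 256 original), because that is what an archive
contains.  At export time the builder applies only the second reshaping:
padding the stored slice to a square (384 x 384), content top-aligned,
pad rows below, pad value the stored equivalent of -1024 HU.  The
inherited pixel block is bit-identical in both steps, across all four
scenarios (no change, vertical, horizontal, both) — the column-split and
pad-value policies are package conventions, configurable via
`couch_spec()`.

### Correction relinking

Each positional correction is normally linked to its image-guidance scan
by UID; when the treatment unit's database link was down, corrections
were still recorded but the link lost.  Records with an intact UID keep
it (`method = "UID"`).  Otherwise the fallback assigns the nearest scan
by acquisition time within a tolerance (120 s default — long enough for
registration-to-correction delays, short against the shortest plausible
scan spacing): `method = "TIMESTAMP"`.  Exact ties, no scan within
tolerance, and two corrections competing for one scan all demote to
`"UNLINKED"` (the timestamp mapping is kept injective), and every
fallback decision lands in the QA accounting.  Exported corrections are
embedded into their MVCT as a private block (group 7771, creator
`TAGMAP-CORR`): three translations (mm), three rotations (deg), the
timestamp, and which linking method was used.

## Identifiers and determinism

Exports must be regression-comparable, so all randomness is seeded and
UID assignment is a pure function: every non-standard UID value is
replaced by `<root>.<seed>.<h1>.<h2>`, where `h1`, `h2` are two
independent 32-bit FNV-1a digests of the source UID and seed (a small,
documented hash implemented in-package; collisions are checked and
fatal).  Because the map is value-consistent across a patient's objects,
every cross-reference — dose to plan, plan and structure set to the CT
frame of reference, QA dose to its MVCT series — keeps resolving, and the
reference-graph closure check (`uid_reference_graph()`) is run after
every assignment.  Two exports of the same archive with the same seed are
byte-identical.

DICOM files are written in Explicit VR Little Endian with defined-length
sequences — the encoding that commercial importers accept most widely —
and the reader refuses other transfer syntaxes rather than guessing.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `warmup_s` | 10 s | beam warm-up preceding projection 1 (event clocks include it) |
| `projection_duration_s` | 0.4 s | seconds per control point |
| `open_leaves` | 11–52 | MLC leaves that ever open (event rows = 2 x 42 = 84) |
| `relink_tolerance_s` | 120 s | timestamp-fallback window |
| `target_width`, `couch_height_px` | 384, 28 | couch-insertion enlargement (256 x 256 to 384 x 284) |
| `broken_link_fraction` | 0.2 | generator: corrections with the UID link removed |
| policy | lenient | write INCOMPLETE objects, recorded in the QA report |

## Problem sizes in the test suite

Unit tests run on deliberately small fixtures (48 x 48 images, 12 x 12 x 6
dose grids, 16–20 projections); the quantization bound is verified on one
hundred 32-cubed grids with maxima drawn from (0, 80] Gy; padding is
exercised at the full 256 x 256 to 384 x 384 geometry; relinking is
checked at 50 scans with +/-30 s jitter and against a brute-force oracle
on 1,000 random instances; and the batch tests run a 20-patient archive
(64 x 64 images, two fractions each) end to end, including independent
reparsing of every output file and a deliberately corrupted patient that
must not affect the other nineteen.

## Known limitations

* The dialect is tomo-lite, not any vendor's schema; adapting to real
  archives means writing TagMaps (and possibly blob-layout readers) for
  that schema, which is precisely the intended workflow.
* The SQL subset covers the treatment-record mapping only; it is not a
  general SQL engine and refuses what it cannot parse.
* XPath support is the path/predicate subset; axes, functions beyond
  `count()`, and multi-document queries are rejected.
* RT-Structure Sets carry ROI identification (numbers, names, frame of
  reference) but no contour geometry — tomo-lite does not model contours.
* The DICOM writer emits Explicit VR Little Endian only, and the reader
  reads only that; this is a deliberate narrowing, checked at parse time.
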