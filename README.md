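# tagmapr

Declarative, batch translation of tomotherapy-style patient archives into
linked, standards-compliant **DICOM-RT** objects — including the "hidden"
data conventional export omits: per-fraction image-guidance positional
corrections, adaptive-RT (QA) doses recalculated on daily MVCT scans, and
delivery (detector) sinograms.

It is aimed at radiotherapy physicists and informaticians who need to
liberate treatment records from proprietary archive formats for trials,
audit and radiomics — unattended, reproducibly, and with QA accounting
for whatever is missing.

## The idea

Each DICOM-RT object type is described by a **TagMap**: a human-readable
XML file pairing every DICOM tag with either a literal value or a query
into the source storage.  The engine

1. parses the TagMap and builds a *query-bearing DICOM skeleton*,
2. evaluates the queries in document order against a pluggable backend —
   XPath over the archive's XML master documents, or a SQL subset over
   relational fixtures — so later queries can bind earlier results
   (patient → study → series → plan), and
3. attaches raw payloads through per-type builder hooks that apply the
   numeric transformations the export needs.

The transformations are:

* **Dose quantization.**  Float32 voxel doses are packed to unsigned
  16-bit with `SF = max(D)/65535`, `D16 = round(D/SF)`, and
  `DoseGridScaling = SF`; reconstruction `D16·SF` is within `SF/2`
  everywhere, i.e. ≤ 0.001 % of the maximum dose.
* **Plan-sinogram decoding.**  Early archives store per-projection MLC
  leaf-open fractions (float32, 64 leaves); later ones store cumulative
  open/close event times (float64, two rows per open leaf, 10 s beam
  warm-up).  The layout is auto-detected, cross-checked against the
  declared storage version, decoded to the common 64-leaf fraction form,
  and embedded in the RT-Plan under private tag (300D,10A7).
* **Plan-CT reshaping.**  Couch-insertion enlargement (e.g. 256×256 →
  384×284) happens in the archive; at export the slice is padded to a
  square (384×384), inherited pixels bit-identical.
* **Correction relinking.**  Corrections keep their scan-UID link when
  intact; lost links are recovered by nearest acquisition timestamp
  within a tolerance, injectively, with ties and conflicts reported as
  UNLINKED.  Corrections ride inside the MVCT files as private tags.

Because real archives are proprietary, the package defines a documented
stand-in dialect, **tomo-lite** (`docs/tomo-lite.md`), and ships a
seeded synthetic-archive generator with a ground-truth manifest, so the
entire pipeline is testable without any clinical data.

## Worked example

```r
library(tagmapr)

# a 2-patient synthetic archive, later-generation storage
g <- generate_archive(archive_spec(n_patients = 2, n_fractions = 2,
                                   base_image_shape = c(64, 64),
                                   target_width = 96, couch_height_px = 8,
                                   dose_shape = c(16, 16, 8),
                                   n_projections = 20, n_channels = 32,
                                   seed = 42), "arch")

job <- export_job("arch", "out", seed = 7)
rep <- run_export(job)
print(rep)
#> <export_report> 2/2 patients processed (2 complete, 0 needing additional processing, 0 failed)

v <- validate_outputs("out", g$manifest)
sum(v$pass); nrow(v)
#> [1] 20
#> [1] 20
```

Every patient directory under `out/` holds one Part-10 file per object
(`<Modality>.<SOPInstanceUID>.dcm`, Explicit VR Little Endian) plus a
`manifest.json` QA report with completeness flags and relink-method
counts; `out/export_report.json` aggregates the batch (the accounting
always satisfies processed = complete + needing-additional-processing).
`validate_outputs()` reparses every file, checks that the UID reference
graph over each patient's export is closed, and cross-checks key values
against the generator's ground truth — above, all 20 checks pass.

A thin command-line front-end with `generate`, `export`, `validate` and
`inspect-tagmap` subcommands ships in `inst/cli/tagmapr-tool.R`:

```sh
Rscript inst/cli/tagmapr-tool.R generate --out arch --patients 2 --seed 5
Rscript inst/cli/tagmapr-tool.R export --archive arch --out out --seed 5
Rscript inst/cli/tagmapr-tool.R validate --out out --manifest arch/manifest.json
```

## Layout

```
R/                  archive model, TagMap engine, SQL subset, transforms,
                    DICOM builders + Part-10 I/O, synthetic generator,
                    batch export
inst/tagmaps/       shipped TagMaps: CT, MVCT, RTPLAN, RTDOSE, RTSTRUCT,
                    QADOSE, DELIVERY_SINOGRAM, treatment record (SQL + XPath)
inst/cli/           command-line front-end
docs/tomo-lite.md   the archive dialect, annotated
vignettes/          methods and design notes
```
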