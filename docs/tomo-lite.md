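# The tomo-lite archive dialect

`tomo-lite` is the documented, self-contained patient-archive dialect this
package reads and its generator writes.  It mirrors the *structure* of
helical-tomotherapy electronic archives — XML master files carrying
treatment metadata, linked by DICOM UIDs to flat raw binaries — without
reproducing any proprietary schema.  Because the export engine is
schema-agnostic (every query lives in a TagMap, not in code), any fully
documented dialect exercises it faithfully.

## Layout

```
<archive root>/
  TL0001/
    patient.xml          master document for one patient
    <UID>.img            image payloads        (uint16 / int16)
    <UID>.bin            dose grids and plan sinograms (float32 / float64)
    <UID>.dpe            delivery (detector) sinograms  (float32)
    ...
  TL0002/
    ...
  manifest.json          generator ground truth (synthetic archives only)
```

All binaries are raw and headerless, little-endian, serialized
column-major over `(rows, columns, slices)`; the referencing XML fragment
declares dtype and shape, and
`file size = element-size(dtype) x rows x cols x slices` must hold
exactly.

## Master document

```xml
<fullPatient formatVersion="4.2.1">        <!-- "3.*" | "4.0*" | other "4.*" -->
  <briefPatient>
    <patientID>TL0001</patientID>
    <patientName>SMITH^ANN</patientName>   <!-- DICOM PN component order -->
    <patientBirthDate>1951-07-20</patientBirthDate>
    <patientSex>F</patientSex>
  </briefPatient>

  <fullImageDataArray>
    <fullImageData>                         <!-- one per stored slice -->
      <dbInfo><databaseUID>1.2.826...17</databaseUID></dbInfo>
      <imageType>KVCT</imageType>           <!-- KVCT (plan CT) | MVCT -->
      <acquisitionDateTime>2011-03-02T09:15:00</acquisitionDateTime>
      <studyUID>...</studyUID>
      <seriesUID>...</seriesUID>
      <frameOfReferenceUID>...</frameOfReferenceUID>
      <fractionNumber>0</fractionNumber>    <!-- 0 = plan CT, n = fraction -->
      <arrayHeader dtype="uint16" dimX="384" dimY="284" dimZ="1" kind="img"/>
      <pixelSpacing>0.754 0.754</pixelSpacing>
      <sliceThickness>2.5</sliceThickness>
      <rescaleIntercept>-1024</rescaleIntercept>
      <isocenterRow>128</isocenterRow>
      <isocenterCol>128</isocenterCol>
    </fullImageData>
  </fullImageDataArray>

  <fullDoseDataArray>
    <fullDoseData>
      <dbInfo><databaseUID>...</databaseUID></dbInfo>
      <doseType>PLAN</doseType>             <!-- PLAN | QA (adaptive) -->
      <referencedPlanUID>...</referencedPlanUID>
      <referencedSeriesUID>...</referencedSeriesUID>  <!-- QA: the MVCT series -->
      <fractionNumber>0</fractionNumber>
      <arrayHeader dtype="float32" dimX="32" dimY="32" dimZ="16" kind="bin"/>
      <gridSpacing>2.5 2.5 2.5</gridSpacing>
      <gridOrigin>-40 -40 -20</gridOrigin>
    </fullDoseData>
  </fullDoseDataArray>

  <fullPlanDataArray>
    <fullPlanData>
      <dbInfo><databaseUID>...</databaseUID></dbInfo>
      <planLabel>HELICAL_1</planLabel>
      <planDateTime>2011-03-01T09:00:00</planDateTime>
      <frameOfReferenceUID>...</frameOfReferenceUID>
      <referencedSeriesUID>...</referencedSeriesUID>
      <planSinogram>
        <dbInfo><databaseUID>...</databaseUID></dbInfo>
        <!-- storage version 3.*: per-projection open fractions,
             float32, dimX=64 leaves, dimY=projections -->
        <!-- storage version 4.*: cumulative open/close event times (s),
             float64, dimY = 2 x number of open leaves, NaN-padded -->
        <arrayHeader dtype="float64" dimX="50" dimY="84" dimZ="1" kind="bin"/>
        <nProjections>50</nProjections>
        <projectionDuration>0.4</projectionDuration>
        <warmupDuration>10</warmupDuration>
        <openLeafIndices>11 12 ... 52</openLeafIndices>  <!-- v4 only -->
      </planSinogram>
      <deliverySinogramArray>
        <deliverySinogram>                  <!-- one per fraction -->
          <dbInfo><databaseUID>...</databaseUID></dbInfo>
          <fractionNumber>1</fractionNumber>
          <arrayHeader dtype="float32" dimX="50" dimY="640" dimZ="1" kind="dpe"/>
        </deliverySinogram>
      </deliverySinogramArray>
      <structureSet>
        <dbInfo><databaseUID>...</databaseUID></dbInfo>
        <roi number="1" name="BODY"/>
        <roi number="2" name="PTV"/>
      </structureSet>
    </fullPlanData>
  </fullPlanDataArray>

  <fullCorrelationDataArray>
    <fullCorrelationData>                   <!-- one per guided fraction -->
      <dbInfo><databaseUID>...</databaseUID></dbInfo>
      <linkedScanUID>...</linkedScanUID>    <!-- absent when the link was lost -->
      <timestamp>2011-03-02T09:16:40</timestamp>
      <lateral>1.2</lateral>                <!-- mm -->
      <longitudinal>-3.4</longitudinal>
      <vertical>0</vertical>
      <roll>0.3</roll>                      <!-- degrees -->
      <pitch>-0.1</pitch>
      <yaw>1.1</yaw>
    </fullCorrelationData>
  </fullCorrelationDataArray>
</fullPatient>
```

## Conventions

- **Version marker.** `fullPatient/@formatVersion`, mapped by prefix:
  `3.*` -> V3, `4.0*` -> V4_0, any other `4.*` -> V4_2PLUS.  An
  unrecognized marker is a hard error.
- **UID linking.** Every binary payload and every cross-fragment
  reference uses a `databaseUID`; a correction's `linkedScanUID` names
  the `fullImageData` of its image-guidance scan.
- **Timestamps** are ISO-8601 with seconds precision, UTC; they convert
  to DICOM DA/TM/DT at export time.
- **Plan sinogram, v3 vs v4.**  v3 stores the finished per-projection
  leaf-open-time fractions (all 64 leaves).  v4 stores, for the leaves
  that ever open, cumulative opening/closing times in seconds since
  beam-on *including* the leading warm-up; rows alternate open/close per
  leaf.  Leaves closed for the whole treatment are not recorded.
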