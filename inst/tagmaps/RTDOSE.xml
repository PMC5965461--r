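<dicom target="RTDOSE" backend="XPATH" versions="V3 V4_0 V4_2PLUS">
  <!-- Planned dose grid (doseType PLAN) -->
  <attr tag="00080018" vr="UI">/fullPatient/fullDoseDataArray/fullDoseData[doseType='PLAN'][1]/dbInfo/databaseUID</attr>
  <attr tag="00100010" vr="PN">/fullPatient/briefPatient/patientName</attr>
  <attr tag="00100020" vr="LO">/fullPatient/briefPatient/patientID</attr>
  <attr tag="0020000D" vr="UI">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/studyUID</attr>
  <attr tag="00280030" vr="DS">/fullPatient/fullDoseDataArray/fullDoseData[doseType='PLAN'][1]/gridSpacing</attr>
  <attr tag="300C0002" vr="SQ">
    <item>
      <attr tag="00081150" vr="UI" src="literal">1.2.840.10008.5.1.4.1.1.481.5</attr>
      <attr tag="00081155" vr="UI">/fullPatient/fullDoseDataArray/fullDoseData[doseType='PLAN'][1]/referencedPlanUID</attr>
    </item>
  </attr>
  <attr tag="7FE00010" vr="OW">/fullPatient/fullDoseDataArray/fullDoseData[doseType='PLAN'][1]/dbInfo/databaseUID</attr>
</dicom>
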