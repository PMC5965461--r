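<dicom target="RTSTRUCT" backend="XPATH" versions="V3 V4_0 V4_2PLUS">
  <attr tag="00080018" vr="UI">/fullPatient/fullPlanDataArray/fullPlanData[1]/structureSet/dbInfo/databaseUID</attr>
  <attr tag="00100010" vr="PN">/fullPatient/briefPatient/patientName</attr>
  <attr tag="00100020" vr="LO">/fullPatient/briefPatient/patientID</attr>
  <attr tag="0020000D" vr="UI">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/studyUID</attr>
  <attr tag="0020000E" vr="UI">/fullPatient/fullPlanDataArray/fullPlanData[1]/structureSet/dbInfo/databaseUID</attr>
  <attr tag="30060002" vr="SH" src="literal">TOMO_STRUCT</attr>
  <!-- one template item expanded to the archive's ROI count via $i -->
  <attr tag="30060020" vr="SQ" count="count(/fullPatient/fullPlanDataArray/fullPlanData/structureSet/roi)">
    <item>
      <attr tag="30060022" vr="IS">/fullPatient/fullPlanDataArray/fullPlanData/structureSet/roi[$i]/@number</attr>
      <attr tag="30060024" vr="UI">/fullPatient/fullPlanDataArray/fullPlanData[1]/frameOfReferenceUID</attr>
      <attr tag="30060026" vr="LO">/fullPatient/fullPlanDataArray/fullPlanData/structureSet/roi[$i]/@name</attr>
    </item>
  </attr>
</dicom>
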