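<dicom target="RTPLAN" backend="XPATH" versions="V3 V4_0 V4_2PLUS">
  <attr tag="00080018" vr="UI">/fullPatient/fullPlanDataArray/fullPlanData[1]/dbInfo/databaseUID</attr>
  <attr tag="00100010" vr="PN">/fullPatient/briefPatient/patientName</attr>
  <attr tag="00100020" vr="LO">/fullPatient/briefPatient/patientID</attr>
  <attr tag="0020000D" vr="UI">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/studyUID</attr>
  <attr tag="00200052" vr="UI">/fullPatient/fullPlanDataArray/fullPlanData[1]/frameOfReferenceUID</attr>
  <attr tag="300A0002" vr="SH">/fullPatient/fullPlanDataArray/fullPlanData[1]/planLabel</attr>
  <attr tag="300A0006" vr="DA">/fullPatient/fullPlanDataArray/fullPlanData[1]/planDateTime</attr>
  <attr tag="300A0007" vr="TM">/fullPatient/fullPlanDataArray/fullPlanData[1]/planDateTime</attr>
</dicom>
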