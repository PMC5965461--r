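<dicom target="CT" backend="XPATH" versions="V3 V4_0 V4_2PLUS">
  <!-- Planning (kilovoltage) CT, one stored slice per object -->
  <attr tag="00080018" vr="UI">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/dbInfo/databaseUID</attr>
  <attr tag="00080020" vr="DA">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/acquisitionDateTime</attr>
  <attr tag="00080030" vr="TM">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/acquisitionDateTime</attr>
  <attr tag="00080060" vr="CS" src="literal">CT</attr>
  <attr tag="0008103E" vr="LO" src="literal">Planning CT</attr>
  <attr tag="00100010" vr="PN">/fullPatient/briefPatient/patientName</attr>
  <attr tag="00100020" vr="LO">/fullPatient/briefPatient/patientID</attr>
  <attr tag="00100030" vr="DA">/fullPatient/briefPatient/patientBirthDate</attr>
  <attr tag="00100040" vr="CS">/fullPatient/briefPatient/patientSex</attr>
  <attr tag="00180050" vr="DS">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/sliceThickness</attr>
  <attr tag="0020000D" vr="UI">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/studyUID</attr>
  <attr tag="0020000E" vr="UI">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/seriesUID</attr>
  <attr tag="00200052" vr="UI">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/frameOfReferenceUID</attr>
  <attr tag="00280030" vr="DS">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/pixelSpacing</attr>
  <attr tag="00281052" vr="DS">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/rescaleIntercept</attr>
  <attr tag="7FE00010" vr="OW">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/dbInfo/databaseUID</attr>
</dicom>
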