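<dicom target="MVCT" backend="XPATH" versions="V3 V4_0 V4_2PLUS">
  <!-- Image-guidance megavoltage CT; the scan is selected by $scanUID -->
  <attr tag="00080018" vr="UI">/fullPatient/fullImageDataArray/fullImageData[dbInfo/databaseUID='$scanUID']/dbInfo/databaseUID</attr>
  <attr tag="00080020" vr="DA">/fullPatient/fullImageDataArray/fullImageData[dbInfo/databaseUID='$scanUID']/acquisitionDateTime</attr>
  <attr tag="00080030" vr="TM">/fullPatient/fullImageDataArray/fullImageData[dbInfo/databaseUID='$scanUID']/acquisitionDateTime</attr>
  <attr tag="00080060" vr="CS" src="literal">CT</attr>
  <attr tag="0008103E" vr="LO" src="literal">MVCT</attr>
  <attr tag="00100010" vr="PN">/fullPatient/briefPatient/patientName</attr>
  <attr tag="00100020" vr="LO">/fullPatient/briefPatient/patientID</attr>
  <attr tag="00200011" vr="IS">/fullPatient/fullImageDataArray/fullImageData[dbInfo/databaseUID='$scanUID']/fractionNumber</attr>
  <attr tag="0020000D" vr="UI">/fullPatient/fullImageDataArray/fullImageData[dbInfo/databaseUID='$scanUID']/studyUID</attr>
  <attr tag="0020000E" vr="UI">/fullPatient/fullImageDataArray/fullImageData[dbInfo/databaseUID='$scanUID']/seriesUID</attr>
  <attr tag="00200052" vr="UI">/fullPatient/fullImageDataArray/fullImageData[dbInfo/databaseUID='$scanUID']/frameOfReferenceUID</attr>
  <attr tag="00280030" vr="DS">/fullPatient/fullImageDataArray/fullImageData[dbInfo/databaseUID='$scanUID']/pixelSpacing</attr>
  <attr tag="00281052" vr="DS">/fullPatient/fullImageDataArray/fullImageData[dbInfo/databaseUID='$scanUID']/rescaleIntercept</attr>
  <attr tag="7FE00010" vr="OW">/fullPatient/fullImageDataArray/fullImageData[dbInfo/databaseUID='$scanUID']/dbInfo/databaseUID</attr>
</dicom>
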