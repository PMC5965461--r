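<dicom target="DELIVERY_SINOGRAM" backend="XPATH" versions="V3 V4_0 V4_2PLUS">
  <!-- Detector signal recorded during delivery of fraction $fraction:
       rows = detector channels, columns = projections -->
  <attr tag="00080018" vr="UI">/fullPatient/fullPlanDataArray/fullPlanData/deliverySinogramArray/deliverySinogram[fractionNumber='$fraction']/dbInfo/databaseUID</attr>
  <attr tag="00080060" vr="CS" src="literal">RTIMAGE</attr>
  <attr tag="0008103E" vr="LO" src="literal">Delivery sinogram</attr>
  <attr tag="00100010" vr="PN">/fullPatient/briefPatient/patientName</attr>
  <attr tag="00100020" vr="LO">/fullPatient/briefPatient/patientID</attr>
  <attr tag="00200011" vr="IS">/fullPatient/fullPlanDataArray/fullPlanData/deliverySinogramArray/deliverySinogram[fractionNumber='$fraction']/fractionNumber</attr>
  <attr tag="0020000D" vr="UI">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/studyUID</attr>
  <attr tag="7FE00010" vr="OW">/fullPatient/fullPlanDataArray/fullPlanData/deliverySinogramArray/deliverySinogram[fractionNumber='$fraction']/dbInfo/databaseUID</attr>
</dicom>
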