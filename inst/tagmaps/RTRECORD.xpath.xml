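<dicom target="RTRECORD" backend="XPATH" versions="V3 V4_0 V4_2PLUS">
  <!-- Same treatment-record mapping served from the archive master XML;
       used to demonstrate backend-agnosticism of the engine -->
  <attr tag="00100010" vr="PN">/fullPatient/briefPatient/patientName</attr>
  <attr tag="0020000D" vr="UI">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/studyUID</attr>
  <attr tag="0020000E" vr="UI">/fullPatient/fullImageDataArray/fullImageData[imageType='KVCT'][1]/seriesUID</attr>
  <attr tag="300C0002" vr="SQ">
    <item>
      <attr tag="00081150" vr="UI" src="literal">1.2.840.10008.5.1.4.1.1.481.5</attr>
      <attr tag="00081155" vr="UI">/fullPatient/fullPlanDataArray/fullPlanData[1]/dbInfo/databaseUID</attr>
    </item>
  </attr>
</dicom>
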