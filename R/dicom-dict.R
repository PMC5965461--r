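# Minimal DICOM data dictionary: VR lookup for the tags the shipped TagMaps
# and builders use.  TagMap entries may omit `vr`; it is then inferred here.

.dcm_dict <- c(
  "00080008" = "CS",  # ImageType
  "00080012" = "DA",  # InstanceCreationDate
  "00080013" = "TM",  # InstanceCreationTime
  "00080016" = "UI",  # SOPClassUID
  "00080018" = "UI",  # SOPInstanceUID
  "00080020" = "DA",  # StudyDate
  "00080021" = "DA",  # SeriesDate
  "00080030" = "TM",  # StudyTime
  "00080031" = "TM",  # SeriesTime
  "00080060" = "CS",  # Modality
  "00080070" = "LO",  # Manufacturer
  "0008103E" = "LO",  # SeriesDescription
  "00081140" = "SQ",  # ReferencedImageSequence
  "00081150" = "UI",  # ReferencedSOPClassUID
  "00081155" = "UI",  # ReferencedSOPInstanceUID
  "00100010" = "PN",  # PatientName
  "00100020" = "LO",  # PatientID
  "00100030" = "DA",  # PatientBirthDate
  "00100040" = "CS",  # PatientSex
  "00180050" = "DS",  # SliceThickness
  "0020000D" = "UI",  # StudyInstanceUID
  "0020000E" = "UI",  # SeriesInstanceUID
  "00200011" = "IS",  # SeriesNumber
  "00200013" = "IS",  # InstanceNumber
  "00200032" = "DS",  # ImagePositionPatient
  "00200037" = "DS",  # ImageOrientationPatient
  "00200052" = "UI",  # FrameOfReferenceUID
  "00280002" = "US",  # SamplesPerPixel
  "00280004" = "CS",  # PhotometricInterpretation
  "00280008" = "IS",  # NumberOfFrames
  "00280010" = "US",  # Rows
  "00280011" = "US",  # Columns
  "00280030" = "DS",  # PixelSpacing
  "00280100" = "US",  # BitsAllocated
  "00280101" = "US",  # BitsStored
  "00280102" = "US",  # HighBit
  "00280103" = "US",  # PixelRepresentation
  "00281052" = "DS",  # RescaleIntercept
  "00281053" = "DS",  # RescaleSlope
  "30040002" = "CS",  # DoseUnits
  "30040004" = "CS",  # DoseType
  "3004000A" = "CS",  # DoseSummationType
  "3004000C" = "DS",  # GridFrameOffsetVector
  "3004000E" = "DS",  # DoseGridScaling
  "300A0002" = "SH",  # RTPlanLabel
  "300A0006" = "DA",  # RTPlanDate
  "300A0007" = "TM",  # RTPlanTime
  "300C0002" = "SQ",  # ReferencedRTPlanSequence
  "300C0060" = "SQ",  # ReferencedStructureSetSequence
  "30060002" = "SH",  # StructureSetLabel
  "30060020" = "SQ",  # StructureSetROISequence
  "30060022" = "IS",  # ROINumber
  "30060024" = "UI",  # ReferencedFrameOfReferenceUID
  "30060026" = "LO",  # ROIName
  "7FE00010" = "OW"   # PixelData
)

dcm_vr_for_tag <- function(tag) {
  vr <- .dcm_dict[[toupper(tag)]]
  if (is.null(vr)) NA_character_ else vr
}

# SOP Class UIDs per object variant
.sop_class <- c(
  CT               = "1.2.840.10008.5.1.4.1.1.2",    # CT Image Storage
  MVCT             = "1.2.840.10008.5.1.4.1.1.2",    # CT Image Storage
  RTPLAN           = "1.2.840.10008.5.1.4.1.1.481.5",
  RTDOSE           = "1.2.840.10008.5.1.4.1.1.481.2",
  RTSTRUCT         = "1.2.840.10008.5.1.4.1.1.481.3",
  QADOSE           = "1.2.840.10008.5.1.4.1.1.481.2", # RT Dose + private label
  DELIVERY_SINOGRAM = "1.2.840.10008.5.1.4.1.1.481.1", # RT Image Storage
  RTRECORD         = "1.2.840.10008.5.1.4.1.1.481.4"
)

sop_class_for_variant <- function(variant) {
  uid <- .sop_class[[variant]]
  if (is.null(uid)) stop("unknown object variant: ", variant)
  uid
}

.modality_for_variant <- c(
  CT = "CT", MVCT = "CT", RTPLAN = "RTPLAN", RTDOSE = "RTDOSE",
  RTSTRUCT = "RTSTRUCT", QADOSE = "RTDOSE", DELIVERY_SINOGRAM = "RTIMAGE",
  RTRECORD = "RTRECORD"
)
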