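# Minimal DICOM data dictionary: the tags the RT Plan / Structure Set /
# Dose pipeline reads and writes. Implicit-VR files resolve VRs here.

dicom_dict <- local({
  d <- rbind(
    c("00020001", "OB", "FileMetaInformationVersion"),
    c("00020002", "UI", "MediaStorageSOPClassUID"),
    c("00020003", "UI", "MediaStorageSOPInstanceUID"),
    c("00020010", "UI", "TransferSyntaxUID"),
    c("00020012", "UI", "ImplementationClassUID"),
    c("00080005", "CS", "SpecificCharacterSet"),
    c("00080012", "DA", "InstanceCreationDate"),
    c("00080013", "TM", "InstanceCreationTime"),
    c("00080016", "UI", "SOPClassUID"),
    c("00080018", "UI", "SOPInstanceUID"),
    c("00080020", "DA", "StudyDate"),
    c("00080030", "TM", "StudyTime"),
    c("00080060", "CS", "Modality"),
    c("00080070", "LO", "Manufacturer"),
    c("00080090", "PN", "ReferringPhysicianName"),
    c("00081030", "LO", "StudyDescription"),
    c("00081090", "LO", "ManufacturerModelName"),
    c("00081150", "UI", "ReferencedSOPClassUID"),
    c("00081155", "UI", "ReferencedSOPInstanceUID"),
    c("00100010", "PN", "PatientName"),
    c("00100020", "LO", "PatientID"),
    c("00100030", "DA", "PatientBirthDate"),
    c("00100040", "CS", "PatientSex"),
    c("00181020", "LO", "SoftwareVersions"),
    c("00185100", "CS", "PatientPosition"),
    c("0020000D", "UI", "StudyInstanceUID"),
    c("0020000E", "UI", "SeriesInstanceUID"),
    c("00200010", "SH", "StudyID"),
    c("00200011", "IS", "SeriesNumber"),
    c("00200032", "DS", "ImagePositionPatient"),
    c("00200037", "DS", "ImageOrientationPatient"),
    c("00200052", "UI", "FrameOfReferenceUID"),
    c("00280002", "US", "SamplesPerPixel"),
    c("00280004", "CS", "PhotometricInterpretation"),
    c("00280008", "IS", "NumberOfFrames"),
    c("00280010", "US", "Rows"),
    c("00280011", "US", "Columns"),
    c("00280030", "DS", "PixelSpacing"),
    c("00280100", "US", "BitsAllocated"),
    c("00280101", "US", "BitsStored"),
    c("00280102", "US", "HighBit"),
    c("00280103", "US", "PixelRepresentation"),
    c("30040002", "CS", "DoseUnits"),
    c("30040004", "CS", "DoseType"),
    c("3004000A", "CS", "DoseSummationType"),
    c("3004000C", "DS", "GridFrameOffsetVector"),
    c("3004000E", "DS", "DoseGridScaling"),
    c("30040014", "CS", "TissueHeterogeneityCorrection"),
    c("30060002", "SH", "StructureSetLabel"),
    c("30060008", "DA", "StructureSetDate"),
    c("30060009", "TM", "StructureSetTime"),
    c("30060020", "SQ", "StructureSetROISequence"),
    c("30060022", "IS", "ROINumber"),
    c("30060026", "LO", "ROIName"),
    c("30060039", "SQ", "ROIContourSequence"),
    c("30060040", "SQ", "ContourSequence"),
    c("30060042", "CS", "ContourGeometricType"),
    c("30060046", "IS", "NumberOfContourPoints"),
    c("30060050", "DS", "ContourData"),
    c("30060080", "SQ", "RTROIObservationsSequence"),
    c("30060082", "IS", "ObservationNumber"),
    c("30060084", "IS", "ReferencedROINumber"),
    c("300600A4", "CS", "RTROIInterpretedType"),
    c("300A0002", "SH", "RTPlanLabel"),
    c("300A0003", "LO", "RTPlanName"),
    c("300A0006", "DA", "RTPlanDate"),
    c("300A0007", "TM", "RTPlanTime"),
    c("300A000C", "CS", "RTPlanGeometry"),
    c("300A0010", "SQ", "DoseReferenceSequence"),
    c("300A0014", "CS", "DoseReferenceStructureType"),
    c("300A0016", "LO", "DoseReferenceDescription"),
    c("300A0020", "CS", "DoseReferenceType"),
    c("300A0026", "DS", "TargetPrescriptionDose"),
    c("300A0070", "SQ", "FractionGroupSequence"),
    c("300A0071", "IS", "FractionGroupNumber"),
    c("300A0078", "IS", "NumberOfFractionsPlanned"),
    c("300A0080", "IS", "NumberOfBeams"),
    c("300A00A0", "IS", "NumberOfBrachyApplicationSetups"),
    c("300A00B0", "SQ", "BeamSequence"),
    c("300A00B2", "SH", "TreatmentMachineName"),
    c("300A00C0", "IS", "BeamNumber"),
    c("300A00C2", "LO", "BeamName"),
    c("300A00C4", "CS", "BeamType"),
    c("300A00C6", "CS", "RadiationType"),
    c("300A010E", "DS", "FinalCumulativeMetersetWeight"),
    c("300A0110", "IS", "NumberOfControlPoints"),
    c("300A0111", "SQ", "ControlPointSequence"),
    c("300A0112", "IS", "ControlPointIndex"),
    c("300A0114", "DS", "NominalBeamEnergy"),
    c("300A011E", "DS", "GantryAngle"),
    c("300A011F", "CS", "GantryRotationDirection"),
    c("300A0120", "DS", "BeamLimitingDeviceAngle"),
    c("300A0122", "DS", "PatientSupportAngle"),
    c("300A012C", "DS", "IsocenterPosition"),
    c("300A0130", "DS", "SourceToSurfaceDistance"),
    c("300A0134", "DS", "CumulativeMetersetWeight"),
    c("300A0180", "SQ", "PatientSetupSequence"),
    c("300A0182", "IS", "PatientSetupNumber"),
    c("300A0202", "CS", "BrachyTreatmentType"),
    c("300A0230", "SQ", "ApplicationSetupSequence"),
    c("300A0234", "IS", "ApplicationSetupNumber"),
    c("300A0280", "SQ", "ChannelSequence"),
    c("300A0282", "IS", "ChannelNumber"),
    c("300A0286", "DS", "ChannelTotalTime"),
    c("300A0308", "CS", "ScanMode"),
    c("300A0392", "IS", "NumberOfScanSpotPositions"),
    c("300C0002", "SQ", "ReferencedRTPlanSequence"),
    c("300C0004", "SQ", "ReferencedBeamSequence"),
    c("300C0006", "IS", "ReferencedBeamNumber"),
    c("300C0060", "SQ", "ReferencedStructureSetSequence"),
    c("300A0084", "DS", "BeamDose"),
    c("300A0086", "DS", "BeamMeterset"),
    c("7FE00010", "OW", "PixelData"))
  data.frame(tag = d[, 1], vr = d[, 2], name = d[, 3],
             stringsAsFactors = FALSE)
})

# SOP class UIDs of the three RT objects and the standard transfer syntaxes.
SOP_RTPLAN   <- "1.2.840.10008.5.1.4.1.1.481.5"
SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
SOP_RTDOSE   <- "1.2.840.10008.5.1.4.1.1.481.2"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dict_by_tag <- function(tag) {
  i <- match(tag, dicom_dict$tag)
  if (is.na(i)) NULL else dicom_dict[i, ]
}

tag_of <- function(name) {
  i <- match(name, dicom_dict$name)
  if (is.na(i)) stop("unknown DICOM attribute: ", name)
  dicom_dict$tag[i]
}
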