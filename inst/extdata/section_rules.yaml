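# Section extraction rules per note type.
# targets: canonical section name -> header pattern(s) (literal strings,
#   matched case-insensitively at line starts, optional trailing colon).
# boundaries: additional headers that terminate a section body without
#   starting a target section.
discharge_summary:
  targets:
    Social History: ["Social History"]
  boundaries: ["Admission Date", "Discharge Date", "Chief Complaint",
               "History of Present Illness", "Past Medical History",
               "Medications", "Discharge Medications", "Allergies",
               "Family History", "Physical Exam", "Hospital Course",
               "Brief Hospital Course", "Discharge Disposition",
               "Discharge Diagnosis"]
social_work:
  targets:
    Patient/Family Assessment: ["Patient/Family Assessment"]
    Past Addictions History: ["Past Addictions History"]
    Past Medical History: ["Past Medical History"]
  boundaries: ["Plan", "Disposition", "Follow Up", "Narrative"]
rehab_services:
  targets:
    Sexual and Social History: ["Sexual and Social History"]
  boundaries: ["Treatment", "Goals", "Plan", "Activity",
               "Past Medical History"]
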