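form:
  id: cabg_ward
  meta:
    title: Ward admission checklist
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: admission_checks
      description: Safe admission to the cardiac ward
      algorithms: [elderly_care, diabetic_care]
      items:
        - {id: id_band_item, text: Identity wristband applied and verified}
        - {id: bloods_item, text: Blood samples for cross-typing taken}
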