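form:
  id: cabg_physio
  meta:
    title: Mobilization checklist
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: mobilization_safety
      description: Safe early mobilization
      items:
        - {id: hemodynamics_item, text: Hemodynamically stable before mobilization}
        - {id: sternal_item, text: Sternal precautions explained to the patient}
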