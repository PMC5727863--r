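form:
  id: cabg_anesthesia
  meta:
    title: Anesthesia induction checklist
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: induction_safety
      description: Safe induction of anesthesia
      items:
        - {id: airway_item, text: Airway assessment documented}
        - {id: drugs_item, text: Emergency drugs drawn up and labelled}
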