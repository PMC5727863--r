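form:
  id: cabg_icu
  meta:
    title: ICU admission checklist
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: icu_handover
      description: Structured ICU handover
      items:
        - {id: handover_item, text: Surgical and anesthetic handover completed}
        - {id: lines_item, text: Lines and drains labelled and patent}
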