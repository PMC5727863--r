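form:
  id: pci_preop
  meta:
    title: PCI pre-operative checklist
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: cardiac_function
      description: Left ventricular function
      algorithms: [lvef_alert]
      items:
        - {id: consent_item, text: Informed consent signed and in chart}
        - id: lvef_doc_item
          text: "Document the most recent LVEF measurement ({lvef})"
          supplementary:
            - {kind: patient_data, payload: lvef}
    - id: renal_function
      description: Renal function and contrast risk
      algorithms: [renal_flag]
      items:
        - {id: creatinine_item, text: "Verify latest creatinine result ({creatinine})"}
        - {id: hydration_item, text: Pre-procedural hydration protocol ordered}
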