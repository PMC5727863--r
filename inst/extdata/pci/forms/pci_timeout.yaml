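form:
  id: pci_timeout
  meta:
    title: PCI procedural time-out
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: procedure_safety
      description: Final safety verification before first puncture
      items:
        - {id: identity_item, text: Patient identity and planned procedure confirmed}
        - {id: allergy_item, text: Contrast allergy status reviewed}
        - {id: access_item, text: Vascular access site marked, guidance: true}
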