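form:
  id: cabg_cardiology
  meta:
    title: Cardiological assessment checklist
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: cardiac_risk
      description: Pre-operative cardiac risk assessment
      items:
        - {id: echo_item, text: Recent echocardiography reviewed}
        - {id: angio_item, text: Coronary angiogram available in theatre}
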