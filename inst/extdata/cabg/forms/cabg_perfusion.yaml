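form:
  id: cabg_perfusion
  meta:
    title: Perfusion checklist
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: bypass_safety
      description: Safe initiation of cardiopulmonary bypass
      items:
        - {id: anticoag_item, text: Anticoagulation confirmed before cannulation}
        - {id: gas_item, text: Gas supply and oxygenator checked}
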