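form:
  id: cabg_or
  meta:
    title: Operating-room preparation checklist
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: or_readiness
      description: Operating-room readiness
      items:
        - {id: perfusion_rig_item, text: Bypass circuit primed and checked}
        - {id: temperature_item, text: Room temperature within protocol range}
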