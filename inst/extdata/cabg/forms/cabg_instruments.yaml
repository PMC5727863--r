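form:
  id: cabg_instruments
  meta:
    title: Instrument preparation checklist
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: instrument_safety
      description: Instrument and swab accountability
      items:
        - {id: count_item, text: Initial instrument and swab count recorded}
        - {id: sterility_item, text: Sterility indicators verified}
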