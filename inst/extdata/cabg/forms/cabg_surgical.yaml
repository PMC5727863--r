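form:
  id: cabg_surgical
  meta:
    title: Surgical time-out checklist
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  problems:
    - id: timeout_safety
      description: Team time-out before incision
      items:
        - {id: team_item, text: All team members introduced by name and role}
        - {id: procedure_item, text: Patient and planned grafts confirmed aloud}
        - {id: antibiotics_item, text: Antibiotic prophylaxis given within 60 minutes}
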