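pathway:
  id: cabg
  meta:
    title: CABG peri-operative care pathway
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  roles:
    - {id: ward_nurse, name: Ward nurse}
    - {id: cardiologist, name: Cardiologist}
    - {id: anesthetist, name: Anesthetist}
    - {id: or_nurse, name: Operating-room nurse}
    - {id: scrub_nurse, name: Scrub nurse}
    - {id: perfusionist, name: Perfusionist}
    - {id: surgeon, name: Cardiac surgeon}
    - {id: icu_nurse, name: ICU nurse}
    - {id: physiotherapist, name: Physiotherapist}
  nodes:
    - {id: start, kind: start}
    - id: admission
      kind: task
      name: Admit patient to the cardiac ward
      roles: [ward_nurse]
      guards:
        - {trigger: on_entry, form: cabg_ward}
    - id: preop_education
      kind: task
      name: Pre-operative patient education
      roles: [ward_nurse]
    - id: preop_assessment
      kind: task
      name: Cardiological pre-operative assessment
      roles: [cardiologist]
      guards:
        - {trigger: on_entry, form: cabg_cardiology}
    - id: anesthesia_evaluation
      kind: task
      name: Anesthesiological evaluation
      roles: [anesthetist]
    - id: xs1
      kind: exclusive_split
      conditions:
        e6: high_risk == true
      default: e7
    - id: additional_workup
      kind: task
      name: Additional cardiac work-up for high-risk patients
      roles: [cardiologist]
    - {id: xm1, kind: exclusive_merge}
    - {id: ps1, kind: parallel_split}
    - id: prepare_operating_room
      kind: task
      name: Prepare the operating room
      roles: [or_nurse]
      guards:
        - {trigger: on_entry, form: cabg_or}
    - id: prepare_instruments
      kind: task
      name: Prepare and count surgical instruments
      roles: [scrub_nurse]
      guards:
        - {trigger: on_entry, form: cabg_instruments}
    - id: induce_anesthesia
      kind: task
      name: Induce anesthesia
      roles: [anesthetist]
      guards:
        - {trigger: on_entry, form: cabg_anesthesia}
    - id: position_patient
      kind: task
      name: Position and drape the patient
      roles: [or_nurse]
    - {id: pj1, kind: parallel_join}
    - id: surgical_timeout
      kind: task
      name: Surgical safety time-out
      roles: [surgeon]
      guards:
        - {trigger: on_entry, form: cabg_surgical}
    - id: initiate_bypass
      kind: task
      name: Initiate cardiopulmonary bypass
      roles: [perfusionist]
      guards:
        - {trigger: on_entry, form: cabg_perfusion}
    - id: perform_grafting
      kind: task
      name: Perform coronary grafting
      roles: [surgeon]
    - id: wean_from_bypass
      kind: task
      name: Wean from cardiopulmonary bypass
      roles: [perfusionist]
    - id: close_and_transfer
      kind: task
      name: Close chest and transfer to ICU
      roles: [surgeon]
      guards:
        - {trigger: on_exit, form: cabg_surgical}
    - id: icu_admission
      kind: task
      name: Admit to intensive care
      roles: [icu_nurse]
      guards:
        - {trigger: on_entry, form: cabg_icu}
    - id: postop_monitoring
      kind: task
      name: Post-operative monitoring
      roles: [icu_nurse]
      guards:
        - {trigger: overdue, form: cabg_icu, overdue_after: 120}
    - id: recovery_block
      kind: ad_hoc
      tasks: [pain_management, mobilization]
      mandatory: [pain_management, mobilization]
    - id: pain_management
      kind: task
      name: Post-operative pain management
      roles: [anesthetist]
    - id: mobilization
      kind: task
      name: Early mobilization
      roles: [physiotherapist]
      guards:
        - {trigger: on_entry, form: cabg_physio}
    - id: discharge_planning
      kind: task
      name: Discharge planning
      roles: [ward_nurse]
    - {id: end, kind: end}
  edges:
    - {id: e1, from: start, to: admission}
    - {id: e2, from: admission, to: preop_education}
    - {id: e3, from: preop_education, to: preop_assessment}
    - {id: e4, from: preop_assessment, to: anesthesia_evaluation}
    - {id: e5, from: anesthesia_evaluation, to: xs1}
    - {id: e6, from: xs1, to: additional_workup}
    - {id: e7, from: xs1, to: xm1}
    - {id: e8, from: additional_workup, to: xm1}
    - {id: e9, from: xm1, to: ps1}
    - {id: e10, from: ps1, to: prepare_operating_room}
    - {id: e11, from: prepare_operating_room, to: prepare_instruments}
    - {id: e12, from: prepare_instruments, to: pj1}
    - {id: e13, from: ps1, to: induce_anesthesia}
    - {id: e14, from: induce_anesthesia, to: position_patient}
    - {id: e15, from: position_patient, to: pj1}
    - {id: e16, from: pj1, to: surgical_timeout}
    - {id: e17, from: surgical_timeout, to: initiate_bypass}
    - {id: e18, from: initiate_bypass, to: perform_grafting}
    - {id: e19, from: perform_grafting, to: wean_from_bypass}
    - {id: e20, from: wean_from_bypass, to: close_and_transfer}
    - {id: e21, from: close_and_transfer, to: icu_admission}
    - {id: e22, from: icu_admission, to: postop_monitoring}
    - {id: e23, from: postop_monitoring, to: recovery_block}
    - {id: e24, from: recovery_block, to: discharge_planning}
    - {id: e25, from: discharge_planning, to: end}
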