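pathway:
  id: pci
  meta:
    title: PCI peri-operative care pathway
    author: checkflow fixtures
    version: "1.0"
    created: "2026-01-15"
  roles:
    - {id: cardiologist, name: Interventional cardiologist}
    - {id: cath_nurse, name: Catheterisation-lab nurse}
    - {id: technician, name: Radiology technician}
  nodes:
    - {id: start, kind: start}
    - id: admission
      kind: task
      name: Admit patient to the catheterisation lab
      roles: [cath_nurse]
    - {id: ps1, kind: parallel_split}
    - id: preop_preparation
      kind: task
      name: Pre-operative preparation
      roles: [cath_nurse]
      guards:
        - {trigger: on_entry, form: pci_preop}
        - {trigger: overdue, form: pci_preop, overdue_after: 120}
    - id: equipment_check
      kind: task
      name: Check imaging and contrast equipment
      roles: [technician]
    - {id: pj1, kind: parallel_join}
    - id: perform_pci
      kind: task
      name: Perform percutaneous coronary intervention
      roles: [cardiologist]
      guards:
        - {trigger: on_entry, form: pci_timeout}
    - id: xs1
      kind: exclusive_split
      conditions:
        e8: complication == true
      default: e9
    - id: extended_monitoring
      kind: task
      name: Extended post-procedural monitoring
      roles: [cardiologist]
    - {id: xm1, kind: exclusive_merge}
    - id: discharge
      kind: task
      name: Discharge and follow-up planning
      roles: [cardiologist]
    - {id: end, kind: end}
  edges:
    - {id: e1, from: start, to: admission}
    - {id: e2, from: admission, to: ps1}
    - {id: e3, from: ps1, to: preop_preparation}
    - {id: e4, from: ps1, to: equipment_check}
    - {id: e5, from: preop_preparation, to: pj1}
    - {id: e6, from: equipment_check, to: pj1}
    - {id: e7, from: pj1, to: perform_pci}
    - {id: e7b, from: perform_pci, to: xs1}
    - {id: e8, from: xs1, to: extended_monitoring}
    - {id: e9, from: xs1, to: xm1}
    - {id: e10, from: extended_monitoring, to: xm1}
    - {id: e11, from: xm1, to: discharge}
    - {id: e12, from: discharge, to: end}
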