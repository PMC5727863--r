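# checkflow

Dynamic, patient-context-aware clinical safety checklists over executable
care pathways.

Static surgical checklists treat every patient identically and arrive
whenever someone remembers them. `checkflow` is for informaticians and
clinical-safety teams who want checklists that are **process-oriented** —
delivered when a clinician enters the right task of a clinical pathway,
addressed to the right role — and **patient-specific** — with items
generated, highlighted in red, or pre-checked by clinical rules evaluated
against the patient's data.

The package provides:

* a **meta-model** of clinical pathways (tasks, roles, parallel / exclusive
  / inclusive gateways, ad-hoc blocks), checklist forms (target clinical
  problems holding checkable items with `{field}` data-binding slots), and
  safety guards (checklist deliveries triggered on task entry, exit, or
  overdue), with whole-model structural and referential validation;
* a **token-based workflow engine** executing cases with BPMN-style
  semantics and a logical clock;
* a **rule engine** for situation–action rules, `WHEN condition THEN
  action AND ...`, with nested rule invocation, provenance chains, and
  Kleene three-valued evaluation — a comparison over missing patient data
  is `unknown`, and rules fire only on `true`, so absent data can never
  assert a finding:

  ```
  eval(condition, context) ∈ {true, false, unknown}
  fire(rule) ⇔ eval(rule.condition, context) = true
  ```

* a **checklist builder and renderer** (plain text, HTML, canonical XML
  that round-trips byte-identically);
* an importer/exporter for a **BPMN 2.0 subset** and a plain-text **rule
  DSL**;
* two bundled peri-operative models — CABG (19 tasks, 9 roles) and PCI
  (with the LVEF < 50 alert rule) — plus a seedable synthetic patient
  generator and a small CLI (`inst/cli/checkflow`).

## Worked example

The bundled PCI model's pre-operative checklist, instantiated for the
example patient whose measured LVEF is 36 (below the alert threshold
of 50):

```r
library(checkflow)
m <- pci_fixture()
m
#> <checkflow model 'pci': 6 tasks, 3 roles, 2 forms, 3 rules>

inst <- instantiate_checklist("pci_preop", pci_example_patient(), m)
cat(render_instance(inst, "text"))
#> Checklist pci_preop.example_patient (form pci_preop) for patient example_patient
#> -- cardiac_function: Left ventricular function
#>   [ ] Informed consent signed and in chart
#>   [ ] Document the most recent LVEF measurement (36)
#> ! [ ] LVEF is 36, below the alert threshold of 50: assess ventricular function M
#> -- renal_function: Renal function and contrast risk
#>   [ ] Verify latest creatinine result (88)
#>   [ ] Pre-procedural hydration protocol ordered
```

The third cardiac item does not exist in the form: the `lvef_alert` rule
generated it because 36 < 50, bound the measured value into the text,
flagged it red (the `!` prefix) and high-priority (the trailing `M`). The
evaluation trace shows why each rule did or did not fire — `unknown` and
`false` are distinguished for auditability:

```r
cat(trace_lines(fire_rules(m, pci_example_patient())), sep = "\n")
#> lvef_alert	true	3
#> renal_flag	false	0
#> contrast_precaution	false	0
```

Executing a case end to end delivers checklists at the right workflow
moments: `enter_task()` fires `on_entry` guards addressed to the task's
roles, `advance_clock()` fires overdue reminders, and
`legal_completion_orders()` enumerates every task ordering the pathway
admits. The same model round-trips through BPMN:

```r
p2 <- import_bpmn(export_bpmn(m$pathway))$pathway   # graph-isomorphic
```

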