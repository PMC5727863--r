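---
title: "Dynamic clinical safety checklists: model and execution semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic clinical safety checklists: model and execution semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checkflow)
```

## The problem

Paper checklists in surgery are static: every patient receives the same
sheet, at a moment chosen by habit rather than by the care process. A
*dynamic* checklist is delivered at the right step of the clinical pathway,
to the right role, with content adapted to the individual patient: items can
be generated, highlighted or pre-checked by clinical rules running against
the patient's record.

`checkflow` implements this as three cooperating layers, mirroring how
checklist platforms separate their engines:

1. a **workflow engine** executing a clinical pathway (who may do what, in
   which order);
2. a **rule engine** evaluating situation–action rules against patient
   context (what this patient needs);
3. a **checklist engine and renderer** merging static form content with rule
   effects into a patient-specific instance.

## The pathway model and its token semantics

A pathway is a directed acyclic graph between one start and one end event.
Nodes are clinical tasks (each owned by at least one role), gateways, and
ad-hoc blocks. Four care-flow patterns are expressible:

* **sequential** — a sequence flow between two tasks;
* **parallel** — a parallel split clones the token onto every outgoing
  branch; its join waits for all of them;
* **conditional** — an exclusive split evaluates branch conditions in
  declared order and routes the token along the first true branch, falling
  back to a mandatory default edge; an inclusive split activates *every*
  true branch (or the default when none is true) and its join synchronises
  on exactly the branches activated by that firing, recorded per firing;
* **ad-hoc** — member tasks are enabled simultaneously and execute in any
  order; the block completes when its mandatory members have completed and
  the remaining members are skipped.

Design choices worth stating explicitly, because the underlying standards
leave them open:

* **Structured nesting is required.** Every split must have a matching join
  of the same family, located via immediate postdominators on the reversed
  graph. This is what makes the inclusive join decidable and lets the
  validator reject models whose join semantics would be ambiguous.
* **Ties at an exclusive split** go to the first true condition in declared
  order; a default edge is mandatory. This removes all nondeterminism from
  routing.
* **An `unknown` branch condition is treated as not taken**, consistent with
  the rule engine's missing-data stance (below): absent patient data routes
  the case along the default, conservative branch.
* **Tasks sit on exactly one incoming and one outgoing flow** (ad-hoc
  members on none). Implicit merges are disallowed; gateways make all
  control flow explicit.
* **Pathways are acyclic.** Loops would make "end reachable from every
  node" and the structured-nesting check undecidable in general; none of
  the peri-operative processes modelled here need them.
* **Time is logical**, advanced only by `advance_clock()`, in minutes. This
  exists solely to make *overdue* triggers deterministic and testable: an
  overdue guard fires exactly once, when its host task has been enabled but
  not completed for strictly longer than `overdue_after`.

Safety guards — the checklist deliveries — are bindings on tasks, not graph
nodes. A binding pairs a trigger (`on_entry`, `on_exit`, `overdue`) with a
checklist form and optional dedicated roles. When activated, the guard
behaves as a runtime task of its own, so a guard can itself carry guards.
An open guard does not block its host task's completion unless the binding
sets `blocking = TRUE`; whether checklist completion should gate care is a
hospital-policy question, so the engine defaults to non-blocking and makes
strictness per-binding.

Completing a task directly from the enabled state (without `enter_task()`)
is allowed for programmatic use and does not fire `on_entry` guards; entry
triggers are tied to the explicit entry event.

## Expressions, three-valued logic, and rules

Rules and branch conditions share one expression language: field
references, literals, comparisons (`< <= > >= == !=`), `AND`/`OR`/`NOT`,
and `EXISTS field`. There is deliberately no arithmetic: peri-operative
decision logic is threshold and boolean testing, and keeping the language
small keeps its semantics auditable. Arithmetic is a documented extension
point.

Evaluation is Kleene three-valued. A comparison touching a field absent
from the patient context yields `unknown`; `unknown` propagates through the
connectives; `EXISTS` never yields `unknown`. A rule fires **only** on
`true` — a safety checklist must never assert a patient-specific finding
from absent data. `unknown` and `false` are indistinguishable in firing but
distinguished in the evaluation trace (`trace_lines()`), so non-firing
logic remains auditable.

Rules are situation–action pairs: `WHEN condition THEN action AND action
...`. Actions add items, highlight in red, pre-check, set priority, attach
supplementary material, or invoke another rule. Nested invocation is
evaluated eagerly, depth-first, in the caller's context; rules do not
assert new facts, so there is no chaining of derived data and a fixpoint is
reached after at most one evaluation per rule per invocation root. Cycles
in the invocation graph are a modelling error: they are rejected statically
at model resolution and raise `RULE_CYCLE` at evaluation time.

When two rules target the same item with conflicting effects (for example
two `set_priority` actions), the last writer in effect order wins and both
rule ids are recorded in the item's provenance; the modelling formats give
no ordering rule for this, so the ambiguity is resolved deterministically
and visibly rather than silently.

## Checklist instantiation and rendering

`instantiate_checklist()` binds the static items' `{field}` slots to
context values, fires each target problem's algorithms, and applies the
effects in order. Rule-added items append at the end of their target
problem's block, preserving form order otherwise. A missing binding field
renders as an em dash and makes the item ineligible for auto-checking —
the system never marks done what it could not verify. Highlighting is an
explicit rule action, not automatic range checking: red marks are driven by
the same auditable rules as everything else, not by a hidden
reference-range table.

Three renderers carry identical semantic flags: gray/auto class (HTML) or
`[x]` (text) for auto-checked items, `item--red` or a `!` prefix for
abnormalities, and the trailing mark `M` for high-priority items. Layout
beyond these flags is intentionally out of scope — content and
representation are kept separate, and the XML format (documented in
`inst/extdata/instance-schema.md`) is the interchange representation. The
XML writer is canonical (fixed attribute order, two-space indent), so
render → parse → render is byte-identical.

A human may override an auto-checked item only by recording an option; the
override is logged in the instance's check log. Un-checking without a
recorded answer is not provided: an audit trail should never lose the fact
that the system had pre-checked the item.

## BPMN subset and the rule DSL

The importer/exporter covers the mapped subset: `process`, `userTask`,
`sequenceFlow` (with `conditionExpression`), the three gateway types (split
versus join decided by degree), `adHocSubProcess` (member tasks nested
inside), `laneSet`/`lane` for roles, plus the start/end events needed to
delimit a process. `conditionExpression` bodies are read in this package's
expression grammar, not XPath or FEEL — a deliberate dialect restriction so
pathway routing and rule conditions share one semantics. Triggers and
safety-guard bindings have no BPMN counterpart; they travel in
`extensionElements` under the `urn:checkflow:bpmn-ext` namespace. That
encoding is original to this package and not interoperable with any
vendor's extension format. Anything outside the subset is a hard error in
strict mode and a skip-with-warning in lenient mode.

The rule DSL (`parse_rule_dsl()`) is the single canonical on-disk rule
syntax. `add_item` names its generated item `<rule_id>_item` so later
actions in the same statement can target it.

## The bundled models and the synthetic cohort

The CABG model ships with 19 clinical tasks across 9 roles — those two
counts are the normative scale of the modelled care process; task names,
lane contents and the gateway topology are authored for this package, since
the published process is only available as a diagram. Each role's lane
carries at least one checklist guard. The PCI model carries the worked
alert logic: the LVEF rule fires iff `lvef < 50` (strict), adding a
red-flagged, high-priority item that binds the measured value (the bundled
example patient has LVEF 36); the renal rule adds the item "Renal
insufficiency noticed" and, through a nested rule, pre-checks the hydration
item and attaches the creatinine value.

`generate_patients()` draws independent per-field values (Bernoulli for
booleans, uniform or truncated normal for numbers) with per-field
missingness, deterministically given a seed. Cohort defaults for the PCI
model (LVEF normal around 55 with SD 10, 15% renal-insufficiency
prevalence, 5% missing LVEF) are plausible for an elective PCI population
and exist to exercise the machinery. The generator deliberately does not
model correlations between fields, longitudinal observation, or coding
noise present in real EMR extracts — passing tests demonstrate engine
correctness on well-formed records, not robustness to messy hospital data.

## Problem sizes used in the test-suite

The property suites run at desk scale, chosen to finish comfortably on one
CPU: 200 random expressions against the brute-force two-valued oracle, 200
fuzzed structured pathways for BPMN round-trips, exhaustive
completion-order enumeration for sub-pathways of at most 7 tasks, and 1000
seeded random executions of each bundled fixture for token conservation and
deadlock freedom. Completion-order equivalence against the
precedence-constraint oracle is checked on unconditional sub-pathways:
conditional branches execute data-dependently, so their orders are not
expressible as a fixed partial order — the conditional patterns are instead
verified directly against their routing semantics.

## Known limitations

* Composed or group roles performing one task jointly are not modelled;
  activations are addressed to roles, any holder may claim, and tasks are
  never duplicated per owner.
* Only the clinical-rule realisation of a decision algorithm is
  implemented; Bayesian networks and heuristic scores are extension points.
* Item ranking ("ranked up" layouts) is reduced to the priority flag; the
  renderer never reorders items.
* No persistence or multi-process state; a case lives in one R session.
* The expression language has no arithmetic and no date algebra; dates
  compare lexicographically as ISO strings.
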