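# Checklist-instance XML format

Canonical serialisation produced by `render_instance(x, "xml")` and read by
`parse_instance_xml()`. The writer is deterministic (fixed attribute order,
two-space indent, LF line endings), so render -> parse -> render is
byte-identical.

```
<checklist instance="..." form="..." patient="..." generated_at="0">
  <problem id="..." description="...">
    <item id="..." template="..." state="unchecked|checked|auto_checked|not_applicable"
          flags="" provenance="static | ruleA ruleB ..." priority="normal|high"
          [options="yes,no,not_applicable"] [response="..."]>
      <text>rendered item text</text>
      <bind slot="field" value="..."/>          <!-- bound patient value -->
      <bind slot="field" value="" missing="true"/> <!-- unresolvable slot -->
      <material kind="patient_data|literature" payload="..."/>
    </item>
  </problem>
</checklist>
```

* `flags` is a space-separated, sorted subset of `highlight_red`
  `priority_mark`.
* `provenance` is either the literal `static` or the rule-invocation chain
  (outermost first) that generated or last modified the item.
* An absent `options` attribute marks a guidance-only item (no checkbox,
  cannot be checked or pre-checked).
* `response` appears once a human has recorded an option.
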