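pci <- pci_fixture()

test_that("low LVEF yields one red-flagged, high-priority alert item binding the value", {
  inst <- instantiate_checklist("pci_preop", pci_example_patient(), pci)
  alerts <- Filter(function(it) !identical(it$provenance, "static"), inst$items)
  expect_length(alerts, 1L)
  a <- alerts[[1]]
  expect_true("highlight_red" %in% a$flags)
  expect_true("priority_mark" %in% a$flags)
  expect_identical(a$bound_values$lvef, 36)
  expect_identical(a$provenance, "lvef_alert")
  expect_identical(a$problem_id, "cardiac_function")
  # appended at the end of its problem block
  cardiac <- Filter(function(it) it$problem_id == "cardiac_function", inst$items)
  expect_identical(cardiac[[length(cardiac)]]$item_id, a$item_id)
})

test_that("a normal LVEF produces no alert and the instance equals its static skeleton", {
  ctx <- patient_context("p", list(lvef = 60, renal_insufficiency = FALSE,
                                   creatinine = 80))
  inst <- instantiate_checklist("pci_preop", ctx, pci)
  expect_true(all(vapply(inst$items, function(it) identical(it$provenance, "static"),
                         logical(1))))
  n_static <- sum(vapply(pci$forms$pci_preop$problems,
                         function(p) length(p$static_items), integer(1)))
  expect_length(inst$items, n_static)
})

test_that("pre_check effects auto-check items and carry nested provenance", {
  ctx <- patient_context("p", list(renal_insufficiency = TRUE, creatinine = 140))
  inst <- instantiate_checklist("pci_preop", ctx, pci)
  hyd <- inst$items[[checkflow:::find_item(inst$items, "hydration_item")]]
  expect_identical(hyd$state, "auto_checked")
  expect_identical(hyd$provenance, c("renal_flag", "contrast_precaution"))
  # the nested rule also attached the creatinine value as material
  kinds <- vapply(hyd$supplementary, `[[`, character(1), "kind")
  expect_true("patient_data" %in% kinds)
  # and the renal item text is the exact clinical wording
  added <- Filter(function(it) !identical(it$provenance, "static"), inst$items)
  expect_true("Renal insufficiency noticed" %in%
                vapply(added, `[[`, character(1), "rendered_text"))
})

test_that("item-count identity: items = static + add_item effects", {
  for (vals in list(list(lvef = 36), list(renal_insufficiency = TRUE),
                    list(lvef = 20, renal_insufficiency = TRUE, creatinine = 200),
                    list())) {
    ctx <- patient_context("p", vals)
    inst <- instantiate_checklist("pci_preop", ctx, pci)
    effs <- fire_rules(pci, ctx)
    n_add <- sum(vapply(effs, function(e) e$kind == "add_item", logical(1)))
    n_static <- sum(vapply(pci$forms$pci_preop$problems,
                           function(p) length(p$static_items), integer(1)))
    expect_length(inst$items, n_static + n_add)
    # provenance completeness: every rule-added item traces to a true rule
    tr <- attr(effs, "trace")
    for (it in inst$items) {
      if (identical(it$provenance, "static")) next
      expect_true(all(tr$truth[tr$rule_id %in% it$provenance] == "true"))
    }
  }
})

test_that("removing context fields never adds items", {
  ctx <- patient_context("p", list(lvef = 36, renal_insufficiency = TRUE,
                                   creatinine = 100))
  full_n <- length(instantiate_checklist("pci_preop", ctx, pci)$items)
  for (f in names(ctx$values)) {
    less <- ctx
    less$values[[f]] <- NULL
    expect_lte(length(instantiate_checklist("pci_preop", less, pci)$items), full_n)
  }
})

test_that("missing binding fields render as an em dash and suppress auto-check", {
  ctx <- patient_context("p", list(renal_insufficiency = TRUE))  # no creatinine
  inst <- instantiate_checklist("pci_preop", ctx, pci)
  cr <- inst$items[[checkflow:::find_item(inst$items, "creatinine_item")]]
  expect_match(cr$rendered_text, "—", fixed = TRUE)
  expect_identical(cr$missing_slots, "creatinine")
  # pre_check on an item is suppressed while a slot is missing: hydration_item
  # has no slots, so construct one directly
  form <- checklist_form("f", list(clinical_problem("p1", "x",
    list(checkable_item("slotted", "value {lvef}")), algorithm_ids = "pc")))
  model <- resolve_model(linear_pathway("T"), forms = list(form),
                         rules = list(rule("pc", "flag == true",
                                           list(action_pre_check("slotted")))),
                         schema = tiny_schema())
  inst2 <- instantiate_checklist("f", patient_context("p", list(flag = TRUE)), model)
  expect_identical(inst2$items[[1]]$state, "unchecked")
})

test_that("effects targeting absent items raise DANGLING_ITEM_REF", {
  form <- checklist_form("f", list(clinical_problem("p1", "x",
    list(checkable_item("i1", "a")), algorithm_ids = "bad")))
  model <- resolve_model(linear_pathway("T"), forms = list(form),
                         rules = list(rule("bad", "flag == true",
                                           list(action_highlight("ghost_item")))),
                         schema = tiny_schema())
  expect_error(instantiate_checklist("f", patient_context("p", list(flag = TRUE)), model),
               class = "checkflow_DANGLING_ITEM_REF")
})

test_that("human checks transition states and log auto-check overrides", {
  ctx <- patient_context("p", list(renal_insufficiency = TRUE, creatinine = 100))
  inst <- instantiate_checklist("pci_preop", ctx, pci)

  inst2 <- record_check(inst, "consent_item", "nurse_1", "yes")
  it <- inst2$items[[checkflow:::find_item(inst2$items, "consent_item")]]
  expect_identical(it$state, "checked")
  expect_identical(it$response, "yes")

  inst3 <- record_check(inst2, "creatinine_item", "nurse_1", "not_applicable")
  expect_identical(inst3$items[[checkflow:::find_item(inst3$items, "creatinine_item")]]$state,
                   "not_applicable")

  # overriding an auto-checked item is allowed but logged
  inst4 <- record_check(inst3, "hydration_item", "nurse_1", "no")
  expect_identical(inst4$items[[checkflow:::find_item(inst4$items, "hydration_item")]]$state,
                   "checked")
  expect_true(inst4$check_log$override[inst4$check_log$item_id == "hydration_item"])

  expect_error(record_check(inst, "consent_item", "n", "maybe"),
               class = "checkflow_BAD_OPTION")
  # guidance-only items cannot be checked
  ti <- instantiate_checklist("pci_timeout", ctx, pci)
  expect_error(record_check(ti, "access_item", "n", "yes"),
               class = "checkflow_NO_OPTIONS")
})

test_that("renderers are deterministic and carry the semantic flags", {
  inst <- instantiate_checklist("pci_preop", pci_example_patient(), pci)
  txt <- render_instance(inst, "text")
  expect_identical(txt, render_instance(inst, "text"))
  lines <- strsplit(txt, "\n")[[1]]
  alert <- grep("^! ", lines, value = TRUE)
  expect_length(alert, 1L)
  expect_match(alert, " M$")          # high priority ends with the mark M
  expect_match(lines[3], "^  \\[ \\] ")  # plain unchecked item
  expect_true(all(nchar(lines) <= 80L))

  html <- render_instance(inst, "html")
  expect_match(html, "item--red", fixed = TRUE)
  expect_match(html, "item--priority", fixed = TRUE)
  ctx <- patient_context("p", list(renal_insufficiency = TRUE, creatinine = 100))
  html2 <- render_instance(instantiate_checklist("pci_preop", ctx, pci), "html")
  expect_match(html2, "item--auto", fixed = TRUE)

  expect_error(render_instance(inst, "pdf"), class = "checkflow_UNKNOWN_FORMAT")
})

test_that("instance XML round-trips byte-identically", {
  for (vals in list(list(lvef = 36, creatinine = 90),
                    list(renal_insufficiency = TRUE),
                    list())) {
    inst <- instantiate_checklist("pci_preop", patient_context("p", vals), pci)
    x1 <- render_instance(inst, "xml")
    x2 <- render_instance(parse_instance_xml(x1), "xml")
    expect_identical(x1, x2)
  }
  # responses survive the round trip
  inst <- record_check(instantiate_checklist("pci_preop", pci_example_patient(), pci),
                       "consent_item", "n", "yes")
  x1 <- render_instance(inst, "xml")
  expect_identical(render_instance(parse_instance_xml(x1), "xml"), x1)
})
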