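test_that("bundled fixtures validate cleanly with the documented structure", {
  cabg <- cabg_fixture()
  rep <- validate_pathway(cabg$pathway)
  expect_true(is_valid(rep))
  n_tasks <- sum(vapply(cabg$pathway$nodes, inherits, logical(1), "cf_task"))
  expect_identical(n_tasks, 19L)
  expect_length(cabg$pathway$roles, 9L)

  pci <- pci_fixture()
  expect_true(is_valid(validate_model(pci)))
})

test_that("dangling role references and unreachable nodes are reported", {
  p <- pathway("bad", list(
    start_event(),
    clinical_task("A", "A", "ghost"),
    end_event()),
    list(flow("f1", "start", "A"), flow("f2", "A", "end")),
    roles = list(r1()))
  rep <- validate_pathway(p)
  expect_false(is_valid(rep))
  expect_true("UNRESOLVED_ROLE" %in% rep$errors$code)

  # orphan task: no incoming flow (and no path from start)
  p2 <- pathway("orphan", list(
    start_event(), clinical_task("A", "A", "r1"),
    clinical_task("B", "B", "r1"), end_event()),
    list(flow("f1", "start", "A"), flow("f2", "A", "end"),
         flow("f3", "B", "end")),
    roles = list(r1()))
  rep2 <- validate_pathway(p2)
  expect_true("UNREACHABLE_NODE" %in% rep2$errors$code)
  expect_true("B" %in% rep2$errors$where[rep2$errors$code == "UNREACHABLE_NODE"])
})

test_that("gateway structure is checked: arity, default edge, cycles", {
  expect_error(gateway("x", "exclusive_split", branch_conditions = list(e1 = "lvef < 50")),
               class = "checkflow_MISSING_DEFAULT_EDGE")

  # cycle A -> B -> A
  p <- pathway("loop", list(
    start_event(), clinical_task("A", "A", "r1"),
    clinical_task("B", "B", "r1"), end_event()),
    list(flow("f1", "start", "A"), flow("f2", "A", "B"),
         flow("f3", "B", "A"), flow("f4", "B", "end")),
    roles = list(r1()))
  expect_true("CYCLE" %in% validate_pathway(p)$errors$code)
})

test_that("form validation checks binding slots and guidance items", {
  schema <- field_schema(c(lvef = "number"))
  ok <- tiny_form()
  expect_true(is_valid(validate_form(ok, schema)))

  # misspelled slot
  bad <- checklist_form("f2", list(clinical_problem("p1", "x",
    list(checkable_item("i1", "value {lvf}")))))
  rep <- validate_form(bad, schema)
  expect_true("UNKNOWN_FIELD" %in% rep$errors$code)

  # guidance-only item marked pre-checkable
  g <- checklist_form("f3", list(clinical_problem("p1", "x",
    list(checkable_item("i1", "guide", options = NULL, pre_checked = TRUE)))))
  expect_true("GUIDANCE_PRECHECK" %in% validate_form(g, schema)$errors$code)

  # supplementary patient_data payload must resolve
  s <- checklist_form("f4", list(clinical_problem("p1", "x",
    list(checkable_item("i1", "x", supplementary = list(
      supplementary_material("patient_data", "nope")))))))
  expect_true("UNKNOWN_FIELD" %in% validate_form(s, schema)$errors$code)
})

test_that("validation is idempotent and side-effect free", {
  p <- cabg_fixture()$pathway
  expect_identical(validate_pathway(p), validate_pathway(p))
  f <- pci_fixture()$forms$pci_preop
  sc <- pci_fixture()$schema
  expect_identical(validate_form(f, sc), validate_form(f, sc))
})

test_that("model resolution fails atomically on dangling references", {
  cabg <- cabg_fixture()
  expect_length(cabg$pathway$roles, 9L)

  # guard references a form the bundle does not ship
  p <- pathway("m", list(
    start_event(),
    clinical_task("A", "A", "r1", guards = list(
      safety_guard(guard_trigger("on_entry"), "missing_form"))),
    end_event()),
    list(flow("f1", "start", "A"), flow("f2", "A", "end")),
    roles = list(r1()))
  expect_error(resolve_model(p), class = "checkflow_DANGLING_REF")

  # empty bundle: nothing to start from
  expect_error(resolve_model(NULL), class = "checkflow_DANGLING_REF")

  # invoke target missing
  p2 <- linear_pathway("A")
  r <- rule("a", "lvef < 50", list(action_invoke_rule("nope")))
  expect_error(resolve_model(p2, rules = list(r), schema = tiny_schema()),
               class = "checkflow_DANGLING_REF")
})

test_that("validated random models execute without reference errors", {
  set.seed(42)
  for (i in 1:25) {
    p <- random_structured_pathway(id = sprintf("fz%d", i))
    rep <- validate_pathway(p)
    expect_true(is_valid(rep), info = sprintf("fuzz %d: %s", i,
      paste(rep$errors$message, collapse = "; ")))
    model <- resolve_model(p, schema = field_schema(c(x = "number")))
    res <- run_case_randomly(model, patient_context("p1", list(x = sample(0:9, 1))))
    expect_false(res$deadlock, info = sprintf("fuzz %d deadlocked", i))
  }
})
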