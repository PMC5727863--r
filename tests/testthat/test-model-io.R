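test_that("the rule DSL parses statements, actions and nested invocations", {
  rules <- parse_rule_dsl(paste(
    'RULE lvef_alert WHEN lvef < 50 THEN add_item "LVEF {lvef}: evaluate cardiac function" AND highlight lvef_alert_item red',
    'RULE chain WHEN flag == true THEN invoke_rule lvef_alert',
    sep = "\n"))
  expect_named(rules, c("lvef_alert", "chain"))
  expect_length(rules$lvef_alert$actions, 2L)
  expect_identical(rules$lvef_alert$actions[[1]]$kind, "add_item")
  expect_identical(rules$lvef_alert$actions[[1]]$item$id, "lvef_alert_item")
  expect_identical(rules$lvef_alert$actions[[2]]$kind, "highlight")
  expect_identical(rules$chain$actions[[1]]$rule_id, "lvef_alert")
  expect_identical(deparse_expression(rules$lvef_alert$condition), "lvef < 50")
})

test_that("DSL errors carry position information and stable codes", {
  err <- tryCatch(parse_rule_dsl("RULE r1 WHEN lvef < 50 add_item \"x\""),
                  checkflow_PARSE_ERROR = identity)
  expect_identical(error_code(err), "PARSE_ERROR")
  expect_true(is.numeric(err$line) && is.numeric(err$col))

  expect_error(parse_rule_dsl(paste(
    'RULE dup WHEN flag == true THEN pre_check x',
    'RULE dup WHEN flag == true THEN pre_check y', sep = "\n")),
    class = "checkflow_DUPLICATE_RULE_ID")
  expect_error(parse_rule_dsl("   "), class = "checkflow_PARSE_ERROR")
})

test_that("every byte sequence either parses or raises a located PARSE_ERROR", {
  set.seed(303)
  alphabet <- c(LETTERS, letters, 0:9, " ", "\n", '"', "<", ">", "=", "(",
                ")", "{", "}", "_", ".", "-", "#", "\\", "!", "&")
  for (i in 1:150) {
    txt <- paste(sample(alphabet, sample(1:60, 1), replace = TRUE), collapse = "")
    res <- tryCatch(parse_rule_dsl(txt), checkflow_error = identity)
    ok <- is.list(res) &&
      (is.null(res$code) || res$code %in% c("PARSE_ERROR", "DUPLICATE_RULE_ID", "BAD_ID"))
    expect_true(ok, info = deparse(txt))
  }
})

test_that("DSL round-trips through format_rule_dsl", {
  rules <- pci_fixture()$rules
  again <- parse_rule_dsl(format_rule_dsl(rules))
  expect_identical(lapply(again, unclass), lapply(rules, unclass))
})

minimal_bpmn <- function(body) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<definitions xmlns="http://www.omg.org/spec/BPMN/20100524/MODEL" ',
         'xmlns:cf="urn:checkflow:bpmn-ext" id="d1" targetNamespace="t">',
         '<process id="p1">', body, '</process></definitions>')
}

test_that("BPMN import maps user tasks, flows and gateways", {
  doc <- minimal_bpmn(paste0(
    '<laneSet id="ls"><lane id="lane_r1" name="clinician">',
    '<flowNodeRef>A</flowNodeRef><flowNodeRef>B</flowNodeRef></lane></laneSet>',
    '<startEvent id="s"/><userTask id="A" name="first"/>',
    '<userTask id="B" name="second"/><endEvent id="e"/>',
    '<sequenceFlow id="f1" sourceRef="s" targetRef="A"/>',
    '<sequenceFlow id="f2" sourceRef="A" targetRef="B"/>',
    '<sequenceFlow id="f3" sourceRef="B" targetRef="e"/>'))
  res <- import_bpmn(doc)
  expect_true(is_valid(res$report))
  p <- res$pathway
  expect_s3_class(p$nodes$A, "cf_task")
  expect_identical(p$nodes$A$role_ids, "r1")
  expect_identical(order_key(legal_completion_orders(p)), "A B")
})

test_that("parallel gateways become split/join pairs by degree", {
  doc <- minimal_bpmn(paste0(
    '<laneSet id="ls"><lane id="lane_r1" name="c"><flowNodeRef>B</flowNodeRef>',
    '<flowNodeRef>C</flowNodeRef></lane></laneSet>',
    '<startEvent id="s"/><parallelGateway id="g1"/>',
    '<userTask id="B" name="B"/><userTask id="C" name="C"/>',
    '<parallelGateway id="g2"/><endEvent id="e"/>',
    '<sequenceFlow id="f1" sourceRef="s" targetRef="g1"/>',
    '<sequenceFlow id="f2" sourceRef="g1" targetRef="B"/>',
    '<sequenceFlow id="f3" sourceRef="g1" targetRef="C"/>',
    '<sequenceFlow id="f4" sourceRef="B" targetRef="g2"/>',
    '<sequenceFlow id="f5" sourceRef="C" targetRef="g2"/>',
    '<sequenceFlow id="f6" sourceRef="g2" targetRef="e"/>'))
  res <- import_bpmn(doc)
  expect_true(is_valid(res$report))
  expect_identical(res$pathway$nodes$g1$kind, "parallel_split")
  expect_identical(res$pathway$nodes$g2$kind, "parallel_join")
})

test_that("elements outside the subset are rejected in strict mode, skipped when lenient", {
  doc <- minimal_bpmn(paste0(
    '<startEvent id="s"/><scriptTask id="bad1" name="nope"/>',
    '<userTask id="A" name="A"/><endEvent id="e"/>',
    '<sequenceFlow id="f1" sourceRef="s" targetRef="A"/>',
    '<sequenceFlow id="f2" sourceRef="A" targetRef="e"/>'))
  err <- tryCatch(import_bpmn(doc, strict = TRUE), checkflow_UNSUPPORTED_ELEMENT = identity)
  expect_identical(error_code(err), "UNSUPPORTED_ELEMENT")
  expect_match(conditionMessage(err), "bad1")

  res <- import_bpmn(doc, strict = FALSE)
  expect_true("UNSUPPORTED_ELEMENT" %in% res$report$warnings$code)
  expect_false("bad1" %in% names(res$pathway$nodes))
})

test_that("BPMN export/import round-trips the fixtures isomorphically", {
  iso_check(cabg_fixture()$pathway)
  iso_check(pci_fixture()$pathway)
  # and the shipped exports match the current exporter
  shipped <- readLines(system.file("extdata", "cabg.bpmn", package = "checkflow"))
  expect_identical(paste(shipped, collapse = "\n"),
                   sub("\n$", "", export_bpmn(cabg_fixture()$pathway)))
})

test_that("BPMN round-trip holds for fuzzed structured pathways", {
  set.seed(404)
  for (i in 1:30) iso_check(random_structured_pathway(id = sprintf("rt%d", i)))
})

test_that("bundle load/save is a semantic identity and rejects unknown keys", {
  m <- pci_fixture()
  d <- withr::local_tempdir()
  save_bundle(m, d)
  m2 <- load_bundle(d)
  expect_identical(lapply(m2$forms, unclass), lapply(m$forms, unclass))
  expect_identical(lapply(m2$rules, unclass), lapply(m$rules, unclass))
  expect_identical(unclass(m2$schema), unclass(m$schema))
  expect_setequal(names(m2$pathway$nodes), names(m$pathway$nodes))

  writeLines("pathway:\n  id: x\nbogus_key: 1", file.path(d, "pathway.yaml"))
  expect_error(load_bundle(d), class = "checkflow_SCHEMA_VIOLATION")
  expect_error(load_bundle(file.path(d, "no_such_dir")),
               class = "checkflow_SCHEMA_VIOLATION")
})

test_that("bundle round-trip holds for random small models", {
  set.seed(505)
  for (i in 1:10) {
    p <- random_structured_pathway(id = sprintf("bl%d", i))
    m <- resolve_model(p, schema = field_schema(c(x = "number")))
    d <- withr::local_tempdir()
    save_bundle(m, d)
    m2 <- load_bundle(d)
    expect_setequal(names(m2$pathway$nodes), names(m$pathway$nodes))
    expect_setequal(names(m2$pathway$edges), names(m$pathway$edges))
    expect_true(is_valid(validate_model(m2)))
  }
}
)
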