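stub <- function(p) checkflow:::stub_model(p)

test_that("starting a case enables the first task only", {
  st <- start_case(stub(linear_pathway(c("A", "B"))), "p1")
  expect_identical(names(enabled_tasks(st)), "A")
  expect_identical(case_log(st)$kind[1], "CASE_STARTED")
  expect_error(start_case(resolve_model(linear_pathway("A")), "p1"),
               NA)
  # invalid models are refused
  bad <- stub(pathway("bad", list(start_event(), clinical_task("A", "A", "ghost"),
                                  end_event()),
                      list(flow("f1", "start", "A"), flow("f2", "A", "end")),
                      roles = list(r1())))
  expect_error(start_case(bad, "p1"), class = "checkflow_INVALID_MODEL")
})

test_that("parallel branches are concurrently enabled and the join waits", {
  m <- stub(parallel_pathway())
  st <- complete_task(start_case(m, "p1"), "A")$state
  expect_setequal(names(enabled_tasks(st)), c("B", "C"))
  st <- complete_task(st, "B")$state
  expect_identical(names(enabled_tasks(st)), "C")
  expect_false(case_complete(st))
  st <- complete_task(st, "C")$state
  expect_true(case_complete(st))
})

test_that("exclusive splits route on patient context, defaulting on false or unknown", {
  m <- stub(exclusive_pathway())
  st <- complete_task(start_case(m, "p1", ctx = patient_context("p1", list(lvef = 36))),
                      "A")$state
  expect_identical(names(enabled_tasks(st)), "LOW")
  st <- complete_task(start_case(m, "p2", ctx = patient_context("p2", list(lvef = 70))),
                      "A")$state
  expect_identical(names(enabled_tasks(st)), "HIGH")
  # missing lvef: unknown is not true, falls to the default branch
  st <- complete_task(start_case(m, "p3", ctx = patient_context("p3", list())),
                      "A")$state
  expect_identical(names(enabled_tasks(st)), "HIGH")
})

test_that("inclusive splits activate every true branch and the join synchronises on them", {
  m <- stub(inclusive_pathway())
  both <- complete_task(start_case(m, "p1",
    ctx = patient_context("p1", list(lvef = 30, age = 80))), "A")$state
  expect_setequal(names(enabled_tasks(both)), c("B", "C"))
  one <- complete_task(both, "B")$state
  expect_false(case_complete(one))
  expect_true(case_complete(complete_task(one, "C")$state))

  # no condition true: only the default branch runs
  def <- complete_task(start_case(m, "p2",
    ctx = patient_context("p2", list(lvef = 60, age = 50))), "A")$state
  expect_identical(names(enabled_tasks(def)), "D")
  expect_true(case_complete(complete_task(def, "D")$state))
})

test_that("actors must hold a required role; completion needs an enabled task", {
  m <- stub(linear_pathway("A"))
  st <- start_case(m, "p1")
  nurse <- potential_owner("n1", "nurse", "other_role")
  expect_error(complete_task(st, "A", nurse), class = "checkflow_ROLE_MISMATCH")
  ok <- potential_owner("d1", "doc", "r1")
  st2 <- complete_task(st, "A", ok)$state
  expect_true(case_complete(st2))
  expect_error(complete_task(st2, "A", ok), class = "checkflow_NOT_ENABLED")
})

guarded_model <- function(guards, extra_forms = list()) {
  p <- pathway("g", list(
    start_event(), clinical_task("A", "A", "r1", guards = guards), end_event()),
    list(flow("f1", "start", "A"), flow("f2", "A", "end")),
    roles = list(r1()))
  resolve_model(p, forms = c(list(tiny_form()), extra_forms),
                schema = tiny_schema())
}

test_that("entering a task fires its on_entry guards; exiting fires on_exit", {
  m <- guarded_model(list(safety_guard(guard_trigger("on_entry"), "f1")))
  r <- enter_task(start_case(m, "p1"), "A")
  expect_length(r$activations, 1L)
  expect_identical(r$activations[[1]]$guard$form_id, "f1")
  expect_identical(r$activations[[1]]$state, "open")
  expect_identical(r$activations[[1]]$roles, "r1")
  # completing afterwards fires nothing further
  expect_length(complete_task(r$state, "A")$activations, 0L)

  m2 <- guarded_model(list(safety_guard(guard_trigger("on_exit"), "f1")))
  st <- start_case(m2, "p1")
  expect_length(enter_task(st, "A")$activations, 0L)
  expect_length(complete_task(st, "A")$activations, 1L)
})

test_that("a guard activity may itself carry guards (second-level activation)", {
  inner_form <- checklist_form("f_inner", list(clinical_problem("pi", "i",
    list(checkable_item("ii", "inner item")))))
  g <- safety_guard(guard_trigger("on_entry"), "f1",
                    guards = list(safety_guard(guard_trigger("on_entry"), "f_inner")))
  m <- guarded_model(list(g), extra_forms = list(inner_form))
  r <- enter_task(start_case(m, "p1"), "A")
  r2 <- enter_guard(r$state, r$activations[[1]]$instance_id)
  expect_length(r2$activations, 1L)
  expect_identical(r2$activations[[1]]$guard$form_id, "f_inner")
  done <- complete_guard(r2$state, r$activations[[1]]$instance_id)
  expect_identical(done$pending_guards[[r$activations[[1]]$instance_id]]$state, "done")
})

test_that("overdue guards fire exactly once after the threshold is crossed", {
  m <- guarded_model(list(safety_guard(guard_trigger("overdue", overdue_after = 60), "f1")))
  st <- start_case(m, "p1")  # A enabled at t = 0
  r <- advance_clock(st, 59)
  expect_length(r$activations, 0L)
  r <- advance_clock(r$state, 2)
  expect_length(r$activations, 1L)
  r <- advance_clock(r$state, 100)
  expect_length(r$activations, 0L)
  # completed tasks never fire overdue guards
  m2 <- guarded_model(list(safety_guard(guard_trigger("overdue", overdue_after = 30), "f1")))
  st2 <- complete_task(start_case(m2, "p1"), "A")$state
  expect_length(advance_clock(st2, 500)$activations, 0L)
})

test_that("ad-hoc blocks allow any order and skip non-mandatory members", {
  m <- stub(adhoc_pathway(c("B", "C")))
  st <- complete_task(start_case(m, "p1"), "A")$state
  expect_setequal(names(enabled_tasks(st)), c("B", "C"))
  st2 <- complete_task(complete_task(st, "C")$state, "B")$state
  expect_true(case_complete(st2))

  p <- adhoc_pathway(c("B", "C", "D"))
  p$nodes$blk$mandatory_task_ids <- c("B", "C")
  m2 <- stub(p)
  st <- complete_task(start_case(m2, "p1"), "A")$state
  st <- complete_task(complete_task(st, "B")$state, "C")$state
  expect_true(case_complete(st))
  expect_identical(unname(st$task_states["D"]), "skipped")
})

test_that("completion-order enumeration matches brute force over precedence constraints", {
  expect_identical(order_key(legal_completion_orders(linear_pathway(c("A", "B", "C")))),
                   "A B C")
  expect_length(legal_completion_orders(adhoc_pathway(c("B", "C"))), 2L)
  expect_length(legal_completion_orders(adhoc_pathway(c("B", "C", "D"))), 6L)

  for (p in list(linear_pathway(c("A", "B", "C")), parallel_pathway(),
                 adhoc_pathway(c("B", "C")), adhoc_pathway(c("B", "C", "D")))) {
    expect_identical(order_key(legal_completion_orders(p)),
                     order_key(oracle_orders(p)), info = p$id)
  }
  expect_error(legal_completion_orders(linear_pathway(paste0("T", 1:8))),
               class = "checkflow_TOO_LARGE")
})

test_that("random runs conserve tokens and reach the end without deadlock", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_structured_pathway(id = sprintf("run%d", i))
    m <- resolve_model(p, schema = field_schema(c(x = "number")))
    res <- run_case_randomly(m, patient_context("p1", list(x = sample(0:9, 1))))
    expect_false(res$deadlock)
    expect_true(all(res$state$tokens == 0L),
                info = sprintf("leftover tokens in %s", p$id))
  }
})

test_that("replaying the same choices reproduces the final state exactly", {
  m <- stub(parallel_pathway())
  play <- function() {
    st <- start_case(m, "p1", "replay")
    for (t in c("A", "C", "B")) st <- complete_task(st, t)$state
    st
  }
  expect_identical(play(), play())
})
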