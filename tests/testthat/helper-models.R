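# shared builders and independent oracles for the test suite

r1 <- function() role("r1", "generic clinician")

linear_pathway <- function(tasks = c("A", "B", "C")) {
  nodes <- c(list(start_event()),
             lapply(tasks, function(t) clinical_task(t, t, "r1")),
             list(end_event()))
  seq_ids <- c("start", tasks, "end")
  edges <- lapply(seq_len(length(seq_ids) - 1L), function(i)
    flow(paste0("f", i), seq_ids[i], seq_ids[i + 1L]))
  pathway(paste0("lin", length(tasks)), nodes, edges, roles = list(r1()))
}

parallel_pathway <- function() {
  # A then B and C in parallel, then end
  pathway("par", list(
    start_event(),
    clinical_task("A", "A", "r1"),
    gateway("ps", "parallel_split"),
    clinical_task("B", "B", "r1"),
    clinical_task("C", "C", "r1"),
    gateway("pj", "parallel_join"),
    end_event()),
    list(flow("f1", "start", "A"), flow("f2", "A", "ps"),
         flow("f3", "ps", "B"), flow("f4", "ps", "C"),
         flow("f5", "B", "pj"), flow("f6", "C", "pj"),
         flow("f7", "pj", "end")),
    roles = list(r1()))
}

exclusive_pathway <- function() {
  # route to LOW when lvef < 50, else default HIGH
  pathway("xor", list(
    start_event(),
    clinical_task("A", "A", "r1"),
    gateway("xs", "exclusive_split",
            branch_conditions = list(e1 = "lvef < 50"), default_edge_id = "e2"),
    clinical_task("LOW", "low lvef branch", "r1"),
    clinical_task("HIGH", "normal branch", "r1"),
    gateway("xm", "exclusive_merge"),
    end_event()),
    list(flow("f1", "start", "A"), flow("f2", "A", "xs"),
         flow("e1", "xs", "LOW"), flow("e2", "xs", "HIGH"),
         flow("f3", "LOW", "xm"), flow("f4", "HIGH", "xm"),
         flow("f5", "xm", "end")),
    roles = list(r1()))
}

inclusive_pathway <- function() {
  pathway("ior", list(
    start_event(),
    clinical_task("A", "A", "r1"),
    gateway("is", "inclusive_split",
            branch_conditions = list(e1 = "lvef < 50", e2 = "age > 70"),
            default_edge_id = "e3"),
    clinical_task("B", "B", "r1"),
    clinical_task("C", "C", "r1"),
    clinical_task("D", "D", "r1"),
    gateway("ij", "inclusive_join"),
    end_event()),
    list(flow("f1", "start", "A"), flow("f2", "A", "is"),
         flow("e1", "is", "B"), flow("e2", "is", "C"), flow("e3", "is", "D"),
         flow("f3", "B", "ij"), flow("f4", "C", "ij"), flow("f5", "D", "ij"),
         flow("f6", "ij", "end")),
    roles = list(r1()))
}

adhoc_pathway <- function(members = c("B", "C")) {
  nodes <- c(list(start_event(), clinical_task("A", "A", "r1"),
                  ad_hoc_block("blk", members)),
             lapply(members, function(m) clinical_task(m, m, "r1")),
             list(end_event()))
  pathway(paste0("adhoc", length(members)), nodes,
          list(flow("f1", "start", "A"), flow("f2", "A", "blk"),
               flow("f3", "blk", "end")),
          roles = list(r1()))
}

tiny_schema <- function() {
  field_schema(c(lvef = "number", age = "number",
                 renal_insufficiency = "boolean", flag = "boolean"))
}

tiny_form <- function(algorithms = character(0)) {
  checklist_form("f1", list(
    clinical_problem("p1", "test problem",
                     list(checkable_item("i1", "static item one"),
                          checkable_item("i2", "value is {lvef}")),
                     algorithm_ids = algorithms)))
}

# --- independent oracles ---------------------------------------------------

# 2-valued oracle: translate the AST into base-R syntax and eval() it in an
# environment holding the (complete) context values
oracle_eval2 <- function(expr, values) {
  tr <- function(e) switch(e$type,
    field = e$name,
    lit = switch(e$kind,
      number = as.character(e$value),
      boolean = if (e$value) "TRUE" else "FALSE",
      text = deparse(e$value)),
    cmp = sprintf("(%s %s %s)", tr(e$lhs), e$op, tr(e$rhs)),
    and = sprintf("(%s & %s)", tr(e$lhs), tr(e$rhs)),
    or = sprintf("(%s | %s)", tr(e$lhs), tr(e$rhs)),
    not = sprintf("(!%s)", tr(e$arg)),
    exists = "TRUE")
  v <- eval(parse(text = tr(expr)), envir = values, enclos = baseenv())
  if (v) "true" else "false"
}

# sample() treats a length-1 numeric vector as 1:n; these never do
sample1 <- function(x) x[sample.int(length(x), 1L)]
sample_k <- function(x, k) x[sample.int(length(x), k)]

# random expression over <= 4 variables (2 numeric, 2 boolean)
random_expression <- function(depth = 3L) {
  leaf <- function() {
    if (stats::runif(1) < 0.5) {
      f <- sample(c("a", "b"), 1)
      op <- sample(c("<", "<=", ">", ">=", "==", "!="), 1)
      sprintf("%s %s %d", f, op, sample(0:9, 1))
    } else {
      f <- sample(c("p", "q"), 1)
      if (stats::runif(1) < 0.5) f else sprintf("%s == %s", f, sample(c("true", "false"), 1))
    }
  }
  build <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.3) return(leaf())
    op <- sample(c("AND", "OR", "NOT"), 1)
    if (op == "NOT") sprintf("NOT (%s)", build(d - 1L))
    else sprintf("(%s) %s (%s)", build(d - 1L), op, build(d - 1L))
  }
  parse_expression(build(depth))
}

random_full_context <- function() {
  patient_context("oracle", list(a = sample(0:9, 1), b = sample(0:9, 1),
                                 p = stats::runif(1) < 0.5, q = stats::runif(1) < 0.5))
}

# brute-force enumeration of completion orders from precedence constraints:
# t1 must precede t2 iff t2 is reachable from t1 but not vice versa (ad-hoc
# membership edges are bidirectional, so members are unordered)
oracle_orders <- function(p) {
  g <- checkflow:::pathway_igraph(p)
  tasks <- names(p$nodes)[vapply(p$nodes, inherits, logical(1), "cf_task")]
  d <- igraph::distances(g, v = tasks, to = tasks, mode = "out")
  prec <- list()
  for (t1 in tasks) for (t2 in tasks) {
    if (t1 != t2 && is.finite(d[t1, t2]) && !is.finite(d[t2, t1]))
      prec[[length(prec) + 1L]] <- c(t1, t2)
  }
  out <- list()
  recurse <- function(done, remaining) {
    if (!length(remaining)) { out[[length(out) + 1L]] <<- done; return(invisible(NULL)) }
    for (t in remaining) {
      ok <- all(vapply(prec, function(pr)
        pr[2] != t || pr[1] %in% done, logical(1)))
      if (ok) recurse(c(done, t), setdiff(remaining, t))
    }
  }
  recurse(character(0), tasks)
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out[order(keys)]
}

order_key <- function(orders) sort(vapply(orders, paste, character(1), collapse = " "))

# --- structured pathway fuzzer ---------------------------------------------

# random properly nested pathway built from sequence/parallel/exclusive/
# inclusive/ad-hoc blocks; always passes validate_pathway
random_structured_pathway <- function(max_depth = 2L, id = "fuzz") {
  counter <- new.env(); counter$n <- 0L
  fresh <- function(prefix) {
    counter$n <- counter$n + 1L
    sprintf("%s%d", prefix, counter$n)
  }
  nodes <- list(); edges <- list()
  add_node <- function(nd) nodes[[nd$id]] <<- nd
  add_edge <- function(from, to) {
    eid <- fresh("e")
    edges[[eid]] <<- flow(eid, from, to)
    eid
  }
  # emits a block between two nodes, returns nothing; from/to are node ids
  # needing a fresh connecting structure
  emit <- function(kind, from, to, depth) {
    if (kind == "task") {
      t <- fresh("t"); add_node(clinical_task(t, t, "r1"))
      add_edge(from, t); add_edge(t, to)
    } else if (kind == "seq") {
      n <- sample(2:3, 1)
      mid <- from
      for (i in seq_len(n - 1L)) {
        t <- fresh("t"); add_node(clinical_task(t, t, "r1"))
        add_edge(mid, t)
        mid <- t
      }
      emit(pick_kind(depth), mid, to, depth - 1L)
    } else if (kind == "adhoc") {
      members <- replicate(sample(2:3, 1), fresh("t"))
      for (m in members) add_node(clinical_task(m, m, "r1"))
      mand <- sample(members, sample(seq_along(members), 1))
      b <- fresh("blk"); add_node(ad_hoc_block(b, members, mand))
      add_edge(from, b); add_edge(b, to)
    } else {
      n_br <- 2L
      g1 <- fresh("g"); g2 <- fresh("g")
      split_kind <- paste0(kind, "_split")
      join_kind <- switch(kind, parallel = "parallel_join",
                          exclusive = "exclusive_merge", inclusive = "inclusive_join")
      add_edge(from, g1)
      branch_entry <- character(n_br)
      for (i in seq_len(n_br)) {
        t <- fresh("t"); add_node(clinical_task(t, t, "r1"))
        branch_entry[i] <- add_edge(g1, t)
        if (depth > 0L && stats::runif(1) < 0.5) emit(pick_kind(depth), t, g2, depth - 1L)
        else add_edge(t, g2)
      }
      if (kind == "parallel") {
        add_node(gateway(g1, "parallel_split"))
      } else {
        conds <- stats::setNames(
          lapply(seq_len(n_br - 1L), function(i) sprintf("x < %d", sample(1:9, 1))),
          branch_entry[seq_len(n_br - 1L)])
        add_node(gateway(g1, split_kind, branch_conditions = conds,
                         default_edge_id = branch_entry[n_br]))
      }
      add_node(gateway(g2, join_kind))
      add_edge(g2, to)
    }
  }
  pick_kind <- function(depth) {
    if (depth <= 0L) "task"
    else sample(c("task", "seq", "parallel", "exclusive", "inclusive", "adhoc"), 1)
  }
  add_node(start_event()); add_node(end_event())
  # top-level: a sequence of 2-3 blocks between start and end
  joints <- c("start", replicate(sample(1:2, 1), {
    t <- fresh("t"); add_node(clinical_task(t, t, "r1")); t
  }), "end")
  for (i in seq_len(length(joints) - 1L)) {
    if (i == 1L) emit(pick_kind(max_depth), joints[i], joints[i + 1L], max_depth)
    else emit(pick_kind(max_depth - 1L), joints[i], joints[i + 1L], max_depth - 1L)
  }
  pathway(id, unname(nodes), unname(edges), roles = list(r1()))
}

# shared BPMN round-trip assertion: import(export(p)) is graph-isomorphic
# with identical ids, kinds, roles, guards and branch conditions
iso_check <- function(p) {
  res <- import_bpmn(export_bpmn(p))
  q <- res$pathway
  expect_true(is_valid(res$report), info = p$id)
  expect_setequal(names(q$nodes), names(p$nodes))
  expect_setequal(names(q$edges), names(p$edges))
  expect_setequal(names(q$roles), names(p$roles))
  for (id in names(p$nodes)) {
    expect_identical(class(q$nodes[[id]])[1], class(p$nodes[[id]])[1], info = id)
    if (inherits(p$nodes[[id]], "cf_task")) {
      expect_setequal(q$nodes[[id]]$role_ids, p$nodes[[id]]$role_ids)
      expect_identical(q$nodes[[id]]$name, p$nodes[[id]]$name)
      expect_equal(q$nodes[[id]]$guards, p$nodes[[id]]$guards, info = id)
    }
    if (inherits(p$nodes[[id]], "cf_gateway")) {
      expect_identical(q$nodes[[id]]$kind, p$nodes[[id]]$kind)
      expect_identical(q$nodes[[id]]$default_edge_id, p$nodes[[id]]$default_edge_id)
      expect_identical(lapply(q$nodes[[id]]$branch_conditions, deparse_expression),
                       lapply(p$nodes[[id]]$branch_conditions, deparse_expression))
    }
    if (inherits(p$nodes[[id]], "cf_adhoc")) {
      expect_setequal(q$nodes[[id]]$task_ids, p$nodes[[id]]$task_ids)
      expect_setequal(q$nodes[[id]]$mandatory_task_ids, p$nodes[[id]]$mandatory_task_ids)
    }
  }
  for (id in names(p$edges)) {
    expect_identical(q$edges[[id]]$from, p$edges[[id]]$from, info = id)
    expect_identical(q$edges[[id]]$to, p$edges[[id]]$to, info = id)
  }
}

run_case_randomly <- function(model, ctx, max_steps = 500L) {
  st <- start_case(model, ctx$patient_id, "t", ctx)
  steps <- 0L
  max_tokens <- 0L
  while (!case_complete(st)) {
    en <- names(enabled_tasks(st))
    if (!length(en)) return(list(state = st, deadlock = TRUE))
    t <- if (length(en) == 1L) en else sample(en, 1L)
    st <- complete_task(st, t)$state
    max_tokens <- max(max_tokens, max(st$tokens))
    steps <- steps + 1L
    if (steps > max_steps) return(list(state = st, deadlock = TRUE))
  }
  list(state = st, deadlock = FALSE, steps = steps, max_tokens = max_tokens)
}
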