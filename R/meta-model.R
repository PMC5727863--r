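#' Domain types for dynamic clinical checklists
#'
#' The meta-model ties three layers together: a *process* layer (clinical
#' pathways built from tasks, gateways and ad-hoc blocks), a *checklist*
#' layer (forms holding checkable items grouped by target clinical problem),
#' and a *decision* layer (situation-action rules evaluated against patient
#' context). Constructors below build plain S3 records; [validate_pathway()],
#' [validate_form()] and [resolve_model()] enforce the structural and
#' referential invariants.
#'
#' @name meta_model
NULL

#' Clinical role
#'
#' A role is a clinical specialisation (surgeon, anesthetist, ward nurse ...)
#' that task eligibility is defined by.
#'
#' @param id identifier, `[A-Za-z0-9_.-]+`
#' @param name non-empty human-readable label
#' @return an object of class `cf_role`
#' @export
role <- function(id, name) {
  assert_id(id, "role id")
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(id = id, name = name), class = "cf_role")
}

#' Potential owner of clinical tasks
#'
#' A person eligible to perform tasks, through one or more roles. Potential
#' owners are runtime configuration, not part of the model documents.
#'
#' @param id identifier
#' @param name label
#' @param role_ids non-empty character vector of role ids
#' @param contact optional free-text contact information
#' @return an object of class `cf_owner`
#' @export
potential_owner <- function(id, name, role_ids, contact = NULL) {
  assert_id(id, "owner id")
  stopifnot(length(role_ids) >= 1L, all(vapply(role_ids, is_valid_id, logical(1))))
  structure(list(id = id, name = name, role_ids = unique(as.character(role_ids)),
                 contact = contact),
            class = "cf_owner")
}

#' Safety-guard triggers
#'
#' A trigger states when a safety guard (typically: perform a checklist)
#' activates: on entering its host task, on exiting it, or once the task has
#' been enabled but not completed for `overdue_after` minutes.
#'
#' @param kind one of `"on_entry"`, `"on_exit"`, `"overdue"`
#' @param overdue_after minutes, required (and > 0) iff `kind == "overdue"`
#' @return an object of class `cf_trigger`
#' @export
guard_trigger <- function(kind = c("on_entry", "on_exit", "overdue"),
                          overdue_after = NULL) {
  kind <- match.arg(kind)
  if (kind == "overdue") {
    stopifnot(is.numeric(overdue_after), length(overdue_after) == 1L,
              overdue_after > 0)
  } else if (!is.null(overdue_after)) {
    stop("overdue_after is only meaningful for kind = 'overdue'")
  }
  structure(list(kind = kind, overdue_after = overdue_after), class = "cf_trigger")
}

#' Safety guard binding
#'
#' Attaches a checklist form to a host clinical task, activated by a trigger.
#' When activated the guard becomes a runtime task in its own right, so a
#' guard may itself carry guards.
#'
#' @param trigger a [guard_trigger()]
#' @param form_id id of the bound checklist form
#' @param guard_role_ids roles addressed by the activation; defaults to the
#'   host task's roles
#' @param guards guards carried by the guard activity itself
#' @param blocking if `TRUE` the host task cannot complete while the
#'   activation is open (default `FALSE`)
#' @return an object of class `cf_guard`
#' @export
safety_guard <- function(trigger, form_id, guard_role_ids = NULL,
                         guards = list(), blocking = FALSE) {
  stopifnot(inherits(trigger, "cf_trigger"))
  assert_id(form_id, "form id")
  structure(list(trigger = trigger, form_id = form_id,
                 guard_role_ids = guard_role_ids, guards = guards,
                 blocking = isTRUE(blocking)),
            class = "cf_guard")
}

#' Clinical task node
#'
#' An atomic clinical activity performed by a person holding one of the
#' task's roles.
#'
#' @param id identifier, unique among pathway nodes
#' @param name label
#' @param role_ids non-empty character vector of role ids
#' @param guards list of [safety_guard()] bindings
#' @return node of classes `cf_task`, `cf_node`
#' @export
clinical_task <- function(id, name, role_ids, guards = list()) {
  assert_id(id, "task id")
  stopifnot(length(role_ids) >= 1L)
  stopifnot(all(vapply(guards, inherits, logical(1), "cf_guard")))
  structure(list(id = id, name = name, role_ids = as.character(role_ids),
                 guards = guards),
            class = c("cf_task", "cf_node"))
}

GATEWAY_KINDS <- c("parallel_split", "parallel_join",
                   "exclusive_split", "exclusive_merge",
                   "inclusive_split", "inclusive_join")

#' Gateway node
#'
#' Gateways realise the parallel and conditional care-flow patterns.
#' Splits fan out, joins/merges fan in; exclusive and inclusive splits carry
#' ordered branch conditions (evaluated against the case's patient context,
#' first-true-wins for exclusive) plus a mandatory default edge.
#'
#' @param id identifier
#' @param kind one of `r paste0('"', GATEWAY_KINDS, '"', collapse = ", ")`
#' @param branch_conditions named list mapping edge id to an expression
#'   (parsed AST or expression source text), for exclusive/inclusive splits
#' @param default_edge_id default outgoing edge, required for
#'   exclusive/inclusive splits
#' @return node of classes `cf_gateway`, `cf_node`
#' @export
gateway <- function(id, kind, branch_conditions = list(), default_edge_id = NULL) {
  assert_id(id, "gateway id")
  kind <- match.arg(kind, GATEWAY_KINDS)
  conditional <- kind %in% c("exclusive_split", "inclusive_split")
  if (conditional && is.null(default_edge_id)) {
    cf_stop("MISSING_DEFAULT_EDGE",
            sprintf("gateway '%s' (%s) requires a default edge", id, kind))
  }
  if (!conditional && (length(branch_conditions) || !is.null(default_edge_id))) {
    stop("branch conditions/default edge only apply to exclusive/inclusive splits")
  }
  branch_conditions <- lapply(branch_conditions, function(e) {
    if (is.character(e)) parse_expression(e) else e
  })
  structure(list(id = id, kind = kind, branch_conditions = branch_conditions,
                 default_edge_id = default_edge_id),
            class = c("cf_gateway", "cf_node"))
}

#' Ad-hoc block node
#'
#' Member tasks execute in no specific order; the block completes when all
#' mandatory members have completed, at which point non-mandatory members
#' are skipped.
#'
#' @param id identifier
#' @param task_ids non-empty member task ids
#' @param mandatory_task_ids subset of `task_ids` (default: all)
#' @return node of classes `cf_adhoc`, `cf_node`
#' @export
ad_hoc_block <- function(id, task_ids, mandatory_task_ids = task_ids) {
  assert_id(id, "block id")
  stopifnot(length(task_ids) >= 1L)
  if (!all(mandatory_task_ids %in% task_ids)) {
    stop("mandatory_task_ids must be a subset of task_ids")
  }
  structure(list(id = id, task_ids = as.character(task_ids),
                 mandatory_task_ids = as.character(mandatory_task_ids)),
            class = c("cf_adhoc", "cf_node"))
}

#' Start / end event nodes
#'
#' Every pathway has exactly one start and one end event delimiting the
#' case lifecycle.
#'
#' @param id identifier
#' @return node of classes `cf_start`/`cf_end`, `cf_node`
#' @export
start_event <- function(id = "start") {
  assert_id(id)
  structure(list(id = id), class = c("cf_start", "cf_node"))
}

#' @rdname start_event
#' @export
end_event <- function(id = "end") {
  assert_id(id)
  structure(list(id = id), class = c("cf_end", "cf_node"))
}

#' Sequence flow (directed edge)
#'
#' @param id identifier
#' @param from,to node ids
#' @return an object of class `cf_flow`
#' @export
flow <- function(id, from, to) {
  assert_id(id, "flow id")
  structure(list(id = id, from = from, to = to), class = "cf_flow")
}

#' Maintenance metadata for model documents
#'
#' @param title,author,version,created free text; `version` must be non-empty
#' @return an object of class `cf_meta`
#' @export
meta_info <- function(title = "", author = "", version = "0.1",
                      created = "1970-01-01") {
  stopifnot(nzchar(version))
  structure(list(title = title, author = author, version = version,
                 created = created),
            class = "cf_meta")
}

#' Clinical pathway
#'
#' A directed acyclic graph of clinical tasks, gateways and ad-hoc blocks
#' between one start and one end event. Role definitions travel with the
#' pathway so it can be validated standalone.
#'
#' @param id identifier
#' @param nodes list of nodes built by [clinical_task()], [gateway()],
#'   [ad_hoc_block()], [start_event()], [end_event()]
#' @param edges list of [flow()] edges
#' @param roles list of [role()] definitions
#' @param meta a [meta_info()]
#' @return an object of class `cf_pathway`
#' @export
pathway <- function(id, nodes, edges, roles = list(), meta = meta_info()) {
  assert_id(id, "pathway id")
  stopifnot(all(vapply(nodes, inherits, logical(1), "cf_node")),
            all(vapply(edges, inherits, logical(1), "cf_flow")),
            all(vapply(roles, inherits, logical(1), "cf_role")))
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  names(edges) <- vapply(edges, `[[`, character(1), "id")
  names(roles) <- vapply(roles, `[[`, character(1), "id")
  starts <- names(nodes)[vapply(nodes, inherits, logical(1), "cf_start")]
  ends   <- names(nodes)[vapply(nodes, inherits, logical(1), "cf_end")]
  structure(list(id = id, nodes = nodes, edges = edges, roles = roles,
                 start_node_id = if (length(starts) == 1L) starts else NA_character_,
                 end_node_id = if (length(ends) == 1L) ends else NA_character_,
                 meta = meta),
            class = "cf_pathway")
}

#' Supplementary material attached to a checkable item
#'
#' @param kind `"patient_data"` (payload names a patient-context field) or
#'   `"literature"` (payload is a citation or URI)
#' @param payload character scalar
#' @return an object of class `cf_material`
#' @export
supplementary_material <- function(kind = c("patient_data", "literature"), payload) {
  kind <- match.arg(kind)
  stopifnot(is.character(payload), length(payload) == 1L, nzchar(payload))
  structure(list(kind = kind, payload = payload), class = "cf_material")
}

#' Checkable item
#'
#' One entry of a checklist form. The description is a template whose
#' `{field}` slots are bound to patient-context values at instantiation.
#' Items without options are guidance-only (used when there is no time to
#' mark answers, e.g. emergencies) and can never be pre-checked.
#'
#' @param id identifier, unique within its form
#' @param description template text; `{field}` marks a binding slot
#' @param options character vector of answer options, or `NULL` for a
#'   guidance-only item; default `c("yes", "no", "not_applicable")`
#' @param priority `"normal"` or `"high"`
#' @param supplementary list of [supplementary_material()]
#' @param source `"static"` or `"rule:<rule_id>"` for rule-generated items
#' @param pre_checked request the item start auto-checked (invalid for
#'   guidance-only items)
#' @return an object of class `cf_item`
#' @export
checkable_item <- function(id, description,
                           options = c("yes", "no", "not_applicable"),
                           priority = c("normal", "high"),
                           supplementary = list(),
                           source = "static",
                           pre_checked = FALSE) {
  assert_id(id, "item id")
  priority <- match.arg(priority)
  stopifnot(is.character(description), length(description) == 1L)
  stopifnot(all(vapply(supplementary, inherits, logical(1), "cf_material")))
  structure(list(id = id, description = description,
                 options = if (is.null(options)) NULL else as.character(options),
                 priority = priority, supplementary = supplementary,
                 source = source, pre_checked = isTRUE(pre_checked)),
            class = "cf_item")
}

#' Binding slots of an item template
#' @param template character scalar with `{field}` slots
#' @return character vector of field names (may be empty)
#' @export
template_slots <- function(template) {
  m <- gregexpr("\\{([A-Za-z0-9_.-]+)\\}", template)[[1]]
  if (m[1] == -1L) return(character(0))
  raw <- regmatches(template, gregexpr("\\{([A-Za-z0-9_.-]+)\\}", template))[[1]]
  unique(sub("^\\{(.*)\\}$", "\\1", raw))
}

#' Target clinical problem
#'
#' Groups the checkable items within a form that address one clinical
#' concern, together with the clinical algorithms (rules) that may add or
#' modify items for it.
#'
#' @param id identifier
#' @param description free text
#' @param static_items ordered list of [checkable_item()]
#' @param algorithm_ids rule ids that may act on this problem
#' @return an object of class `cf_problem`
#' @export
clinical_problem <- function(id, description = "", static_items = list(),
                             algorithm_ids = character(0)) {
  assert_id(id, "problem id")
  stopifnot(all(vapply(static_items, inherits, logical(1), "cf_item")))
  structure(list(id = id, description = description,
                 static_items = static_items,
                 algorithm_ids = as.character(algorithm_ids)),
            class = "cf_problem")
}

#' Checklist form
#'
#' Static container for the content of a checklist task: one or more target
#' clinical problems, each holding checkable items.
#'
#' @param id identifier
#' @param problems non-empty ordered list of [clinical_problem()]
#' @param meta a [meta_info()]
#' @return an object of class `cf_form`
#' @export
checklist_form <- function(id, problems, meta = meta_info()) {
  assert_id(id, "form id")
  stopifnot(length(problems) >= 1L,
            all(vapply(problems, inherits, logical(1), "cf_problem")))
  names(problems) <- vapply(problems, `[[`, character(1), "id")
  structure(list(id = id, meta = meta, problems = problems), class = "cf_form")
}

#' Patient-context field catalogue
#'
#' Declares the patient-data fields rules and item templates may reference,
#' with their types.
#'
#' @param fields named character vector or list: field name -> type, one of
#'   `"number"`, `"boolean"`, `"text"`, `"date"`
#' @return an object of class `cf_schema`
#' @export
field_schema <- function(fields) {
  fields <- unlist(fields)
  stopifnot(length(fields) > 0L, !is.null(names(fields)),
            all(nzchar(names(fields))),
            all(fields %in% c("number", "boolean", "text", "date")))
  structure(as.list(fields), class = "cf_schema")
}

# ---------------------------------------------------------------------------
# Validation

#' Validation report
#'
#' Collects violations as data rather than raising: a model is loadable for
#' execution iff `errors` is empty. Entries have `code`, `where` (node or
#' item id) and `message`.
#'
#' @param errors,warnings data frames with columns code, where, message
#' @return an object of class `cf_report`
#' @export
validation_report <- function(errors = NULL, warnings = NULL) {
  empty <- data.frame(code = character(0), where = character(0),
                      message = character(0), stringsAsFactors = FALSE)
  structure(list(errors = if (is.null(errors)) empty else errors,
                 warnings = if (is.null(warnings)) empty else warnings),
            class = "cf_report")
}

#' @export
print.cf_report <- function(x, ...) {
  cat(sprintf("<validation report: %d error(s), %d warning(s)>\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) {
    for (i in seq_len(nrow(x$errors)))
      cat(sprintf("  E %s @%s: %s\n", x$errors$code[i], x$errors$where[i],
                  x$errors$message[i]))
  }
  if (nrow(x$warnings)) {
    for (i in seq_len(nrow(x$warnings)))
      cat(sprintf("  W %s @%s: %s\n", x$warnings$code[i], x$warnings$where[i],
                  x$warnings$message[i]))
  }
  invisible(x)
}

#' Is a report clean?
#' @param report a [validation_report()]
#' @return `TRUE` iff the report has no errors
#' @export
is_valid <- function(report) nrow(report$errors) == 0L

report_collector <- function() {
  errors <- list(); warnings <- list()
  list(
    error = function(code, where, message)
      errors[[length(errors) + 1L]] <<- data.frame(
        code = code, where = where, message = message, stringsAsFactors = FALSE),
    warning = function(code, where, message)
      warnings[[length(warnings) + 1L]] <<- data.frame(
        code = code, where = where, message = message, stringsAsFactors = FALSE),
    report = function() validation_report(
      errors = if (length(errors)) do.call(rbind, errors) else NULL,
      warnings = if (length(warnings)) do.call(rbind, warnings) else NULL)
  )
}

# igraph over pathway structure; ad-hoc membership contributes virtual
# block<->member edges so reachability covers member tasks
pathway_igraph <- function(p) {
  nodes <- names(p$nodes)
  ft <- lapply(p$edges, function(e) c(e$from, e$to))
  for (nd in p$nodes) {
    if (inherits(nd, "cf_adhoc")) {
      for (t in nd$task_ids) ft <- c(ft, list(c(nd$id, t)), list(c(t, nd$id)))
    }
  }
  el <- if (length(ft)) do.call(rbind, ft) else matrix(character(0), ncol = 2)
  keep <- el[, 1] %in% nodes & el[, 2] %in% nodes
  igraph::graph_from_data_frame(
    data.frame(from = el[keep, 1], to = el[keep, 2], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
}

node_in_edges <- function(p, id)  Filter(function(e) e$to == id, p$edges)
node_out_edges <- function(p, id) Filter(function(e) e$from == id, p$edges)

# pair each parallel/inclusive/exclusive split with its structured join via
# the immediate-postdominator chain on the (acyclic) flow graph
pair_gateways <- function(p) {
  g <- pathway_igraph(p)
  if (is.na(p$end_node_id)) return(list(pairs = list(), ok = FALSE))
  rg <- igraph::reverse_edges(g)
  dom <- tryCatch(
    igraph::dominator_tree(rg, root = p$end_node_id),
    error = function(e) NULL)
  if (is.null(dom)) return(list(pairs = list(), ok = FALSE))
  ipdom <- rep(NA_character_, length(igraph::V(g)))
  names(ipdom) <- igraph::V(g)$name
  dm <- dom$dom
  # igraph returns the immediate dominator per vertex (root excluded or NA)
  dn <- igraph::V(rg)$name
  for (i in seq_along(dm)) {
    d <- dm[i]
    if (!is.na(d) && d >= 1) ipdom[dn[i]] <- dn[d]
  }
  join_kind <- c(parallel_split = "parallel_join",
                 exclusive_split = "exclusive_merge",
                 inclusive_split = "inclusive_join")
  pairs <- list(); ok <- TRUE
  for (nd in p$nodes) {
    if (!inherits(nd, "cf_gateway") || !nd$kind %in% names(join_kind)) next
    want <- join_kind[[nd$kind]]
    cur <- ipdom[[nd$id]]
    found <- NA_character_
    while (!is.na(cur)) {
      cn <- p$nodes[[cur]]
      if (inherits(cn, "cf_gateway") && cn$kind == want) { found <- cur; break }
      cur <- if (cur %in% names(ipdom)) ipdom[[cur]] else NA_character_
    }
    if (is.na(found)) ok <- FALSE else pairs[[nd$id]] <- found
  }
  list(pairs = pairs, ok = ok)
}

#' Validate a clinical pathway
#'
#' Checks every structural invariant: unique well-formed identifiers, role
#' resolution, exactly one start and one end event, edge endpoint
#' resolution, acyclicity, reachability of every node from the start and of
#' the end from every node, gateway arity/default-edge/branch-condition
#' consistency, structured split/join nesting, and ad-hoc block membership.
#' Violations are report entries, never R errors.
#'
#' @param p a [pathway()]
#' @return a [validation_report()]
#' @export
validate_pathway <- function(p) {
  rc <- report_collector()
  ids <- vapply(p$nodes, `[[`, character(1), "id")
  for (dup in unique(ids[duplicated(ids)]))
    rc$error("DUPLICATE_ID", dup, "duplicate node id")
  for (id in ids) if (!is_valid_id(id))
    rc$error("BAD_ID", id, "node id not [A-Za-z0-9_.-]+")

  starts <- ids[vapply(p$nodes, inherits, logical(1), "cf_start")]
  ends   <- ids[vapply(p$nodes, inherits, logical(1), "cf_end")]
  if (length(starts) != 1L)
    rc$error("BAD_START", p$id, sprintf("expected 1 start event, found %d", length(starts)))
  if (length(ends) != 1L)
    rc$error("BAD_END", p$id, sprintf("expected 1 end event, found %d", length(ends)))

  known_roles <- names(p$roles)
  for (nd in p$nodes) {
    if (inherits(nd, "cf_task")) {
      if (!length(nd$role_ids))
        rc$error("NO_ROLE", nd$id, "clinical task has no role")
      for (r in setdiff(nd$role_ids, known_roles))
        rc$error("UNRESOLVED_ROLE", nd$id, sprintf("unknown role '%s'", r))
      for (gd in nd$guards) {
        for (r in setdiff(gd$guard_role_ids %||% character(0), known_roles))
          rc$error("UNRESOLVED_ROLE", nd$id, sprintf("guard references unknown role '%s'", r))
        if (gd$trigger$kind == "overdue" &&
            (is.null(gd$trigger$overdue_after) || gd$trigger$overdue_after <= 0))
          rc$error("BAD_TRIGGER", nd$id, "overdue trigger without positive overdue_after")
      }
    }
    if (inherits(nd, "cf_adhoc")) {
      for (t in setdiff(nd$task_ids, ids))
        rc$error("DANGLING_REF", nd$id, sprintf("ad-hoc member '%s' not a node", t))
      for (t in nd$task_ids) {
        if (t %in% ids && !inherits(p$nodes[[t]], "cf_task"))
          rc$error("ADHOC_NOT_TASK", nd$id, sprintf("ad-hoc member '%s' is not a clinical task", t))
      }
    }
  }

  edge_ids <- vapply(p$edges, `[[`, character(1), "id")
  for (dup in unique(edge_ids[duplicated(edge_ids)]))
    rc$error("DUPLICATE_ID", dup, "duplicate edge id")
  adhoc_members <- unlist(lapply(p$nodes, function(n)
    if (inherits(n, "cf_adhoc")) n$task_ids else character(0)))
  for (e in p$edges) {
    for (endp in c(e$from, e$to)) if (!endp %in% ids)
      rc$error("EDGE_UNKNOWN_NODE", e$id, sprintf("edge endpoint '%s' missing", endp))
    if (e$from %in% adhoc_members || e$to %in% adhoc_members)
      rc$error("ADHOC_EDGED_MEMBER", e$id,
               "ad-hoc member tasks must not carry sequence flows")
  }

  for (nd in p$nodes) {
    if (inherits(nd, "cf_task") && !nd$id %in% adhoc_members ||
        inherits(nd, "cf_adhoc")) {
      # structured modelling: tasks and blocks sit on exactly one flow each way
      if (length(node_in_edges(p, nd$id)) != 1L)
        rc$error("TASK_ARITY", nd$id, "needs exactly one incoming sequence flow")
      if (length(node_out_edges(p, nd$id)) != 1L)
        rc$error("TASK_ARITY", nd$id, "needs exactly one outgoing sequence flow")
    }
    if (!inherits(nd, "cf_gateway")) next
    ins <- length(node_in_edges(p, nd$id)); outs <- length(node_out_edges(p, nd$id))
    if (grepl("split$", nd$kind) && outs < 2L)
      rc$error("BAD_GATEWAY_ARITY", nd$id, sprintf("%s needs >= 2 outgoing edges", nd$kind))
    if (grepl("(join|merge)$", nd$kind) && ins < 2L)
      rc$error("BAD_GATEWAY_ARITY", nd$id, sprintf("%s needs >= 2 incoming edges", nd$kind))
    if (nd$kind %in% c("exclusive_split", "inclusive_split")) {
      out_ids <- vapply(node_out_edges(p, nd$id), `[[`, character(1), "id")
      for (eid in setdiff(names(nd$branch_conditions), out_ids))
        rc$error("UNKNOWN_BRANCH_EDGE", nd$id, sprintf("condition on non-outgoing edge '%s'", eid))
      if (is.null(nd$default_edge_id) || !nd$default_edge_id %in% out_ids)
        rc$error("MISSING_DEFAULT_EDGE", nd$id, "default edge absent or not outgoing")
    }
  }

  # graph-level checks run whenever ids are coherent enough to build the
  # graph (arity-style errors do not block reachability diagnostics)
  blocking <- c("DUPLICATE_ID", "BAD_ID", "EDGE_UNKNOWN_NODE",
                "BAD_START", "BAD_END", "DANGLING_REF", "ADHOC_NOT_TASK")
  if (!any(rc$report()$errors$code %in% blocking)) {
    g <- pathway_igraph(p)
    # membership edges are bidirectional by construction; test the flow
    # graph without them for cycles
    fl <- igraph::graph_from_data_frame(
      data.frame(from = vapply(p$edges, `[[`, character(1), "from"),
                 to = vapply(p$edges, `[[`, character(1), "to")),
      directed = TRUE, vertices = data.frame(name = ids))
    if (!igraph::is_acyclic(fl))
      rc$error("CYCLE", p$id, "pathway flow graph contains a cycle")
    fwd <- igraph::subcomponent(g, p$start_node_id, mode = "out")$name
    for (v in setdiff(ids, fwd))
      rc$error("UNREACHABLE_NODE", v, "not reachable from start")
    bwd <- igraph::subcomponent(g, p$end_node_id, mode = "in")$name
    for (v in setdiff(ids, bwd))
      rc$error("NO_PATH_TO_END", v, "end not reachable from node")
    if (nrow(rc$report()$errors) == 0L) {
      pg <- pair_gateways(p)
      if (!pg$ok)
        rc$error("BAD_GATEWAY_NESTING", p$id,
                 "split/join gateways do not pair up in a structured way")
    }
  }
  rc$report()
}

#' Validate a checklist form against a field catalogue
#'
#' Checks item-id uniqueness, that every `{field}` binding slot and every
#' `patient_data` supplementary payload names a declared context field, and
#' that guidance-only items are not marked pre-checkable.
#'
#' @param form a [checklist_form()]
#' @param schema a [field_schema()]
#' @return a [validation_report()]
#' @export
validate_form <- function(form, schema) {
  rc <- report_collector()
  known <- names(schema)
  seen <- character(0)
  for (pr in form$problems) {
    for (it in pr$static_items) {
      if (it$id %in% seen)
        rc$error("DUPLICATE_ID", it$id, "duplicate item id within form")
      seen <- c(seen, it$id)
      for (f in setdiff(template_slots(it$description), known))
        rc$error("UNKNOWN_FIELD", it$id, sprintf("binding slot '{%s}' not in schema", f))
      for (sm in it$supplementary) {
        if (sm$kind == "patient_data" && !sm$payload %in% known)
          rc$error("UNKNOWN_FIELD", it$id,
                   sprintf("patient_data payload '%s' not in schema", sm$payload))
      }
      if (is.null(it$options) && isTRUE(it$pre_checked))
        rc$error("GUIDANCE_PRECHECK", it$id,
                 "guidance-only item cannot be pre-checked")
    }
  }
  rc$report()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Model container and resolution

#' Assemble and cross-link a model
#'
#' A model bundles one pathway with its checklist forms, rule sets and the
#' patient-context field catalogue. `resolve_model()` verifies every
#' cross-document reference (guard form ids, problem algorithm ids, rule
#' invocation targets, expression fields) and fails atomically with
#' `DANGLING_REF` on the first dangling id; the returned model is safe to
#' execute.
#'
#' @param pathway a validated [pathway()]
#' @param forms list of [checklist_form()]
#' @param rules list of [rule()] objects
#' @param schema a [field_schema()]
#' @param owners optional runtime list of [potential_owner()]
#' @return an object of class `cf_model`
#' @export
resolve_model <- function(pathway, forms = list(), rules = list(),
                          schema = field_schema(c(.none = "text")),
                          owners = list()) {
  if (is.null(pathway) || !inherits(pathway, "cf_pathway"))
    cf_stop("DANGLING_REF", "bundle has no pathway (start node unresolvable)")
  names(forms) <- vapply(forms, `[[`, character(1), "id")
  names(rules) <- vapply(rules, `[[`, character(1), "id")
  names(owners) <- vapply(owners, `[[`, character(1), "id")

  for (nd in pathway$nodes) {
    if (!inherits(nd, "cf_task")) next
    for (gd in nd$guards) {
      if (!gd$form_id %in% names(forms))
        cf_stop("DANGLING_REF",
                sprintf("task '%s' guard references missing form '%s'", nd$id, gd$form_id),
                id = gd$form_id)
    }
  }
  for (fm in forms) {
    for (pr in fm$problems) {
      for (a in pr$algorithm_ids) if (!a %in% names(rules))
        cf_stop("DANGLING_REF",
                sprintf("problem '%s' references missing rule '%s'", pr$id, a),
                id = a)
    }
  }
  for (rl in rules) {
    for (ac in rl$actions) {
      if (ac$kind == "invoke_rule" && !ac$rule_id %in% names(rules))
        cf_stop("DANGLING_REF",
                sprintf("rule '%s' invokes missing rule '%s'", rl$id, ac$rule_id),
                id = ac$rule_id)
    }
    for (f in setdiff(expression_fields(rl$condition), names(schema)))
      cf_stop("DANGLING_REF",
              sprintf("rule '%s' condition references undeclared field '%s'", rl$id, f),
              id = f)
  }
  for (ow in owners) {
    for (r in setdiff(ow$role_ids, names(pathway$roles)))
      cf_stop("DANGLING_REF",
              sprintf("owner '%s' holds unknown role '%s'", ow$id, r), id = r)
  }
  # static rule-graph lint: invocation cycles are modelling errors
  lint_rule_cycles(rules)
  structure(list(pathway = pathway, forms = forms, rules = rules,
                 schema = schema, owners = owners),
            class = "cf_model")
}

#' Validate a whole model
#'
#' Convenience wrapper running [validate_pathway()] on the pathway and
#' [validate_form()] on every form, concatenating the reports.
#'
#' @param model a `cf_model`
#' @return a [validation_report()]
#' @export
validate_model <- function(model) {
  reports <- c(list(validate_pathway(model$pathway)),
               lapply(model$forms, validate_form, schema = model$schema))
  validation_report(
    errors = do.call(rbind, lapply(reports, `[[`, "errors")),
    warnings = do.call(rbind, lapply(reports, `[[`, "warnings")))
}

#' @export
print.cf_model <- function(x, ...) {
  n_tasks <- sum(vapply(x$pathway$nodes, inherits, logical(1), "cf_task"))
  cat(sprintf("<checkflow model '%s': %d tasks, %d roles, %d forms, %d rules>\n",
              x$pathway$id, n_tasks, length(x$pathway$roles),
              length(x$forms), length(x$rules)))
  invisible(x)
}
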