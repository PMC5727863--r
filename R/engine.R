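#' Token-based execution of clinical pathways
#'
#' A case is executed with BPMN-style token semantics: tokens live on
#' sequence flows, a clinical task is enabled while a token sits on its
#' incoming flow, and gateways consume and produce tokens according to their
#' kind. Parallel splits clone the token onto every outgoing flow and their
#' join waits for all of them; exclusive splits route the token along the
#' first branch whose condition is true (in declared order) or the default;
#' inclusive splits activate every true branch (or the default when none
#' is true) and their join synchronises on exactly the branches that were
#' activated, recorded per firing. Ad-hoc blocks enable all member tasks at
#' once and complete when the mandatory members have completed, skipping the
#' rest. An `unknown` branch condition (missing patient data) is treated as
#' not taken, consistently with the rule engine.
#'
#' The clock is logical, in minutes, advanced only by [advance_clock()]; it
#' exists to make overdue safety-guard triggers deterministic and testable.
#'
#' @name pathway_engine
NULL

#' Start a case
#'
#' @param model a resolved `cf_model` (see [resolve_model()]); it must pass
#'   [validate_model()], otherwise `INVALID_MODEL` is raised
#' @param patient_id patient identifier
#' @param case_id case identifier
#' @param ctx the case's [patient_context()], used for conditional branch
#'   routing
#' @return a `cf_case` workflow state with one token on the start event's
#'   outgoing flow (propagated, so the first task(s) are enabled)
#' @export
start_case <- function(model, patient_id, case_id = "case1",
                       ctx = patient_context(patient_id)) {
  stopifnot(inherits(model, "cf_model"))
  rep <- validate_model(model)
  if (!is_valid(rep))
    cf_stop("INVALID_MODEL",
            sprintf("model has %d validation error(s); first: %s",
                    nrow(rep$errors), rep$errors$message[1]), report = rep)
  p <- model$pathway
  tokens <- stats::setNames(integer(length(p$edges)), names(p$edges))
  node_ids <- names(p$nodes)
  task_states <- stats::setNames(rep("dormant", length(node_ids)), node_ids)
  st <- structure(list(
    case_id = case_id, patient_id = patient_id, model = model, ctx = ctx,
    task_states = task_states, tokens = tokens,
    adhoc_entered = character(0),
    incl_expect = list(),
    gateway_pairs = pair_gateways(p)$pairs,
    pending_guards = list(),
    overdue_fired = character(0),
    enabled_at = stats::setNames(numeric(0), character(0)),
    clock = 0, complete = FALSE, guard_seq = 0L,
    log = new_log()), class = "cf_case")
  st <- log_event(st, "CASE_STARTED", p$id, NA_character_)
  out <- node_out_edges(p, p$start_node_id)
  st$tokens[out[[1]]$id] <- st$tokens[out[[1]]$id] + 1L
  propagate(st)
}

new_log <- function() data.frame(time = numeric(0), kind = character(0),
                                 node = character(0), actor = character(0),
                                 stringsAsFactors = FALSE)

log_event <- function(st, kind, node, actor = NA_character_) {
  st$log <- rbind(st$log, data.frame(time = st$clock, kind = kind, node = node,
                                     actor = actor, stringsAsFactors = FALSE))
  st
}

# --- token propagation -----------------------------------------------------

# run gateway/ad-hoc/end transitions to quiescence, then refresh which
# tasks are enabled; pathways are validated acyclic so this terminates
propagate <- function(st) {
  p <- st$model$pathway
  repeat {
    progressed <- FALSE
    for (nd in p$nodes) {
      if (inherits(nd, "cf_gateway")) {
        fired <- fire_gateway(st, nd)
        if (!is.null(fired)) { st <- fired; progressed <- TRUE }
      } else if (inherits(nd, "cf_adhoc")) {
        inn <- node_in_edges(p, nd$id)
        if (length(inn) && st$tokens[inn[[1]]$id] > 0L &&
            !nd$id %in% st$adhoc_entered) {
          st$tokens[inn[[1]]$id] <- st$tokens[inn[[1]]$id] - 1L
          st$adhoc_entered <- c(st$adhoc_entered, nd$id)
          st$task_states[nd$id] <- "enabled"
          st <- log_event(st, "BLOCK_ENTERED", nd$id)
          progressed <- TRUE
        }
      } else if (inherits(nd, "cf_end")) {
        inn <- node_in_edges(p, nd$id)
        for (e in inn) {
          if (st$tokens[e$id] > 0L) {
            st$tokens[e$id] <- st$tokens[e$id] - 1L
            st$complete <- TRUE
            st <- log_event(st, "CASE_COMPLETED", nd$id)
            progressed <- TRUE
          }
        }
      }
    }
    if (!progressed) break
  }
  refresh_enabled(st)
}

fire_gateway <- function(st, nd) {
  p <- st$model$pathway
  inn <- node_in_edges(p, nd$id)
  out <- node_out_edges(p, nd$id)
  in_ids <- vapply(inn, `[[`, character(1), "id")
  out_ids <- vapply(out, `[[`, character(1), "id")
  switch(nd$kind,
    parallel_split = {
      if (st$tokens[in_ids[1]] < 1L) return(NULL)
      st$tokens[in_ids[1]] <- st$tokens[in_ids[1]] - 1L
      st$tokens[out_ids] <- st$tokens[out_ids] + 1L
      st
    },
    parallel_join = {
      if (!all(st$tokens[in_ids] >= 1L)) return(NULL)
      st$tokens[in_ids] <- st$tokens[in_ids] - 1L
      st$tokens[out_ids[1]] <- st$tokens[out_ids[1]] + 1L
      st
    },
    exclusive_split = {
      if (st$tokens[in_ids[1]] < 1L) return(NULL)
      st$tokens[in_ids[1]] <- st$tokens[in_ids[1]] - 1L
      chosen <- nd$default_edge_id
      for (eid in names(nd$branch_conditions)) {
        if (eval_expression(nd$branch_conditions[[eid]], st$ctx,
                            st$model$schema) == "true") { chosen <- eid; break }
      }
      st$tokens[chosen] <- st$tokens[chosen] + 1L
      st <- log_event(st, "BRANCH_TAKEN", nd$id, chosen)
      st
    },
    exclusive_merge = {
      src <- in_ids[st$tokens[in_ids] > 0L]
      if (!length(src)) return(NULL)
      st$tokens[src[1]] <- st$tokens[src[1]] - 1L
      st$tokens[out_ids[1]] <- st$tokens[out_ids[1]] + 1L
      st
    },
    inclusive_split = {
      if (st$tokens[in_ids[1]] < 1L) return(NULL)
      st$tokens[in_ids[1]] <- st$tokens[in_ids[1]] - 1L
      taken <- character(0)
      for (eid in names(nd$branch_conditions)) {
        if (eval_expression(nd$branch_conditions[[eid]], st$ctx,
                            st$model$schema) == "true") taken <- c(taken, eid)
      }
      if (!length(taken)) taken <- nd$default_edge_id
      st$tokens[taken] <- st$tokens[taken] + 1L
      join_id <- st$gateway_pairs[[nd$id]]
      if (!is.null(join_id)) {
        # record, per firing, which incoming flows of the join to await
        branch_to_join <- vapply(taken, function(eid)
          trace_edge_to_join(p, eid, join_id), character(1))
        q <- st$incl_expect[[join_id]] %||% list()
        st$incl_expect[[join_id]] <- c(q, list(unname(branch_to_join)))
      }
      st <- log_event(st, "BRANCH_TAKEN", nd$id, paste(taken, collapse = "+"))
      st
    },
    inclusive_join = {
      q <- st$incl_expect[[nd$id]]
      if (is.null(q) || !length(q)) return(NULL)
      want <- q[[1]]
      if (!all(st$tokens[want] >= 1L)) return(NULL)
      st$tokens[want] <- st$tokens[want] - 1L
      st$tokens[out_ids[1]] <- st$tokens[out_ids[1]] + 1L
      st$incl_expect[[nd$id]] <- q[-1]
      st
    })
}

# which incoming flow of `join_id` lies downstream of branch edge `eid`:
# follow the unique structured path until the join is the target
trace_edge_to_join <- function(p, eid, join_id) {
  cur <- eid
  for (i in seq_len(length(p$edges) + 1L)) {
    e <- p$edges[[cur]]
    if (e$to == join_id) return(cur)
    outs <- node_out_edges(p, e$to)
    if (!length(outs)) break
    # structured nesting: inner splits rejoin before the outer join, so any
    # outgoing edge leads to the same incoming flow of join_id
    cur <- outs[[1]]$id
  }
  cf_stop("BAD_GATEWAY_NESTING",
          sprintf("branch '%s' does not reach join '%s'", eid, join_id))
}

refresh_enabled <- function(st) {
  p <- st$model$pathway
  members <- unlist(lapply(p$nodes, function(n)
    if (inherits(n, "cf_adhoc")) n$task_ids else character(0)))
  for (nd in p$nodes) {
    if (!inherits(nd, "cf_task")) next
    cur <- st$task_states[nd$id]
    if (cur %in% c("completed", "skipped", "active")) next
    enabled <-
      if (nd$id %in% members) {
        blk <- Find(function(b) inherits(b, "cf_adhoc") && nd$id %in% b$task_ids, p$nodes)
        blk$id %in% st$adhoc_entered && st$task_states[blk$id] != "completed"
      } else {
        any(vapply(node_in_edges(p, nd$id), function(e) st$tokens[e$id] > 0L, logical(1)))
      }
    if (enabled && cur == "dormant") {
      st$task_states[nd$id] <- "enabled"
      st$enabled_at[nd$id] <- st$clock
      st <- log_event(st, "TASK_ENABLED", nd$id)
    } else if (!enabled && cur == "enabled") {
      st$task_states[nd$id] <- "dormant"
    }
  }
  st
}

# --- queries ---------------------------------------------------------------

#' Currently enabled tasks
#'
#' Pure query. Parallel branches report all concurrently enabled tasks;
#' an entered ad-hoc block reports all its not-yet-completed member tasks.
#'
#' @param st a `cf_case`
#' @return named list mapping enabled task id to its role ids
#' @export
enabled_tasks <- function(st) {
  stopifnot(inherits(st, "cf_case"))
  ids <- names(st$task_states)[st$task_states == "enabled"]
  ids <- ids[vapply(ids, function(i) inherits(st$model$pathway$nodes[[i]], "cf_task"),
                    logical(1))]
  stats::setNames(lapply(ids, function(i) st$model$pathway$nodes[[i]]$role_ids), ids)
}

#' Is the case complete?
#' @param st a `cf_case`
#' @return logical
#' @export
case_complete <- function(st) isTRUE(st$complete)

# --- guard activation ------------------------------------------------------

new_activation <- function(st, gd, host_task_id) {
  st$guard_seq <- st$guard_seq + 1L
  roles <- gd$guard_role_ids
  if (is.null(roles)) {
    host <- st$model$pathway$nodes[[host_task_id]]
    roles <- if (!is.null(host)) host$role_ids else character(0)
  }
  act <- structure(list(
    instance_id = sprintf("%s.g%d", st$case_id, st$guard_seq),
    guard = gd, host_task_id = host_task_id,
    activated_at = st$clock, state = "open", roles = roles),
    class = "cf_activation")
  st$pending_guards[[act$instance_id]] <- act
  st <- log_event(st, "GUARD_ACTIVATED", host_task_id, act$instance_id)
  list(state = st, activation = act)
}

fire_trigger_guards <- function(st, task_id, kind) {
  nd <- st$model$pathway$nodes[[task_id]]
  acts <- list()
  for (gd in nd$guards) {
    if (gd$trigger$kind == kind) {
      r <- new_activation(st, gd, task_id)
      st <- r$state
      acts[[length(acts) + 1L]] <- r$activation
    }
  }
  list(state = st, activations = acts)
}

#' Enter a task
#'
#' Marks an enabled task active and fires its `on_entry` safety guards:
#' each matching guard binding yields one open [GuardActivation] addressed
#' to the guard's roles (defaulting to the host task's). This is the moment
#' a dynamic checklist is delivered — each checklist is triggered when a
#' clinical user enters a clinical task.
#'
#' @param st a `cf_case`
#' @param task_id id of an enabled task
#' @param actor optional [potential_owner()]; when given, must hold one of
#'   the task's roles
#' @return list with elements `state` (new `cf_case`) and `activations`
#'   (list of guard activations)
#' @export
enter_task <- function(st, task_id, actor = NULL) {
  stopifnot(inherits(st, "cf_case"))
  if (is.na(st$task_states[task_id]) || st$task_states[task_id] != "enabled")
    cf_stop("NOT_ENABLED", sprintf("task '%s' is not enabled", task_id))
  check_actor_role(st, task_id, actor)
  st$task_states[task_id] <- "active"
  st <- log_event(st, "TASK_ENTERED", task_id, actor_id(actor))
  fire_trigger_guards(st, task_id, "on_entry")
}

#' Complete a task
#'
#' Completes an enabled or active task, consumes its input token, produces
#' downstream tokens (evaluating exclusive/inclusive split conditions
#' against the case's patient context) and fires `on_exit` guards. For
#' ad-hoc member tasks, completion of the last mandatory member completes
#' the whole block and skips the remaining members.
#'
#' @inheritParams enter_task
#' @return list with elements `state` and `activations`
#' @export
complete_task <- function(st, task_id, actor = NULL) {
  stopifnot(inherits(st, "cf_case"))
  if (is.na(st$task_states[task_id]) ||
      !st$task_states[task_id] %in% c("enabled", "active"))
    cf_stop("NOT_ENABLED", sprintf("task '%s' is not enabled or active", task_id))
  check_actor_role(st, task_id, actor)
  for (ga in st$pending_guards) {
    if (ga$state == "open" && ga$host_task_id == task_id && ga$guard$blocking)
      cf_stop("GUARD_BLOCKING",
              sprintf("open blocking guard '%s' on task '%s'", ga$instance_id, task_id))
  }
  p <- st$model$pathway
  members <- unlist(lapply(p$nodes, function(n)
    if (inherits(n, "cf_adhoc")) n$task_ids else character(0)))
  st$task_states[task_id] <- "completed"
  st <- log_event(st, "TASK_COMPLETED", task_id, actor_id(actor))
  res <- fire_trigger_guards(st, task_id, "on_exit")
  st <- res$state

  if (task_id %in% members) {
    blk <- Find(function(b) inherits(b, "cf_adhoc") && task_id %in% b$task_ids, p$nodes)
    done <- all(st$task_states[blk$mandatory_task_ids] == "completed")
    if (done) {
      for (t in blk$task_ids) {
        if (!st$task_states[t] %in% c("completed", "skipped")) {
          st$task_states[t] <- "skipped"
          st <- log_event(st, "TASK_SKIPPED", t)
        }
      }
      st$task_states[blk$id] <- "completed"
      st <- log_event(st, "BLOCK_COMPLETED", blk$id)
      out <- node_out_edges(p, blk$id)
      st$tokens[out[[1]]$id] <- st$tokens[out[[1]]$id] + 1L
    }
  } else {
    inn <- node_in_edges(p, task_id)
    src <- Find(function(e) st$tokens[e$id] > 0L, inn)
    if (!is.null(src)) st$tokens[src$id] <- st$tokens[src$id] - 1L
    out <- node_out_edges(p, task_id)
    st$tokens[out[[1]]$id] <- st$tokens[out[[1]]$id] + 1L
  }
  st <- propagate(st)
  list(state = st, activations = res$activations)
}

check_actor_role <- function(st, task_id, actor) {
  if (is.null(actor)) return(invisible(TRUE))
  stopifnot(inherits(actor, "cf_owner"))
  roles <- st$model$pathway$nodes[[task_id]]$role_ids
  if (!length(intersect(actor$role_ids, roles)))
    cf_stop("ROLE_MISMATCH",
            sprintf("actor '%s' holds none of the roles required by task '%s' (%s)",
                    actor$id, task_id, paste(roles, collapse = ", ")))
  invisible(TRUE)
}

actor_id <- function(actor) if (is.null(actor)) NA_character_ else actor$id

#' Enter / complete a guard activation
#'
#' An activated safety guard behaves as a runtime clinical task: entering it
#' fires the guard activity's own `on_entry` guards (a guard may carry
#' guards), completing it closes the activation.
#'
#' @param st a `cf_case`
#' @param instance_id guard activation id
#' @param actor optional [potential_owner()]
#' @return `enter_guard()`: list of `state` and `activations`;
#'   `complete_guard()`: the new state
#' @export
enter_guard <- function(st, instance_id, actor = NULL) {
  ga <- st$pending_guards[[instance_id]]
  if (is.null(ga) || ga$state != "open")
    cf_stop("NOT_ENABLED", sprintf("guard activation '%s' is not open", instance_id))
  st <- log_event(st, "GUARD_ENTERED", ga$host_task_id, instance_id)
  acts <- list()
  for (gd in ga$guard$guards) {
    if (gd$trigger$kind == "on_entry") {
      r <- new_activation(st, gd, ga$host_task_id)
      st <- r$state
      acts[[length(acts) + 1L]] <- r$activation
    }
  }
  list(state = st, activations = acts)
}

#' @rdname enter_guard
#' @export
complete_guard <- function(st, instance_id, actor = NULL) {
  ga <- st$pending_guards[[instance_id]]
  if (is.null(ga) || ga$state != "open")
    cf_stop("NOT_ENABLED", sprintf("guard activation '%s' is not open", instance_id))
  st$pending_guards[[instance_id]]$state <- "done"
  log_event(st, "GUARD_COMPLETED", ga$host_task_id, instance_id)
}

#' Advance the logical clock
#'
#' Moves the case clock forward and fires `overdue` safety guards exactly
#' once per binding: a guard fires when its host task has been enabled but
#' not completed for strictly longer than `overdue_after` minutes.
#'
#' @param st a `cf_case`
#' @param minutes positive number of minutes
#' @return list with elements `state` and `activations` (overdue guard
#'   activations fired by this advance)
#' @export
advance_clock <- function(st, minutes) {
  stopifnot(inherits(st, "cf_case"), is.numeric(minutes), minutes > 0)
  st$clock <- st$clock + minutes
  st <- log_event(st, "CLOCK_ADVANCED", NA_character_, as.character(minutes))
  acts <- list()
  p <- st$model$pathway
  for (nd in p$nodes) {
    if (!inherits(nd, "cf_task")) next
    if (!st$task_states[nd$id] %in% c("enabled", "active")) next
    t0 <- st$enabled_at[nd$id]
    if (is.na(t0)) next
    for (k in seq_along(nd$guards)) {
      gd <- nd$guards[[k]]
      if (gd$trigger$kind != "overdue") next
      key <- sprintf("%s#%d", nd$id, k)
      if (key %in% st$overdue_fired) next
      if (st$clock - t0 > gd$trigger$overdue_after) {
        r <- new_activation(st, gd, nd$id)
        st <- r$state
        acts[[length(acts) + 1L]] <- r$activation
        st$overdue_fired <- c(st$overdue_fired, key)
      }
    }
  }
  list(state = st, activations = acts)
}

# --- enumeration of completion orders --------------------------------------

#' Enumerate legal task-completion orders
#'
#' Explores every interleaving reachable by repeatedly completing any
#' enabled task, returning the set of complete task-id sequences. Intended
#' as an executable semantics for small pathways (test-oracle support);
#' refuses pathways with more than `max_tasks` clinical tasks.
#'
#' @param x a `cf_model` or a bare [pathway()] (forms referenced by guards
#'   are stubbed; guards do not influence ordering)
#' @param ctx optional [patient_context()] for conditional branch routing
#' @param max_tasks refusal threshold (default 7)
#' @return list of character vectors (task ids in completion order), sorted
#'   lexicographically
#' @export
legal_completion_orders <- function(x, ctx = NULL, max_tasks = 7L) {
  model <- if (inherits(x, "cf_model")) x else stub_model(x)
  n_tasks <- sum(vapply(model$pathway$nodes, inherits, logical(1), "cf_task"))
  if (n_tasks > max_tasks)
    cf_stop("TOO_LARGE", sprintf("%d tasks exceeds max_tasks = %d", n_tasks, max_tasks))
  ctx <- ctx %||% patient_context("p0")
  st0 <- start_case(model, ctx$patient_id, "enum", ctx)
  out <- list()
  walk <- function(st, prefix) {
    en <- names(enabled_tasks(st))
    if (!length(en)) {
      if (case_complete(st)) out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (t in sort(en)) {
      st2 <- complete_task(st, t)$state
      walk(st2, c(prefix, t))
    }
  }
  walk(st0, character(0))
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out[order(keys)][!duplicated(sort(keys))]
}

# wrap a bare pathway as an executable model, stubbing guard form refs
stub_model <- function(p) {
  stopifnot(inherits(p, "cf_pathway"))
  form_ids <- unique(unlist(lapply(p$nodes, function(n)
    if (inherits(n, "cf_task")) vapply(n$guards, `[[`, character(1), "form_id")
    else character(0))))
  forms <- lapply(form_ids, function(fid)
    checklist_form(fid, list(clinical_problem(
      paste0(fid, ".p"), "stub",
      list(checkable_item(paste0(fid, ".i"), "stub item"))))))
  resolve_model(p, forms = forms)
}

#' Event log of a case
#' @param st a `cf_case`
#' @return data frame with columns time, kind, node, actor
#' @export
case_log <- function(st) st$log

#' Export the event log as structured lines
#'
#' One record per event, tab-separated in fixed field order
#' (time, kind, node, actor).
#' @param st a `cf_case`
#' @return character vector
#' @export
log_lines <- function(st) {
  lg <- st$log
  sprintf("%g\t%s\t%s\t%s", lg$time, lg$kind,
          ifelse(is.na(lg$node), "-", lg$node),
          ifelse(is.na(lg$actor), "-", lg$actor))
}
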