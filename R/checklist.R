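#' Patient-specific checklist instances
#'
#' [instantiate_checklist()] merges a form's static items with the effects
#' of its clinical rules for one patient: rules may add items, highlight
#' abnormal findings in red, pre-check items the system can verify itself,
#' raise priorities and attach supplementary material. Every rule-generated
#' artefact carries provenance (the rule-invocation chain that produced it),
#' so a clinician can always ask *why* an item is on their checklist.
#'
#' @name checklist_builder
NULL

ITEM_STATES <- c("unchecked", "checked", "auto_checked", "not_applicable")
ITEM_FLAGS  <- c("highlight_red", "priority_mark")

format_value <- function(v) {
  if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE)
  else if (is.logical(v)) if (v) "true" else "false"
  else as.character(v)
}

# build one item instance from a checkable-item template; missing binding
# fields render as an em dash and make the item ineligible for auto-check
bind_item <- function(it, ctx, problem_id, provenance) {
  slots <- template_slots(it$description)
  bound <- list(); missing <- character(0)
  text <- it$description
  for (s in slots) {
    v <- context_value(ctx, s)
    if (is.null(v)) {
      missing <- c(missing, s)
      text <- gsub(paste0("{", s, "}"), "—", text, fixed = TRUE)
    } else {
      bound[[s]] <- v
      text <- gsub(paste0("{", s, "}"), format_value(v), text, fixed = TRUE)
    }
  }
  state <- "unchecked"
  if (isTRUE(it$pre_checked) && !is.null(it$options) && !length(missing))
    state <- "auto_checked"
  structure(list(
    item_id = it$id, template = it$description, rendered_text = text,
    state = state,
    flags = if (it$priority == "high") "priority_mark" else character(0),
    bound_values = bound,
    missing_slots = missing, options = it$options, priority = it$priority,
    supplementary = it$supplementary, response = NULL,
    provenance = provenance, problem_id = problem_id),
    class = "cf_item_instance")
}

#' Instantiate a checklist form for one patient
#'
#' Static items are bound to the patient context; then the rules referenced
#' by each target clinical problem are fired (in problem order, rule
#' declaration order, depth-first through invocations) and their effects
#' applied in order. `add_item` appends the new item at the end of its
#' problem's block; item-targeting effects must reference an item present in
#' the instance, otherwise `DANGLING_ITEM_REF` is raised. An item whose
#' binding slots are incompletely covered by the context renders the missing
#' slot as an em dash and is never auto-checked.
#'
#' @param form a [checklist_form()] or the id of a form in `model`
#' @param ctx a [patient_context()]
#' @param model a `cf_model` supplying rules and schema
#' @param instance_id identifier for the instance (default derived from form
#'   and patient ids)
#' @param generated_at logical time stamp in minutes
#' @return an object of class `cf_instance`
#' @export
instantiate_checklist <- function(form, ctx, model,
                                  instance_id = NULL, generated_at = 0) {
  if (is.character(form)) {
    form_obj <- model$forms[[form]]
    if (is.null(form_obj)) cf_stop("DANGLING_REF", sprintf("no form '%s' in model", form))
    form <- form_obj
  }
  stopifnot(inherits(form, "cf_form"), inherits(ctx, "cf_context"))
  instance_id <- instance_id %||% paste(form$id, ctx$patient_id, sep = ".")

  items <- list()
  trace <- character(0)
  effects_fired <- 0L
  for (pr in form$problems) {
    for (it in pr$static_items)
      items[[length(items) + 1L]] <- bind_item(it, ctx, pr$id, "static")
  }
  # fire each problem's algorithms (with the full rule catalogue available
  # for invoke_rule resolution), then apply effects in problem order
  for (pr in form$problems) {
    if (!length(pr$algorithm_ids)) next
    effs <- fire_problem_rules(model, pr$algorithm_ids, ctx)
    trace <- c(trace, trace_lines(effs))
    for (eff in effs) {
      effects_fired <- effects_fired + 1L
      items <- apply_effect(items, eff, ctx, pr$id)
    }
  }
  if (!length(items))
    cf_stop("EMPTY_INSTANCE", sprintf("form '%s' produced no items", form$id))
  structure(list(instance_id = instance_id, form_id = form$id,
                 patient_id = ctx$patient_id, generated_at = generated_at,
                 items = items, n_effects = effects_fired,
                 problems = lapply(form$problems, function(p)
                   list(id = p$id, description = p$description)),
                 trace = trace, check_log = new_check_log()),
            class = "cf_instance")
}

# evaluate only the problem's algorithm rules as roots, but let invoke_rule
# reach any rule in the model
fire_problem_rules <- function(model, algorithm_ids, ctx) {
  roots <- model$rules[algorithm_ids]
  others <- model$rules[setdiff(names(model$rules), algorithm_ids)]
  all_rules <- c(roots, others)
  effs <- fire_rules(all_rules, ctx, model$schema)
  tr <- attr(effs, "trace")
  # keep only effects whose outermost provenance is one of the roots
  keep <- vapply(effs, function(e) e$provenance[1] %in% algorithm_ids, logical(1))
  out <- effs[keep]
  attr(out, "trace") <- tr[tr$rule_id %in% reachable_rules(model$rules, algorithm_ids), ,
                           drop = FALSE]
  out
}

reachable_rules <- function(rules, roots) {
  seen <- character(0); frontier <- roots
  while (length(frontier)) {
    nxt <- character(0)
    for (rid in frontier) {
      if (rid %in% seen || is.null(rules[[rid]])) next
      seen <- c(seen, rid)
      for (ac in rules[[rid]]$actions)
        if (ac$kind == "invoke_rule") nxt <- c(nxt, ac$rule_id)
    }
    frontier <- nxt
  }
  seen
}

find_item <- function(items, item_id) {
  for (i in seq_along(items)) if (items[[i]]$item_id == item_id) return(i)
  NA_integer_
}

apply_effect <- function(items, eff, ctx, problem_id) {
  target_problem <- eff$problem_id %||% problem_id
  if (eff$kind == "add_item") {
    it <- eff$item
    it$source <- paste0("rule:", eff$provenance[length(eff$provenance)])
    inst <- bind_item(it, ctx, target_problem, eff$provenance)
    # append at the end of the target problem's block, preserving form order
    idx <- which(vapply(items, function(x) x$problem_id == target_problem, logical(1)))
    pos <- if (length(idx)) max(idx) else length(items)
    items <- append(items, list(inst), after = pos)
    return(items)
  }
  i <- find_item(items, eff$item_id)
  if (is.na(i))
    cf_stop("DANGLING_ITEM_REF",
            sprintf("effect '%s' targets item '%s' absent from the instance",
                    eff$kind, eff$item_id))
  it <- items[[i]]
  if (eff$kind == "highlight") {
    it$flags <- union(it$flags, "highlight_red")
  } else if (eff$kind == "pre_check") {
    if (is.null(it$options))
      cf_stop("GUIDANCE_PRECHECK",
              sprintf("guidance-only item '%s' cannot be pre-checked", it$item_id))
    if (!length(it$missing_slots) && it$state == "unchecked")
      it$state <- "auto_checked"
  } else if (eff$kind == "set_priority") {
    it$priority <- eff$level
    it$flags <- if (eff$level == "high") union(it$flags, "priority_mark")
                else setdiff(it$flags, "priority_mark")
  } else if (eff$kind == "attach_material") {
    it$supplementary <- c(it$supplementary, list(eff$material))
  }
  it$provenance <- unique(c(setdiff(it$provenance, "static"), eff$provenance))
  if (!length(it$provenance)) it$provenance <- "static"
  items[[i]] <- it
  items
}

new_check_log <- function() data.frame(item_id = character(0), actor = character(0),
                                       option = character(0), override = logical(0),
                                       stringsAsFactors = FALSE)

#' Record a human check on an instance item
#'
#' Transitions `unchecked -> checked` (or `not_applicable` when that option
#' is chosen). Auto-checked items may be overridden by a human check; the
#' override is recorded in the instance's check log. Guidance-only items
#' have no options and cannot be checked.
#'
#' @param instance a `cf_instance`
#' @param item_id target item
#' @param actor actor identifier (free text) or a [potential_owner()]
#' @param option one of the item's options
#' @return the updated `cf_instance`
#' @export
record_check <- function(instance, item_id, actor, option) {
  i <- find_item(instance$items, item_id)
  if (is.na(i))
    cf_stop("DANGLING_ITEM_REF", sprintf("no item '%s' in instance", item_id))
  it <- instance$items[[i]]
  if (is.null(it$options))
    cf_stop("NO_OPTIONS", sprintf("item '%s' is guidance-only", item_id))
  if (!option %in% it$options)
    cf_stop("BAD_OPTION", sprintf("option '%s' not among {%s}", option,
                                  paste(it$options, collapse = ", ")))
  override <- it$state == "auto_checked"
  it$state <- if (option == "not_applicable") "not_applicable" else "checked"
  it$response <- option
  instance$items[[i]] <- it
  actor <- if (inherits(actor, "cf_owner")) actor$id else as.character(actor)
  instance$check_log <- rbind(instance$check_log, data.frame(
    item_id = item_id, actor = actor, option = option, override = override,
    stringsAsFactors = FALSE))
  instance
}

#' @export
print.cf_instance <- function(x, ...) {
  cat(render_instance(x, "text"), sep = "\n")
  invisible(x)
}
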