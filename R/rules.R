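#' Situation-action rules
#'
#' A rule pairs a condition [parse_expression()] with an ordered list of
#' actions. Actions either shape a checklist instance (`add_item`,
#' `highlight`, `pre_check`, `set_priority`, `attach_material`) or invoke
#' another rule (`invoke_rule`), which is what makes rules *nested*: a
#' clinical algorithm decomposes into sub-rules the way guideline flowcharts
#' decompose into sub-guidelines.
#'
#' @param id identifier
#' @param condition expression source text or `cf_expr` AST
#' @param actions non-empty list of `cf_action` objects
#' @param problem_id optional id of the target clinical problem rule-added
#'   items belong to
#' @return an object of class `cf_rule`
#' @export
rule <- function(id, condition, actions, problem_id = NULL) {
  assert_id(id, "rule id")
  if (is.character(condition)) condition <- parse_expression(condition)
  stopifnot(length(actions) >= 1L,
            all(vapply(actions, inherits, logical(1), "cf_action")))
  structure(list(id = id, condition = condition, actions = actions,
                 problem_id = problem_id),
            class = "cf_rule")
}

new_action <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "cf_action")
}

#' Rule actions
#'
#' Constructors for the six action kinds. `add_item` carries a
#' [checkable_item()] template (its `source` is stamped `rule:<id>` when the
#' rule fires); the item-targeting actions reference an item id in the
#' instance under construction; `invoke_rule` evaluates another rule in the
#' same patient context.
#'
#' @param item a [checkable_item()] template
#' @param item_id target item id
#' @param color highlight colour; only `"red"` carries checklist semantics
#' @param level `"normal"` or `"high"`
#' @param material a [supplementary_material()]
#' @param rule_id id of the invoked rule
#' @return an object of class `cf_action`
#' @name actions
NULL

#' @rdname actions
#' @export
action_add_item <- function(item) {
  stopifnot(inherits(item, "cf_item"))
  new_action("add_item", item = item)
}

#' @rdname actions
#' @export
action_highlight <- function(item_id, color = "red") {
  assert_id(item_id, "item id")
  stopifnot(identical(color, "red"))
  new_action("highlight", item_id = item_id, color = color)
}

#' @rdname actions
#' @export
action_pre_check <- function(item_id) {
  assert_id(item_id, "item id")
  new_action("pre_check", item_id = item_id)
}

#' @rdname actions
#' @export
action_set_priority <- function(item_id, level = c("high", "normal")) {
  assert_id(item_id, "item id")
  new_action("set_priority", item_id = item_id, level = match.arg(level))
}

#' @rdname actions
#' @export
action_attach_material <- function(item_id, material) {
  assert_id(item_id, "item id")
  stopifnot(inherits(material, "cf_material"))
  new_action("attach_material", item_id = item_id, material = material)
}

#' @rdname actions
#' @export
action_invoke_rule <- function(rule_id) {
  assert_id(rule_id, "rule id")
  new_action("invoke_rule", rule_id = rule_id)
}

# ---------------------------------------------------------------------------

#' Fire a collection of rules against a patient context
#'
#' Each rule's condition is evaluated in three-valued logic; its actions
#' emit effects iff the condition is `"true"` (`"false"` and `"unknown"`
#' both suppress, so missing data never fires a rule). Effects appear in
#' rule declaration order, then action order, depth-first through
#' `invoke_rule` chains; invoked rules are evaluated eagerly in the same
#' (caller's) context. Each effect carries a provenance chain of rule ids,
#' outermost invocation first.
#'
#' An `invoke_rule` chain that revisits a rule id raises `RULE_CYCLE`.
#'
#' @param rules list of [rule()] objects (or a `cf_model`, whose rules are
#'   used)
#' @param ctx a [patient_context()]
#' @param schema optional [field_schema()] for runtime type checking
#' @return list of `cf_effect` objects; attribute `"trace"` holds a data
#'   frame with one row per rule evaluation (rule id, truth value, number of
#'   effects emitted)
#' @export
fire_rules <- function(rules, ctx, schema = NULL) {
  if (inherits(rules, "cf_model")) {
    schema <- schema %||% rules$schema
    rules <- rules$rules
  }
  stopifnot(all(vapply(rules, inherits, logical(1), "cf_rule")))
  names(rules) <- vapply(rules, `[[`, character(1), "id")
  effects <- list()
  trace <- list()

  eval_rule <- function(rl, chain) {
    if (rl$id %in% chain)
      cf_stop("RULE_CYCLE",
              sprintf("rule invocation chain revisits '%s' (chain: %s)",
                      rl$id, paste(c(chain, rl$id), collapse = " -> ")))
    chain <- c(chain, rl$id)
    truth <- eval_expression(rl$condition, ctx, schema)
    n_before <- length(effects)
    if (truth == "true") {
      for (ac in rl$actions) {
        if (ac$kind == "invoke_rule") {
          target <- rules[[ac$rule_id]]
          if (is.null(target))
            cf_stop("DANGLING_REF",
                    sprintf("rule '%s' invokes missing rule '%s'", rl$id, ac$rule_id))
          eval_rule(target, chain)
        } else {
          eff <- unclass(ac)
          eff$provenance <- chain
          eff$problem_id <- rl$problem_id
          effects[[length(effects) + 1L]] <<- structure(eff, class = "cf_effect")
        }
      }
    }
    trace[[length(trace) + 1L]] <<- data.frame(
      rule_id = rl$id, truth = truth,
      effects = length(effects) - n_before, stringsAsFactors = FALSE)
    invisible(NULL)
  }

  for (rl in rules) eval_rule(rl, character(0))
  tr <- if (length(trace)) do.call(rbind, trace) else
    data.frame(rule_id = character(0), truth = character(0), effects = integer(0))
  structure(effects, trace = tr)
}

#' Line-oriented evaluation trace
#'
#' One record per rule evaluation: rule id, truth value, effects emitted.
#' `unknown` outcomes are distinguished from `false` so clinical logic is
#' auditable even when it does not fire.
#'
#' @param effects result of [fire_rules()]
#' @return character vector of trace lines
#' @export
trace_lines <- function(effects) {
  tr <- attr(effects, "trace")
  if (is.null(tr) || !nrow(tr)) return(character(0))
  sprintf("%s\t%s\t%d", tr$rule_id, tr$truth, tr$effects)
}

# static lint used at model resolution: the invoke_rule graph must be acyclic
lint_rule_cycles <- function(rules) {
  if (!length(rules)) return(invisible(TRUE))
  ids <- names(rules)
  edges <- list()
  for (rl in rules) {
    for (ac in rl$actions) {
      if (ac$kind == "invoke_rule" && ac$rule_id %in% ids)
        edges[[length(edges) + 1L]] <- c(rl$id, ac$rule_id)
    }
  }
  if (!length(edges)) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(
    as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = ids))
  if (!igraph::is_acyclic(g))
    cf_stop("RULE_CYCLE", "rule invocation graph contains a cycle")
  invisible(TRUE)
}
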