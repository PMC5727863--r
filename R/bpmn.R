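BPMN_NS <- "http://www.omg.org/spec/BPMN/20100524/MODEL"
EXT_NS  <- "urn:checkflow:bpmn-ext"

# element local names of the supported BPMN subset (plus the start/end
# events needed to delimit a process)
BPMN_SUBSET <- c("definitions", "process", "laneSet", "lane", "flowNodeRef",
                 "startEvent", "endEvent", "userTask", "sequenceFlow",
                 "conditionExpression", "parallelGateway", "exclusiveGateway",
                 "inclusiveGateway", "adHocSubProcess", "extensionElements",
                 "potentialOwner", "resourceRole", "resourceRef",
                 "documentation", "incoming", "outgoing")
EXT_SUBSET <- c("safetyGuard", "mandatory")

#' Import a BPMN 2.0 document as a clinical pathway
#'
#' Applies the concept mapping: `process` becomes the pathway, `userTask` a
#' clinical task, `sequenceFlow` an edge, `parallelGateway` a parallel
#' split/join (by degree), `exclusiveGateway`/`inclusiveGateway` a
#' conditional split/merge, `adHocSubProcess` an ad-hoc block (member tasks
#' nested inside), and `lane` a role whose `flowNodeRef`s assign tasks.
#' `conditionExpression` bodies on the outgoing flows of conditional splits
#' are parsed with the package's expression grammar (a documented dialect
#' restriction; XPath/FEEL bodies are not understood), and the gateway
#' `default` attribute names the default edge. Safety-guard bindings and
#' triggers have no BPMN counterpart; they travel in `extensionElements`
#' under the `urn:checkflow:bpmn-ext` namespace.
#'
#' @param doc XML text, a file path, or an `xml2` document
#' @param strict if `TRUE` (default), any element outside the subset raises
#'   `UNSUPPORTED_ELEMENT` naming the offending id; if `FALSE` it is skipped
#'   with a report warning
#' @return list with elements `pathway` (a [pathway()]) and `report` (a
#'   [validation_report()] from [validate_pathway()] plus importer warnings)
#' @export
import_bpmn <- function(doc, strict = TRUE) {
  if (!inherits(doc, "xml_document")) doc <- xml2::read_xml(doc)
  ns <- c(b = BPMN_NS, cf = EXT_NS)
  rc <- report_collector()

  for (el in xml2::xml_find_all(doc, "//*")) {
    nm <- xml2::xml_name(el, ns = ns)
    ok <- nm %in% BPMN_SUBSET ||
      nm %in% paste0("b:", BPMN_SUBSET) ||
      nm %in% paste0("cf:", EXT_SUBSET)
    if (!ok) {
      id <- xml2::xml_attr(el, "id")
      what <- sprintf("unsupported element <%s>%s", xml2::xml_name(el),
                      if (!is.na(id)) sprintf(" id '%s'", id) else "")
      if (strict) cf_stop("UNSUPPORTED_ELEMENT", what, id = id)
      rc$warning("UNSUPPORTED_ELEMENT", id %||% "?", paste(what, "- skipped"))
      xml2::xml_remove(el)
    }
  }

  proc <- xml2::xml_find_first(doc, ".//b:process", ns = ns)
  if (inherits(proc, "xml_missing"))
    cf_stop("SCHEMA_VIOLATION", "document contains no <process>")
  pid <- xml2::xml_attr(proc, "id") %|NA|% "pathway"

  roles <- list(); task_roles <- list()
  for (lane in xml2::xml_find_all(proc, ".//b:laneSet/b:lane", ns = ns)) {
    rid <- xml2::xml_attr(lane, "id")
    rid <- sub("^lane_", "", rid)
    roles[[rid]] <- role(rid, xml2::xml_attr(lane, "name") %|NA|% rid)
    for (ref in xml2::xml_find_all(lane, "./b:flowNodeRef", ns = ns)) {
      t <- xml2::xml_text(ref)
      task_roles[[t]] <- c(task_roles[[t]], rid)
    }
  }

  edges <- list()
  gw_conditions <- list()  # source gateway id -> named list(edge -> expr)
  for (sf in xml2::xml_find_all(proc, ".//b:sequenceFlow", ns = ns)) {
    eid <- xml2::xml_attr(sf, "id")
    edges[[eid]] <- flow(eid, xml2::xml_attr(sf, "sourceRef"),
                         xml2::xml_attr(sf, "targetRef"))
    cond <- xml2::xml_find_first(sf, "./b:conditionExpression", ns = ns)
    if (!inherits(cond, "xml_missing")) {
      src <- xml2::xml_attr(sf, "sourceRef")
      gw_conditions[[src]] <- c(gw_conditions[[src]],
                                stats::setNames(list(parse_expression(xml2::xml_text(cond))), eid))
    }
  }
  out_deg <- table(vapply(edges, `[[`, character(1), "from"))
  in_deg <- table(vapply(edges, `[[`, character(1), "to"))
  deg <- function(tab, id) if (id %in% names(tab)) as.integer(tab[[id]]) else 0L

  parse_guards <- function(task_el) {
    guards <- list()
    for (g in xml2::xml_find_all(task_el, "./b:extensionElements/cf:safetyGuard", ns = ns)) {
      kind <- xml2::xml_attr(g, "trigger")
      od <- xml2::xml_attr(g, "overdueAfter")
      rids <- xml2::xml_attr(g, "roles")
      guards[[length(guards) + 1L]] <- safety_guard(
        guard_trigger(kind, overdue_after = if (is.na(od)) NULL else as.numeric(od)),
        form_id = xml2::xml_attr(g, "form"),
        guard_role_ids = if (is.na(rids)) NULL else strsplit(rids, " ", fixed = TRUE)[[1]],
        blocking = identical(xml2::xml_attr(g, "blocking"), "true"))
    }
    guards
  }

  make_task <- function(el) {
    tid <- xml2::xml_attr(el, "id")
    rids <- unique(c(task_roles[[tid]],
                     vapply(xml2::xml_find_all(el, "./b:potentialOwner/b:resourceRef", ns = ns),
                            xml2::xml_text, character(1))))
    nd <- structure(list(id = tid, name = xml2::xml_attr(el, "name") %|NA|% tid,
                         role_ids = rids, guards = parse_guards(el)),
                    class = c("cf_task", "cf_node"))
    if (!length(rids)) rc$error("NO_ROLE", tid, "task assigned to no lane or owner")
    nd
  }

  nodes <- list()
  for (el in xml2::xml_children(proc)) {
    nm <- xml2::xml_name(el, ns = ns)
    id <- xml2::xml_attr(el, "id")
    node <- switch(nm,
      "b:startEvent" = start_event(id),
      "b:endEvent" = end_event(id),
      "b:userTask" = make_task(el),
      "b:parallelGateway" =
        gateway(id, if (deg(out_deg, id) > 1L) "parallel_split" else "parallel_join"),
      "b:exclusiveGateway" = ,
      "b:inclusiveGateway" = {
        fam <- if (nm == "b:exclusiveGateway") "exclusive" else "inclusive"
        if (deg(out_deg, id) > 1L) {
          gateway(id, paste0(fam, "_split"),
                  branch_conditions = gw_conditions[[id]] %||% list(),
                  default_edge_id = xml2::xml_attr(el, "default"))
        } else {
          gateway(id, if (fam == "exclusive") "exclusive_merge" else "inclusive_join")
        }
      },
      "b:adHocSubProcess" = {
        members <- xml2::xml_find_all(el, "./b:userTask", ns = ns)
        mids <- vapply(members, xml2::xml_attr, character(1), "id")
        mand <- xml2::xml_find_first(el, "./b:extensionElements/cf:mandatory", ns = ns)
        mand_ids <- if (inherits(mand, "xml_missing")) mids
                    else strsplit(xml2::xml_attr(mand, "tasks"), " ", fixed = TRUE)[[1]]
        for (m in members) nodes[[xml2::xml_attr(m, "id")]] <- make_task(m)
        ad_hoc_block(id, mids, mand_ids)
      },
      NULL)
    if (!is.null(node)) nodes[[node$id]] <- node
  }

  p <- pathway(pid, unname(nodes), unname(edges), roles = unname(roles),
               meta = meta_info(title = xml2::xml_attr(proc, "name") %|NA|% pid))
  rep <- validate_pathway(p)
  rep <- validation_report(errors = rbind(rc$report()$errors, rep$errors),
                           warnings = rbind(rc$report()$warnings, rep$warnings))
  list(pathway = p, report = rep)
}

`%|NA|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Export a clinical pathway as a BPMN 2.0 document
#'
#' Inverse of [import_bpmn()] on the mapped subset:
#' `import_bpmn(export_bpmn(p))` yields a pathway graph-isomorphic to `p`
#' with identical node, edge and role ids. Output is a deterministic
#' canonical serialisation (fixed attribute order, two-space indent).
#'
#' @param p a validated [pathway()]
#' @return character scalar holding the BPMN XML document
#' @export
export_bpmn <- function(p) {
  stopifnot(inherits(p, "cf_pathway"))
  a <- function(name, val) sprintf(" %s=\"%s\"", name, xml_escape(val))
  L <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
         paste0("<bpmn:definitions xmlns:bpmn=\"", BPMN_NS, "\"",
                " xmlns:cf=\"", EXT_NS, "\"",
                a("id", paste0("defs_", p$id)),
                a("targetNamespace", "urn:checkflow:models"), ">"),
         paste0("  <bpmn:process", a("id", p$id),
                a("name", p$meta$title %||% p$id),
                a("isExecutable", "true"), ">"))

  # lanes: one per role, listing the tasks (including ad-hoc members) that
  # carry the role
  if (length(p$roles)) {
    L <- c(L, paste0("    <bpmn:laneSet", a("id", paste0(p$id, "_lanes")), ">"))
    for (r in p$roles) {
      refs <- character(0)
      for (nd in p$nodes) {
        if (inherits(nd, "cf_task") && r$id %in% nd$role_ids)
          refs <- c(refs, nd$id)
      }
      L <- c(L, paste0("      <bpmn:lane", a("id", paste0("lane_", r$id)),
                       a("name", r$name), ">"),
             sprintf("        <bpmn:flowNodeRef>%s</bpmn:flowNodeRef>", refs),
             "      </bpmn:lane>")
    }
    L <- c(L, "    </bpmn:laneSet>")
  }

  guard_lines <- function(guards, indent) {
    if (!length(guards)) return(character(0))
    gl <- vapply(guards, function(gd) {
      paste0(indent, "  <cf:safetyGuard", a("form", gd$form_id),
             a("trigger", gd$trigger$kind),
             if (!is.null(gd$trigger$overdue_after))
               a("overdueAfter", format_value(gd$trigger$overdue_after)) else "",
             if (!is.null(gd$guard_role_ids))
               a("roles", paste(gd$guard_role_ids, collapse = " ")) else "",
             if (gd$blocking) a("blocking", "true") else "",
             "/>")
    }, character(1))
    c(paste0(indent, "<bpmn:extensionElements>"), gl,
      paste0(indent, "</bpmn:extensionElements>"))
  }

  task_lines <- function(nd, indent) {
    body <- c(guard_lines(nd$guards, paste0(indent, "  ")),
              unlist(lapply(nd$role_ids, function(r)
                c(paste0(indent, "  <bpmn:potentialOwner>"),
                  sprintf("%s    <bpmn:resourceRef>%s</bpmn:resourceRef>", indent, r),
                  paste0(indent, "  </bpmn:potentialOwner>")))))
    c(paste0(indent, "<bpmn:userTask", a("id", nd$id), a("name", nd$name), ">"),
      body,
      paste0(indent, "</bpmn:userTask>"))
  }

  members <- unlist(lapply(p$nodes, function(n)
    if (inherits(n, "cf_adhoc")) n$task_ids else character(0)))

  for (nd in p$nodes) {
    if (inherits(nd, "cf_start")) {
      L <- c(L, paste0("    <bpmn:startEvent", a("id", nd$id), "/>"))
    } else if (inherits(nd, "cf_end")) {
      L <- c(L, paste0("    <bpmn:endEvent", a("id", nd$id), "/>"))
    } else if (inherits(nd, "cf_task")) {
      if (nd$id %in% members) next  # serialised inside its block
      L <- c(L, task_lines(nd, "    "))
    } else if (inherits(nd, "cf_gateway")) {
      el <- switch(sub("_.*", "", nd$kind),
                   parallel = "bpmn:parallelGateway",
                   exclusive = "bpmn:exclusiveGateway",
                   inclusive = "bpmn:inclusiveGateway")
      L <- c(L, paste0("    <", el, a("id", nd$id),
                       if (!is.null(nd$default_edge_id))
                         a("default", nd$default_edge_id) else "",
                       "/>"))
    } else if (inherits(nd, "cf_adhoc")) {
      L <- c(L, paste0("    <bpmn:adHocSubProcess", a("id", nd$id), ">"),
             paste0("      <bpmn:extensionElements>"),
             paste0("        <cf:mandatory",
                    a("tasks", paste(nd$mandatory_task_ids, collapse = " ")), "/>"),
             paste0("      </bpmn:extensionElements>"))
      for (m in nd$task_ids) L <- c(L, task_lines(p$nodes[[m]], "      "))
      L <- c(L, "    </bpmn:adHocSubProcess>")
    }
  }

  # branch conditions re-attach to their sequence flows on export
  cond_for_edge <- list()
  for (nd in p$nodes) {
    if (inherits(nd, "cf_gateway") && length(nd$branch_conditions))
      for (eid in names(nd$branch_conditions))
        cond_for_edge[[eid]] <- deparse_expression(nd$branch_conditions[[eid]])
  }
  for (e in p$edges) {
    cond <- cond_for_edge[[e$id]]
    if (is.null(cond)) {
      L <- c(L, paste0("    <bpmn:sequenceFlow", a("id", e$id),
                       a("sourceRef", e$from), a("targetRef", e$to), "/>"))
    } else {
      L <- c(L, paste0("    <bpmn:sequenceFlow", a("id", e$id),
                       a("sourceRef", e$from), a("targetRef", e$to), ">"),
             paste0("      <bpmn:conditionExpression>", xml_escape(cond),
                    "</bpmn:conditionExpression>"),
             "    </bpmn:sequenceFlow>")
    }
  }
  paste(c(L, "  </bpmn:process>", "</bpmn:definitions>", ""), collapse = "\n")
}
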