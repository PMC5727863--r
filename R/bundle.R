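#' Native model bundles
#'
#' A model bundle is a directory holding `pathway.yaml`, `schema.yaml`,
#' `forms/*.yaml` and `rules/*.rules`. [load_bundle()] parses and
#' schema-checks every document (unknown keys raise `SCHEMA_VIOLATION` with
#' a pointer path) and returns a fully cross-linked model via
#' [resolve_model()]; [save_bundle()] writes a model back so that
#' `load_bundle(save_bundle(m))` is semantically identical to `m`.
#'
#' @param path bundle directory
#' @return a `cf_model`
#' @export
load_bundle <- function(path) {
  if (!dir.exists(path))
    cf_stop("SCHEMA_VIOLATION", sprintf("bundle directory '%s' not found", path))
  pw_file <- file.path(path, "pathway.yaml")
  if (!file.exists(pw_file))
    cf_stop("DANGLING_REF", "bundle has no pathway.yaml (start node unresolvable)")
  pw <- yaml::read_yaml(pw_file)
  check_keys(pw, "pathway", "/")
  p <- pathway_from_list(pw$pathway)

  schema <- field_schema(c(.none = "text"))
  sc_file <- file.path(path, "schema.yaml")
  if (file.exists(sc_file)) {
    sc <- yaml::read_yaml(sc_file)
    check_keys(sc, "fields", "/")
    schema <- field_schema(sc$fields)
  }

  forms <- list()
  for (f in sort(list.files(file.path(path, "forms"), pattern = "\\.ya?ml$",
                            full.names = TRUE))) {
    doc <- yaml::read_yaml(f)
    check_keys(doc, "form", paste0("/", basename(f)))
    fm <- form_from_list(doc$form, paste0("/", basename(f)))
    forms[[fm$id]] <- fm
  }

  rules <- list()
  for (f in sort(list.files(file.path(path, "rules"), pattern = "\\.rules$",
                            full.names = TRUE))) {
    for (rl in parse_rule_dsl(f)) {
      if (rl$id %in% names(rules))
        cf_stop("DUPLICATE_RULE_ID", sprintf("rule '%s' defined in two files", rl$id))
      rules[[rl$id]] <- rl
    }
  }
  resolve_model(p, forms = forms, rules = rules, schema = schema)
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    cf_stop("SCHEMA_VIOLATION",
            sprintf("unknown key '%s' at %s", extra[1], where),
            pointer = paste0(where, extra[1]))
  invisible(TRUE)
}

pathway_from_list <- function(pw) {
  check_keys(pw, c("id", "meta", "roles", "nodes", "edges"), "/pathway/")
  meta <- meta_from_list(pw$meta)
  roles <- lapply(pw$roles, function(r) {
    check_keys(r, c("id", "name"), "/pathway/roles/")
    role(r$id, r$name %||% r$id)
  })
  nodes <- lapply(pw$nodes, function(nd) {
    check_keys(nd, c("id", "kind", "name", "roles", "guards", "tasks",
                     "mandatory", "conditions", "default"),
               sprintf("/pathway/nodes/%s/", nd$id %||% "?"))
    kind <- nd$kind %||% "task"
    switch(kind,
      start = start_event(nd$id),
      end = end_event(nd$id),
      task = clinical_task(nd$id, nd$name %||% nd$id,
                           as.character(unlist(nd$roles)),
                           guards = lapply(nd$guards, guard_from_list)),
      ad_hoc = ad_hoc_block(nd$id, as.character(unlist(nd$tasks)),
                            if (is.null(nd$mandatory)) as.character(unlist(nd$tasks))
                            else as.character(unlist(nd$mandatory))),
      if (kind %in% GATEWAY_KINDS) {
        gateway(nd$id, kind,
                branch_conditions = lapply(nd$conditions %||% list(), identity),
                default_edge_id = nd$default)
      } else cf_stop("SCHEMA_VIOLATION",
                     sprintf("unknown node kind '%s' at /pathway/nodes/%s", kind, nd$id)))
  })
  edges <- lapply(pw$edges, function(e) {
    check_keys(e, c("id", "from", "to"), "/pathway/edges/")
    flow(e$id, e$from, e$to)
  })
  pathway(pw$id, nodes, edges, roles = roles, meta = meta)
}

meta_from_list <- function(m) {
  if (is.null(m)) return(meta_info())
  check_keys(m, c("title", "author", "version", "created"), "/meta/")
  meta_info(m$title %||% "", m$author %||% "", as.character(m$version %||% "0.1"),
            as.character(m$created %||% "1970-01-01"))
}

guard_from_list <- function(g) {
  check_keys(g, c("trigger", "form", "overdue_after", "roles", "blocking"), "/guards/")
  safety_guard(
    guard_trigger(g$trigger, overdue_after = g$overdue_after),
    form_id = g$form,
    guard_role_ids = if (is.null(g$roles)) NULL else as.character(unlist(g$roles)),
    blocking = isTRUE(g$blocking))
}

form_from_list <- function(fm, where) {
  check_keys(fm, c("id", "meta", "problems"), paste0(where, "/form/"))
  problems <- lapply(fm$problems, function(pr) {
    check_keys(pr, c("id", "description", "algorithms", "items"),
               paste0(where, "/form/problems/"))
    items <- lapply(pr$items, function(it) {
      check_keys(it, c("id", "text", "options", "guidance", "priority",
                      "pre_checked", "supplementary"),
                 paste0(where, "/items/"))
      opts <- if (isTRUE(it$guidance)) NULL
              else if (is.null(it$options)) c("yes", "no", "not_applicable")
              else yaml_options(it$options)
      checkable_item(it$id, it$text,
                     options = opts,
                     priority = it$priority %||% "normal",
                     supplementary = lapply(it$supplementary, function(sm)
                       supplementary_material(sm$kind, sm$payload)),
                     pre_checked = isTRUE(it$pre_checked))
    })
    clinical_problem(pr$id, pr$description %||% "", items,
                     algorithm_ids = as.character(unlist(pr$algorithms)))
  })
  checklist_form(fm$id, problems, meta = meta_from_list(fm$meta))
}

# YAML 1.1 reads bare yes/no as logicals; map them back to option strings
yaml_options <- function(x) {
  vapply(x, function(v) {
    if (is.logical(v)) { if (v) "yes" else "no" } else as.character(v)
  }, character(1))
}

#' @rdname load_bundle
#' @param model a `cf_model`
#' @return `save_bundle()` returns `path` invisibly
#' @export
save_bundle <- function(model, path) {
  stopifnot(inherits(model, "cf_model"))
  dir.create(file.path(path, "forms"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "rules"), recursive = TRUE, showWarnings = FALSE)
  p <- model$pathway
  node_to_list <- function(nd) {
    if (inherits(nd, "cf_start")) list(id = nd$id, kind = "start")
    else if (inherits(nd, "cf_end")) list(id = nd$id, kind = "end")
    else if (inherits(nd, "cf_task")) {
      out <- list(id = nd$id, kind = "task", name = nd$name,
                  roles = as.list(nd$role_ids))
      if (length(nd$guards)) out$guards <- lapply(nd$guards, function(gd) {
        g <- list(trigger = gd$trigger$kind, form = gd$form_id)
        if (!is.null(gd$trigger$overdue_after)) g$overdue_after <- gd$trigger$overdue_after
        if (!is.null(gd$guard_role_ids)) g$roles <- as.list(gd$guard_role_ids)
        if (gd$blocking) g$blocking <- TRUE
        g
      })
      out
    } else if (inherits(nd, "cf_adhoc")) {
      list(id = nd$id, kind = "ad_hoc", tasks = as.list(nd$task_ids),
           mandatory = as.list(nd$mandatory_task_ids))
    } else {
      out <- list(id = nd$id, kind = nd$kind)
      if (length(nd$branch_conditions))
        out$conditions <- lapply(nd$branch_conditions, deparse_expression)
      if (!is.null(nd$default_edge_id)) out$default <- nd$default_edge_id
      out
    }
  }
  pw <- list(pathway = list(
    id = p$id,
    meta = list(title = p$meta$title, author = p$meta$author,
                version = p$meta$version, created = as.character(p$meta$created)),
    roles = lapply(p$roles, function(r) list(id = r$id, name = r$name)),
    nodes = unname(lapply(p$nodes, node_to_list)),
    edges = unname(lapply(p$edges, function(e) list(id = e$id, from = e$from, to = e$to)))))
  yaml::write_yaml(pw, file.path(path, "pathway.yaml"))
  sc <- Filter(function(nm) nm != ".none", names(model$schema))
  if (length(sc))
    yaml::write_yaml(list(fields = model$schema[sc]), file.path(path, "schema.yaml"))
  for (fm in model$forms) {
    doc <- list(form = list(
      id = fm$id,
      meta = list(title = fm$meta$title, author = fm$meta$author,
                  version = fm$meta$version, created = as.character(fm$meta$created)),
      problems = unname(lapply(fm$problems, function(pr) {
        out <- list(id = pr$id, description = pr$description)
        if (length(pr$algorithm_ids)) out$algorithms <- as.list(pr$algorithm_ids)
        out$items <- lapply(pr$static_items, function(it) {
          x <- list(id = it$id, text = it$description)
          if (is.null(it$options)) x$guidance <- TRUE
          else if (!identical(it$options, c("yes", "no", "not_applicable")))
            x$options <- as.list(it$options)
          if (it$priority != "normal") x$priority <- it$priority
          if (isTRUE(it$pre_checked)) x$pre_checked <- TRUE
          if (length(it$supplementary))
            x$supplementary <- lapply(it$supplementary, function(sm)
              list(kind = sm$kind, payload = sm$payload))
          x
        })
        out
      }))))
    yaml::write_yaml(doc, file.path(path, "forms", paste0(fm$id, ".yaml")))
  }
  if (length(model$rules))
    writeLines(format_rule_dsl(model$rules),
               file.path(path, "rules", "rules.rules"))
  invisible(path)
}
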