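#' Render a checklist instance
#'
#' Three deterministic, byte-stable output formats carry the same semantic
#' flags: auto-checked items (gray class in HTML, `[x]` in text), red
#' highlighting of abnormal findings (`item--red` / `!` prefix), and the
#' high-priority mark `M` ending the item line. XML output conforms to the
#' instance schema shipped in `inst/extdata/instance-schema.md` and
#' round-trips through [parse_instance_xml()] byte-identically.
#'
#' @param instance a `cf_instance`
#' @param format one of `"text"`, `"html"`, `"xml"`
#' @return character scalar (the document)
#' @export
render_instance <- function(instance, format = c("text", "html", "xml")) {
  stopifnot(inherits(instance, "cf_instance"))
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("text", "html", "xml"))
    cf_stop("UNKNOWN_FORMAT", sprintf("unknown render format '%s'",
                                      paste(format, collapse = "/")))
  switch(format,
         text = render_text(instance),
         html = render_html(instance),
         xml = render_xml(instance))
}

items_by_problem <- function(instance) {
  split(instance$items,
        factor(vapply(instance$items, `[[`, character(1), "problem_id"),
               levels = vapply(instance$problems, `[[`, character(1), "id")))
}

item_line <- function(it) {
  box <- if (is.null(it$options)) "   " else switch(it$state,
    unchecked = "[ ]", checked = "[x]", auto_checked = "[x]",
    not_applicable = "[-]")
  prefix <- if ("highlight_red" %in% it$flags) "! " else "  "
  suffix <- if (it$priority == "high") " M" else ""
  # 80-column plain text: truncate the item text, never the flags
  width <- 80L - nchar(prefix) - nchar(box) - 1L - nchar(suffix)
  paste0(prefix, box, " ", strtrim(it$rendered_text, width), suffix)
}

render_text <- function(x) {
  out <- c(sprintf("Checklist %s (form %s) for patient %s", x$instance_id,
                   x$form_id, x$patient_id))
  by_pr <- items_by_problem(x)
  for (pr in x$problems) {
    out <- c(out, sprintf("-- %s%s", pr$id,
                          if (nzchar(pr$description)) paste0(": ", pr$description) else ""))
    for (it in by_pr[[pr$id]]) out <- c(out, item_line(it))
  }
  paste(out, collapse = "\n")
}

html_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

render_html <- function(x) {
  css <- paste(
    ".item{font-family:sans-serif;margin:2px 0}",
    ".item--auto{color:#777;background:#eee}",
    ".item--red{color:#b00020;font-weight:bold}",
    ".item--priority::after{content:' M';font-weight:bold}",
    sep = "\n")
  lines <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
             paste0("<style>", css, "</style>"), "</head><body>",
             sprintf("<h1>Checklist %s</h1>", html_escape(x$instance_id)),
             sprintf("<p>form %s — patient %s</p>", html_escape(x$form_id),
                     html_escape(x$patient_id)))
  by_pr <- items_by_problem(x)
  for (pr in x$problems) {
    lines <- c(lines, sprintf("<h2>%s</h2>", html_escape(pr$id)), "<ul>")
    for (it in by_pr[[pr$id]]) {
      cls <- c("item",
               if (it$state == "auto_checked") "item--auto",
               if ("highlight_red" %in% it$flags) "item--red",
               if (it$priority == "high") "item--priority")
      mark <- if (is.null(it$options)) "" else switch(it$state,
        unchecked = "&#9744; ", checked = "&#9745; ",
        auto_checked = "&#9745; ", not_applicable = "&#8709; ")
      lines <- c(lines, sprintf("<li class=\"%s\">%s%s</li>",
                                paste(cls, collapse = " "), mark,
                                html_escape(it$rendered_text)))
    }
    lines <- c(lines, "</ul>")
  }
  paste(c(lines, "</body></html>"), collapse = "\n")
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

# canonical writer: fixed attribute order, two-space indent, LF line ends,
# so render -> parse -> render is byte-identical
render_xml <- function(x) {
  a <- function(name, val) sprintf(" %s=\"%s\"", name, xml_escape(val))
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<checklist",
                    a("instance", x$instance_id), a("form", x$form_id),
                    a("patient", x$patient_id),
                    a("generated_at", format_value(x$generated_at)), ">"))
  by_pr <- items_by_problem(x)
  for (pr in x$problems) {
    lines <- c(lines, paste0("  <problem", a("id", pr$id),
                             a("description", pr$description), ">"))
    for (it in by_pr[[pr$id]]) {
      attrs <- paste0(
        a("id", it$item_id), a("template", it$template),
        a("state", it$state), a("flags", paste(sort(it$flags), collapse = " ")),
        a("provenance", paste(it$provenance, collapse = " ")),
        a("priority", it$priority),
        if (!is.null(it$options)) a("options", paste(it$options, collapse = ",")) else "",
        if (!is.null(it$response)) a("response", it$response) else "")
      lines <- c(lines, paste0("    <item", attrs, ">"),
                 paste0("      <text>", xml_escape(it$rendered_text), "</text>"))
      for (s in names(it$bound_values))
        lines <- c(lines, paste0("      <bind", a("slot", s),
                                 a("value", format_value(it$bound_values[[s]])), "/>"))
      for (s in it$missing_slots)
        lines <- c(lines, paste0("      <bind", a("slot", s), a("value", ""),
                                 a("missing", "true"), "/>"))
      for (sm in it$supplementary)
        lines <- c(lines, paste0("      <material", a("kind", sm$kind),
                                 a("payload", sm$payload), "/>"))
      lines <- c(lines, "    </item>")
    }
    lines <- c(lines, "  </problem>")
  }
  paste(c(lines, "</checklist>", ""), collapse = "\n")
}

#' Parse an instance XML document
#'
#' Inverse of `render_instance(x, "xml")`: reconstructs a `cf_instance`
#' such that re-rendering reproduces the input byte for byte. Check-log
#' history and the evaluation trace are not part of the interchange format.
#'
#' @param text XML document as a character scalar (or a file path)
#' @return a `cf_instance`
#' @export
parse_instance_xml <- function(text) {
  doc <- xml2::read_xml(text)
  root <- xml2::xml_find_first(doc, "/checklist")
  if (is.na(xml2::xml_name(root)) || xml2::xml_name(root) != "checklist")
    cf_stop("SCHEMA_VIOLATION", "root element must be <checklist>")
  ga <- xml2::xml_attr(root, "generated_at")
  problems <- list(); items <- list()
  for (pn in xml2::xml_find_all(root, "problem")) {
    pid <- xml2::xml_attr(pn, "id")
    problems[[pid]] <- list(id = pid, description = xml2::xml_attr(pn, "description"))
    for (itn in xml2::xml_find_all(pn, "item")) {
      flags <- xml2::xml_attr(itn, "flags")
      opts <- xml2::xml_attr(itn, "options")
      resp <- xml2::xml_attr(itn, "response")
      bound <- list(); missing <- character(0)
      for (bn in xml2::xml_find_all(itn, "bind")) {
        if (identical(xml2::xml_attr(bn, "missing"), "true")) {
          missing <- c(missing, xml2::xml_attr(bn, "slot"))
        } else {
          v <- xml2::xml_attr(bn, "value")
          num <- suppressWarnings(as.numeric(v))
          bound[[xml2::xml_attr(bn, "slot")]] <-
            if (!is.na(num) && grepl("^-?[0-9.]+$", v)) num
            else if (v %in% c("true", "false")) v == "true"
            else v
        }
      }
      mats <- lapply(xml2::xml_find_all(itn, "material"), function(mn)
        supplementary_material(xml2::xml_attr(mn, "kind"), xml2::xml_attr(mn, "payload")))
      items[[length(items) + 1L]] <- structure(list(
        item_id = xml2::xml_attr(itn, "id"),
        template = xml2::xml_attr(itn, "template"),
        rendered_text = xml2::xml_text(xml2::xml_find_first(itn, "text")),
        state = xml2::xml_attr(itn, "state"),
        flags = if (nzchar(flags)) strsplit(flags, " ", fixed = TRUE)[[1]] else character(0),
        bound_values = bound, missing_slots = missing,
        options = if (is.na(opts)) NULL else strsplit(opts, ",", fixed = TRUE)[[1]],
        priority = xml2::xml_attr(itn, "priority"),
        supplementary = mats,
        response = if (is.na(resp)) NULL else resp,
        provenance = strsplit(xml2::xml_attr(itn, "provenance"), " ", fixed = TRUE)[[1]],
        problem_id = pid), class = "cf_item_instance")
    }
  }
  structure(list(instance_id = xml2::xml_attr(root, "instance"),
                 form_id = xml2::xml_attr(root, "form"),
                 patient_id = xml2::xml_attr(root, "patient"),
                 generated_at = as.numeric(ga),
                 items = items, n_effects = NA_integer_,
                 problems = unname(problems), trace = character(0),
                 check_log = new_check_log()),
            class = "cf_instance")
}
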