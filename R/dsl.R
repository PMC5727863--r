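#' The WHEN/THEN rule language
#'
#' Clinical rules are edited as plain text, one statement per rule:
#'
#' ```
#' RULE <id> [FOR <problem_id>] WHEN <condition> THEN <action> [AND <action>]*
#' ```
#'
#' The condition uses the expression grammar of [parse_expression()].
#' Actions are:
#'
#' * `add_item "template text"` — appends a patient-specific item; the new
#'   item's id is `<rule_id>_item` (`_item2`, `_item3`, ... for further
#'   `add_item`s in the same rule), and `{field}` slots in the template bind
#'   patient data
#' * `highlight <item_id> red`
#' * `pre_check <item_id>`
#' * `set_priority <item_id> high|normal`
#' * `attach_material <item_id> patient_data <field>` or
#'   `attach_material <item_id> literature "citation"`
#' * `invoke_rule <rule_id>` — nests another rule as this rule's action
#'
#' Lines starting with `#` are comments; statements may span lines. Strings
#' use double quotes with backslash escapes.
#'
#' @param text DSL source (character scalar, possibly multi-line) or a file
#'   path ending in `.rules`
#' @return list of [rule()] objects, named by rule id
#' @export
parse_rule_dsl <- function(text) {
  if (length(text) == 1L && grepl("\\.rules$", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  if (!nzchar(trimws(text)))
    cf_stop("PARSE_ERROR", "empty rule file", line = 1L, col = 1L)
  toks <- dsl_tokenize(text)
  rules <- list()
  i <- 1L
  while (i <= length(toks) && toks[[i]]$type != "eof") {
    res <- parse_rule_statement(toks, i)
    if (res$rule$id %in% names(rules))
      cf_stop("DUPLICATE_RULE_ID",
              sprintf("rule id '%s' redefined (line %d)", res$rule$id, toks[[i]]$line))
    rules[[res$rule$id]] <- res$rule
    i <- res$next_i
  }
  rules
}

# line/column-tracking tokenizer shared by statements and embedded
# expressions (expressions are re-parsed from their source slice)
dsl_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*#", line)) next
    i <- 1L; n <- nchar(line)
    while (i <= n) {
      ch <- substr(line, i, i)
      if (grepl("^\\s$", ch)) { i <- i + 1L; next }
      rest <- substr(line, i, n)
      if (ch == "\"") {
        m <- regmatches(rest, regexpr('^"(\\\\.|[^"\\\\])*"', rest))
        if (!length(m))
          cf_stop("PARSE_ERROR", sprintf("unterminated string (line %d, col %d)", ln, i),
                  line = ln, col = i)
        toks[[length(toks) + 1L]] <- list(type = "string", text = dsl_unquote(m),
                                          line = ln, col = i)
        i <- i + nchar(m); next
      }
      m <- regmatches(rest, regexpr("^(<=|>=|==|!=|<|>|\\(|\\))", rest))
      if (length(m) && nzchar(m)) {
        toks[[length(toks) + 1L]] <- list(type = "op", text = m, line = ln, col = i)
        i <- i + nchar(m); next
      }
      m <- regmatches(rest, regexpr("^-?[0-9]+(\\.[0-9]+)?", rest))
      if (length(m) && nzchar(m)) {
        toks[[length(toks) + 1L]] <- list(type = "number", text = m, line = ln, col = i)
        i <- i + nchar(m); next
      }
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_.-]*", rest))
      if (length(m) && nzchar(m)) {
        type <- if (m %in% c("RULE", "WHEN", "THEN", "FOR", "AND")) m else "word"
        toks[[length(toks) + 1L]] <- list(type = type, text = m, line = ln, col = i)
        i <- i + nchar(m); next
      }
      cf_stop("PARSE_ERROR",
              sprintf("unexpected character '%s' (line %d, col %d)", ch, ln, i),
              line = ln, col = i)
    }
  }
  toks[[length(toks) + 1L]] <- list(type = "eof", text = "",
                                    line = length(lines) + 1L, col = 1L)
  toks
}

dsl_unquote <- function(q) {
  s <- substr(q, 2L, nchar(q) - 1L)
  s <- gsub("\\\\\"", "\"", s)
  s <- gsub("\\\\n", "\n", s)
  s <- gsub("\\\\t", "\t", s)
  gsub("\\\\\\\\", "\\\\", s)
}

dsl_quote <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  paste0("\"", gsub("\"", "\\\\\"", s), "\"")
}

tok_err <- function(tk, what) {
  cf_stop("PARSE_ERROR",
          sprintf("%s (line %d, col %d, near '%s')", what, tk$line, tk$col, tk$text),
          line = tk$line, col = tk$col)
}

parse_rule_statement <- function(toks, i) {
  tk <- toks[[i]]
  if (tk$type != "RULE") tok_err(tk, "expected RULE")
  i <- i + 1L
  idt <- toks[[i]]
  if (idt$type != "word" || !is_valid_id(idt$text)) tok_err(idt, "expected rule id")
  rule_id <- idt$text; i <- i + 1L
  problem_id <- NULL
  if (toks[[i]]$type == "FOR") {
    i <- i + 1L
    pt <- toks[[i]]
    if (pt$type != "word") tok_err(pt, "expected problem id after FOR")
    problem_id <- pt$text; i <- i + 1L
  }
  if (toks[[i]]$type != "WHEN") tok_err(toks[[i]], "expected WHEN")
  i <- i + 1L
  # collect the condition's tokens up to THEN and re-serialise them for the
  # expression parser
  cond_parts <- character(0)
  cond_start <- toks[[i]]
  while (!toks[[i]]$type %in% c("THEN", "eof", "RULE")) {
    tk <- toks[[i]]
    cond_parts <- c(cond_parts,
                    if (tk$type == "string") dsl_quote(tk$text) else tk$text)
    i <- i + 1L
  }
  if (toks[[i]]$type != "THEN")
    tok_err(toks[[if (i > 1) i - 1L else i]], "statement missing THEN after the WHEN clause")
  if (!length(cond_parts)) tok_err(cond_start, "empty WHEN condition")
  condition <- tryCatch(parse_expression(paste(cond_parts, collapse = " ")),
                        checkflow_PARSE_ERROR = function(e)
                          cf_stop("PARSE_ERROR",
                                  sprintf("bad condition in rule '%s' (line %d): %s",
                                          rule_id, cond_start$line, conditionMessage(e)),
                                  line = cond_start$line, col = cond_start$col))
  i <- i + 1L
  actions <- list()
  n_added <- 0L
  repeat {
    res <- parse_action(toks, i, rule_id, n_added)
    actions[[length(actions) + 1L]] <- res$action
    n_added <- res$n_added
    i <- res$next_i
    if (toks[[i]]$type == "AND") { i <- i + 1L; next }
    break
  }
  list(rule = rule(rule_id, condition, actions, problem_id = problem_id), next_i = i)
}

parse_action <- function(toks, i, rule_id, n_added) {
  tk <- toks[[i]]
  if (tk$type != "word") tok_err(tk, "expected an action keyword")
  kind <- tk$text; i <- i + 1L
  need <- function(type, what) {
    t <- toks[[i]]
    if (t$type != type) tok_err(t, what)
    i <<- i + 1L
    t$text
  }
  action <- switch(kind,
    add_item = {
      txt <- need("string", "add_item requires a quoted item template")
      n_added <- n_added + 1L
      item_id <- if (n_added == 1L) paste0(rule_id, "_item")
                 else sprintf("%s_item%d", rule_id, n_added)
      action_add_item(checkable_item(item_id, txt, source = paste0("rule:", rule_id)))
    },
    highlight = {
      id <- need("word", "highlight requires an item id")
      color <- need("word", "highlight requires a colour")
      if (color != "red") tok_err(toks[[i - 1L]], "only 'red' highlighting is supported")
      action_highlight(id, color)
    },
    pre_check = action_pre_check(need("word", "pre_check requires an item id")),
    set_priority = {
      id <- need("word", "set_priority requires an item id")
      lvl <- need("word", "set_priority requires a level (high|normal)")
      if (!lvl %in% c("high", "normal"))
        tok_err(toks[[i - 1L]], "priority level must be high or normal")
      action_set_priority(id, lvl)
    },
    attach_material = {
      id <- need("word", "attach_material requires an item id")
      mk <- need("word", "attach_material requires a kind (patient_data|literature)")
      if (mk == "patient_data") {
        action_attach_material(id, supplementary_material("patient_data",
          need("word", "patient_data requires a field name")))
      } else if (mk == "literature") {
        action_attach_material(id, supplementary_material("literature",
          need("string", "literature requires a quoted citation")))
      } else tok_err(toks[[i - 1L]], "material kind must be patient_data or literature")
    },
    invoke_rule = action_invoke_rule(need("word", "invoke_rule requires a rule id")),
    tok_err(tk, sprintf("unknown action '%s'", kind)))
  list(action = action, next_i = i, n_added = n_added)
}

#' Serialise rules back to DSL text
#'
#' Inverse of [parse_rule_dsl()] up to whitespace; reparsing yields
#' semantically identical rules.
#'
#' @param rules list of [rule()] objects
#' @return character scalar of DSL source
#' @export
format_rule_dsl <- function(rules) {
  fmt_action <- function(ac) switch(ac$kind,
    add_item = paste("add_item", dsl_quote(ac$item$description)),
    highlight = paste("highlight", ac$item_id, ac$color),
    pre_check = paste("pre_check", ac$item_id),
    set_priority = paste("set_priority", ac$item_id, ac$level),
    attach_material = paste("attach_material", ac$item_id, ac$material$kind,
                            if (ac$material$kind == "literature")
                              dsl_quote(ac$material$payload) else ac$material$payload),
    invoke_rule = paste("invoke_rule", ac$rule_id))
  stmts <- vapply(rules, function(rl) {
    sprintf("RULE %s%s WHEN %s THEN %s", rl$id,
            if (!is.null(rl$problem_id)) paste(" FOR", rl$problem_id) else "",
            deparse_expression(rl$condition),
            paste(vapply(rl$actions, fmt_action, character(1)), collapse = " AND "))
  }, character(1))
  paste(stmts, collapse = "\n")
}
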