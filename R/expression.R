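#' Condition expressions over patient context
#'
#' Rules and conditional care flows share one small expression language:
#' field references, literals (number, quoted text, boolean, ISO dates as
#' quoted text), the comparisons `< <= > >= == !=`, the connectives
#' `AND OR NOT`, the presence test `EXISTS field`, and parentheses. There is
#' deliberately no arithmetic: every decision exercised by peri-operative
#' checklists is a threshold or boolean test, and keeping the language total
#' keeps its missing-data semantics easy to audit.
#'
#' Evaluation is three-valued (Kleene): a comparison touching a field absent
#' from the patient context yields `"unknown"`, and `unknown` propagates
#' through the connectives (`TRUE AND unknown = unknown`,
#' `TRUE OR unknown = TRUE`, ...). `EXISTS` never yields `"unknown"`. A rule
#' only fires on `"true"`, so missing data can never assert a
#' patient-specific finding.
#'
#' @param text expression source text
#' @return `parse_expression()` returns an AST of class `cf_expr`.
#' @examples
#' e <- parse_expression("lvef < 50")
#' eval_expression(e, patient_context("p1", list(lvef = 36)))  # "true"
#' eval_expression(e, patient_context("p1", list()))           # "unknown"
#' @export
parse_expression <- function(text) {
  toks <- expr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$src <- text
  e <- parse_or(st)
  tk <- peek_tok(st)
  if (tk$type != "eof") {
    cf_stop("PARSE_ERROR", sprintf("unexpected '%s' at column %d in expression", tk$text, tk$col),
            line = 1L, col = tk$col)
  }
  class(e) <- c("cf_expr", class(e))
  e
}

# --- tokenizer -------------------------------------------------------------

expr_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- list()
  i <- 1L; n <- nchar(text)
  push <- function(type, txt, col) toks[[length(toks) + 1L]] <<- list(type = type, text = txt, col = col)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    rest <- substr(text, i, n)
    if (grepl("^(<=|>=|==|!=|<|>)", rest)) {
      op <- regmatches(rest, regexpr("^(<=|>=|==|!=|<|>)", rest))
      push("op", op, i); i <- i + nchar(op); next
    }
    if (ch == "(") { push("lparen", ch, i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ch, i); i <- i + 1L; next }
    if (ch == "\"") {
      j <- i + 1L; out <- character(0)
      repeat {
        if (j > n) cf_stop("PARSE_ERROR", sprintf("unterminated string at column %d", i),
                           line = 1L, col = i)
        cj <- substr(text, j, j)
        if (cj == "\\") {
          nxt <- substr(text, j + 1L, j + 1L)
          out <- c(out, switch(nxt, n = "\n", t = "\t", "\"" = "\"", "\\" = "\\", nxt))
          j <- j + 2L; next
        }
        if (cj == "\"") break
        out <- c(out, cj); j <- j + 1L
      }
      push("string", paste0(out, collapse = ""), i); i <- j + 1L; next
    }
    m <- regmatches(rest, regexpr("^-?[0-9]+(\\.[0-9]+)?", rest))
    if (length(m) && nzchar(m)) { push("number", m, i); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_.-]*", rest))
    if (length(m) && nzchar(m)) {
      up <- toupper(m)
      type <- if (up %in% c("AND", "OR", "NOT", "EXISTS")) tolower(up)
              else if (up %in% c("TRUE", "FALSE")) "boolean"
              else "ident"
      push(type, m, i); i <- i + nchar(m); next
    }
    cf_stop("PARSE_ERROR", sprintf("unexpected character '%s' at column %d", ch, i),
            line = 1L, col = i)
  }
  push("eof", "", n + 1L)
  toks
}

peek_tok <- function(st) st$toks[[st$pos]]
next_tok <- function(st) { t <- st$toks[[st$pos]]; st$pos <- st$pos + 1L; t }
expect_tok <- function(st, type) {
  t <- next_tok(st)
  if (t$type != type)
    cf_stop("PARSE_ERROR",
            sprintf("expected %s but found '%s' at column %d", type, t$text, t$col),
            line = 1L, col = t$col)
  t
}

# --- recursive descent -----------------------------------------------------

parse_or <- function(st) {
  lhs <- parse_and(st)
  while (peek_tok(st)$type == "or") {
    next_tok(st)
    lhs <- list(type = "or", lhs = lhs, rhs = parse_and(st))
  }
  lhs
}

parse_and <- function(st) {
  lhs <- parse_not(st)
  while (peek_tok(st)$type == "and") {
    next_tok(st)
    lhs <- list(type = "and", lhs = lhs, rhs = parse_not(st))
  }
  lhs
}

parse_not <- function(st) {
  if (peek_tok(st)$type == "not") {
    next_tok(st)
    return(list(type = "not", arg = parse_not(st)))
  }
  parse_primary(st)
}

parse_primary <- function(st) {
  tk <- peek_tok(st)
  if (tk$type == "lparen") {
    next_tok(st)
    e <- parse_or(st)
    expect_tok(st, "rparen")
    return(maybe_comparison(st, e))
  }
  if (tk$type == "exists") {
    next_tok(st)
    f <- expect_tok(st, "ident")
    return(list(type = "exists", field = f$text))
  }
  maybe_comparison(st, parse_operand(st))
}

parse_operand <- function(st) {
  tk <- next_tok(st)
  switch(tk$type,
    ident = list(type = "field", name = tk$text),
    number = list(type = "lit", kind = "number", value = as.numeric(tk$text)),
    string = list(type = "lit", kind = "text", value = tk$text),
    boolean = list(type = "lit", kind = "boolean", value = toupper(tk$text) == "TRUE"),
    cf_stop("PARSE_ERROR",
            sprintf("expected a field or literal but found '%s' at column %d",
                    tk$text, tk$col),
            line = 1L, col = tk$col))
}

maybe_comparison <- function(st, lhs) {
  force(lhs)  # lhs consumes tokens; force before peeking
  if (peek_tok(st)$type != "op") return(lhs)
  op <- next_tok(st)$text
  rhs <- parse_operand(st)
  list(type = "cmp", op = op, lhs = lhs, rhs = rhs)
}

# --- field inventory and canonical text ------------------------------------

#' Fields referenced by an expression
#' @param expr a `cf_expr` AST
#' @return character vector of field names
#' @export
expression_fields <- function(expr) {
  if (is.null(expr)) return(character(0))
  switch(expr$type,
    field = expr$name,
    exists = expr$field,
    lit = character(0),
    cmp = unique(c(expression_fields(expr$lhs), expression_fields(expr$rhs))),
    not = expression_fields(expr$arg),
    unique(c(expression_fields(expr$lhs), expression_fields(expr$rhs))))
}

#' Canonical source text of an expression AST
#'
#' `parse_expression(deparse_expression(e))` is structurally identical to
#' `e`; used when serialising models.
#' @param expr a `cf_expr` AST
#' @return character scalar
#' @export
deparse_expression <- function(expr) {
  dep <- function(e) switch(e$type,
    field = e$name,
    exists = paste("EXISTS", e$field),
    lit = switch(e$kind,
      number = format(e$value, scientific = FALSE, trim = TRUE),
      boolean = if (e$value) "true" else "false",
      text = paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", e$value)), "\"")),
    cmp = sprintf("%s %s %s", dep(e$lhs), e$op, dep(e$rhs)),
    not = sprintf("NOT (%s)", dep(e$arg)),
    and = sprintf("(%s AND %s)", dep(e$lhs), dep(e$rhs)),
    or = sprintf("(%s OR %s)", dep(e$lhs), dep(e$rhs)))
  dep(expr)
}

# ---------------------------------------------------------------------------
# Patient context

#' Patient context record
#'
#' The flat field-to-value mapping rules evaluate against, typically sourced
#' from an EMR extract; here authored directly or produced by
#' [generate_patients()]. Values are numbers, logicals or strings; a field
#' that is absent (or `NA`) is *missing* and comparisons touching it
#' evaluate to `"unknown"`.
#'
#' @param patient_id identifier
#' @param values named list of field values
#' @param observed_at optional named list of per-field timestamps
#' @return an object of class `cf_context`
#' @export
patient_context <- function(patient_id, values = list(), observed_at = NULL) {
  assert_id(patient_id, "patient id")
  stopifnot(is.list(values))
  if (length(values)) stopifnot(!is.null(names(values)), all(nzchar(names(values))),
                                !anyDuplicated(names(values)))
  structure(list(patient_id = patient_id, values = values,
                 observed_at = observed_at),
            class = "cf_context")
}

context_value <- function(ctx, field) {
  v <- ctx$values[[field]]
  if (is.null(v) || (length(v) == 1L && is.na(v))) NULL else v
}

value_kind <- function(v) {
  if (is.numeric(v)) "number"
  else if (is.logical(v)) "boolean"
  else if (is.character(v)) "text"
  else NA_character_
}

# ---------------------------------------------------------------------------
# Evaluation

#' Evaluate an expression against a patient context
#'
#' @param expr a `cf_expr` AST from [parse_expression()] (character input is
#'   parsed on the fly)
#' @param ctx a [patient_context()]
#' @param schema optional [field_schema()]; when given, runtime values whose
#'   type contradicts the declared field type raise `TYPE_MISMATCH`
#' @return one of `"true"`, `"false"`, `"unknown"`
#' @export
eval_expression <- function(expr, ctx, schema = NULL) {
  if (is.character(expr)) expr <- parse_expression(expr)
  tv <- eval3(expr, ctx, schema)
  if (is.na(tv)) "unknown" else if (tv) "true" else "false"
}

# internal: logical with NA as unknown; R's &, |, ! are already Kleene
eval3 <- function(e, ctx, schema) {
  switch(e$type,
    and = eval3(e$lhs, ctx, schema) & eval3(e$rhs, ctx, schema),
    or  = eval3(e$lhs, ctx, schema) | eval3(e$rhs, ctx, schema),
    not = !eval3(e$arg, ctx, schema),
    exists = !is.null(context_value(ctx, e$field)),
    cmp = eval_cmp(e, ctx, schema),
    field = {
      v <- fetch_typed(ctx, e$name, schema)
      if (is.null(v)) NA
      else if (is.logical(v)) v
      else cf_stop("TYPE_MISMATCH",
                   sprintf("field '%s' used as a bare condition must be boolean", e$name))
    },
    lit = {
      if (e$kind != "boolean")
        cf_stop("TYPE_MISMATCH", "non-boolean literal used as a condition")
      e$value
    })
}

fetch_typed <- function(ctx, field, schema) {
  v <- context_value(ctx, field)
  if (is.null(v)) return(NULL)
  if (!is.null(schema) && !is.null(schema[[field]])) {
    declared <- schema[[field]]
    got <- value_kind(v)
    ok <- switch(declared,
      number = got == "number",
      boolean = got == "boolean",
      text = got == "text",
      date = got == "text")
    if (!isTRUE(ok))
      cf_stop("TYPE_MISMATCH",
              sprintf("field '%s' declared %s but holds a %s value", field, declared, got))
  }
  v
}

eval_cmp <- function(e, ctx, schema) {
  side <- function(s) {
    if (s$type == "field") fetch_typed(ctx, s$name, schema)
    else if (s$type == "lit") s$value
    else cf_stop("TYPE_MISMATCH", "comparison operand must be a field or literal")
  }
  l <- side(e$lhs); r <- side(e$rhs)
  if (is.null(l) || is.null(r)) return(NA)
  lk <- value_kind(l); rk <- value_kind(r)
  if (is.na(lk) || is.na(rk) || lk != rk)
    cf_stop("TYPE_MISMATCH",
            sprintf("cannot compare %s with %s", lk %||% "?", rk %||% "?"))
  if (lk == "boolean" && !e$op %in% c("==", "!="))
    cf_stop("TYPE_MISMATCH", "booleans only support == and !=")
  res <- switch(e$op,
    "<"  = l <  r, "<=" = l <= r,
    ">"  = l >  r, ">=" = l >= r,
    "==" = l == r, "!=" = l != r)
  as.logical(res)
}
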