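#' Classed error conditions
#'
#' All errors raised by checkflow carry a machine-readable `code` (for
#' example `RULE_CYCLE` or `DANGLING_REF`) and signal a condition of classes
#' `checkflow_<code>`, `checkflow_error`, `error`.
#'
#' @param code short upper-case error code
#' @param message human-readable message
#' @param ... further fields stored on the condition object
#' @keywords internal
#' @noRd
cf_stop <- function(code, message, ...) {
  cond <- structure(
    class = c(paste0("checkflow_", code), "checkflow_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, message), call = sys.call(-1),
         code = code, ...)
  )
  stop(cond)
}

#' Extract the error code from a checkflow condition
#' @param cond a condition object
#' @return character scalar or `NA`
#' @export
error_code <- function(cond) {
  if (!is.null(cond$code)) cond$code else NA_character_
}

# identifier discipline shared by every model document: XML-id and
# file-name safe, case-sensitive
is_valid_id <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl("^[A-Za-z0-9_.-]+$", x)
}

assert_id <- function(x, what = "identifier") {
  if (!is_valid_id(x)) {
    cf_stop("BAD_ID", sprintf("%s must match [A-Za-z0-9_.-]+, got %s",
                              what, deparse(substitute(x))))
  }
  x
}
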