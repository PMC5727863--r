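#' Synthetic patient cohorts
#'
#' Stands in for EMR extracts: each field is drawn independently per patient
#' from its declared distribution, then masked at the field's missingness
#' rate. Boolean fields are Bernoulli at the given prevalence; numeric
#' fields are uniform or (bound-truncated) normal. Generation is
#' deterministic given the profile's seed and leaves the caller's RNG state
#' untouched.
#'
#' @param n number of patients (>= 0)
#' @param seed integer seed
#' @param field_specs named list: each element is a list with `type`
#'   (`"number"` or `"boolean"`) plus, for numbers, `dist`
#'   (`"uniform"`/`"normal"`), `min`/`max` (uniform, and truncation bounds
#'   for normal) or `mean`/`sd` (normal); for booleans, `prevalence` in
#'   \[0,1\]; optionally `missing` in \[0,1\] (default 0)
#' @return an object of class `cf_cohort_profile`
#' @export
cohort_profile <- function(n, seed, field_specs) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0,
            is.numeric(seed), length(seed) == 1L,
            is.list(field_specs), !is.null(names(field_specs)))
  for (nm in names(field_specs)) {
    fs <- field_specs[[nm]]
    stopifnot(fs$type %in% c("number", "boolean"))
    if (fs$type == "boolean")
      stopifnot(fs$prevalence >= 0, fs$prevalence <= 1)
    miss <- fs$missing %||% 0
    stopifnot(miss >= 0, miss <= 1)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 field_specs = field_specs),
            class = "cf_cohort_profile")
}

#' @rdname cohort_profile
#' @param profile a `cf_cohort_profile`
#' @return `generate_patients()` returns a list of [patient_context()]
#'   records of length `n`
#' @export
generate_patients <- function(profile) {
  stopifnot(inherits(profile, "cf_cohort_profile"))
  if (profile$n == 0L) return(list())
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(profile$seed)
  out <- vector("list", profile$n)
  width <- nchar(as.character(profile$n))
  for (i in seq_len(profile$n)) {
    values <- list()
    for (nm in names(profile$field_specs)) {
      fs <- profile$field_specs[[nm]]
      if (stats::runif(1) < (fs$missing %||% 0)) next
      values[[nm]] <- if (fs$type == "boolean") {
        stats::runif(1) < fs$prevalence
      } else if ((fs$dist %||% "uniform") == "uniform") {
        stats::runif(1, fs$min, fs$max)
      } else {
        v <- stats::rnorm(1, fs$mean, fs$sd)
        if (!is.null(fs$min)) v <- max(v, fs$min)
        if (!is.null(fs$max)) v <- min(v, fs$max)
        v
      }
    }
    out[[i]] <- patient_context(sprintf("p%0*d", width, i), values)
  }
  out
}

# default cohort profile for the bundled PCI model's schema; prevalences are
# plausible for an elective PCI population
pci_cohort_profile <- function(n, seed) {
  cohort_profile(n, seed, list(
    lvef = list(type = "number", dist = "normal", mean = 55, sd = 10,
                min = 10, max = 80, missing = 0.05),
    creatinine = list(type = "number", dist = "normal", mean = 90, sd = 25,
                      min = 40, max = 400),
    renal_insufficiency = list(type = "boolean", prevalence = 0.15),
    complication = list(type = "boolean", prevalence = 0.1),
    age = list(type = "number", dist = "normal", mean = 66, sd = 10,
               min = 30, max = 95)))
}

cabg_cohort_profile <- function(n, seed) {
  cohort_profile(n, seed, list(
    age = list(type = "number", dist = "normal", mean = 67, sd = 9,
               min = 35, max = 92),
    high_risk = list(type = "boolean", prevalence = 0.3),
    diabetes = list(type = "boolean", prevalence = 0.35, missing = 0.02)))
}
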