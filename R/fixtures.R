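#' Bundled worked models
#'
#' Two peri-operative care models ship with the package as native bundles
#' under `extdata/` (with matching BPMN exports):
#'
#' * `cabg_fixture()` — a coronary-artery-bypass-graft peri-operative
#'   pathway with 19 clinical tasks across 9 roles, exercising parallel and
#'   exclusive gateways, an ad-hoc recovery block, and one checklist guard
#'   per role lane. Task names and topology are authored for this package;
#'   only the task and role counts follow the published care process.
#' * `pci_fixture()` — a percutaneous-coronary-intervention pathway whose
#'   pre-operative checklist carries the left-ventricular-ejection-fraction
#'   (LVEF) alert rule (fires iff LVEF < 50, adding a red-flagged,
#'   high-priority item that binds the measured value) and a
#'   renal-insufficiency rule adding the item "Renal insufficiency noticed"
#'   and pre-checking the hydration-protocol item through a nested rule.
#'
#' @return a resolved `cf_model`
#' @export
cabg_fixture <- function() {
  load_bundle(system.file("extdata", "cabg", package = "checkflow", mustWork = TRUE))
}

#' @rdname cabg_fixture
#' @export
pci_fixture <- function() {
  load_bundle(system.file("extdata", "pci", package = "checkflow", mustWork = TRUE))
}

#' Worked-example patient for the PCI model
#'
#' A synthetic patient whose measured LVEF of 36 lies below the alert
#' threshold of 50, so instantiating the PCI pre-operative checklist yields
#' one rule-generated alert item flagged red.
#'
#' @return a [patient_context()]
#' @export
pci_example_patient <- function() {
  patient_context("example_patient", list(
    lvef = 36, creatinine = 88, renal_insufficiency = FALSE,
    complication = FALSE, age = 61))
}
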