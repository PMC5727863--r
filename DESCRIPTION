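Package: checkflow
Title: Dynamic Clinical Safety Checklists over Executable Care Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An executable engine for dynamic, patient-context-aware clinical
    safety checklists. Declarative models of clinical pathways, checklist
    forms and situation-action rules are validated for referential and
    structural integrity, executed per patient case through a token-based
    workflow engine supporting sequential, parallel, conditional and ad-hoc
    care flows, and rendered as patient-specific checklist instances with
    rule-driven item generation, highlighting and pre-checking. Includes an
    importer and exporter for a BPMN 2.0 subset, a plain-text WHEN/THEN rule
    language, bundled coronary-artery-bypass-graft (CABG) and
    percutaneous-coronary-intervention (PCI) pathway models, and a seedable
    synthetic patient-cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
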