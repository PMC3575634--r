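Package: femfit
Title: Virtual Fitting of Proximal Femoral Intramedullary Nails
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Virtual implant-fitting pipeline for cephalomedullary nails in
    the proximal femur. Builds parametric triangulated models of nail designs
    (PFNA-II-like, InterTan-like, generic), generates seeded cohorts of
    landmarked synthetic endosteal femur models with configurable anterior
    bow, neck-shaft angle and canal calibre, places each nail according to
    manufacturer-rule constraints (entry at the greater-trochanter vertex,
    head element through the femoral head centre), quantifies geometric
    fitness (impingement thickness, length and location, tip protrusion,
    mid-shaft anterior gap) from signed nail-to-cortex penetration fields,
    and compares nail designs over paired cohorts with incidence and paired
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
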