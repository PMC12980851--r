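Package: healthkg
Title: Schema-Driven Construction of Validated, De-Identified Patient Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Transforms heterogeneous per-patient health records (JSON or
    tabular/CSV) into validated, de-identified RDF knowledge graphs with one
    named graph per patient. From a single RDF schema document it derives the
    data-facing artifacts (a JSON Schema, CSV/SQL-DDL ingestion templates, and
    SHACL shapes), mints collision-free IRIs under a four-part naming
    convention, applies replayable de-identification (field pseudonymization,
    per-patient date shifting, list/regex substitution), validates the
    generated quads against the shapes and loaded terminologies, and manages a
    file-based store of named graphs with patient-level atomicity, delta loads
    and consent revocation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
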