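Package: ccemap
Title: Topographic Severity Mapping for Colon Capsule Endoscopy in Ulcerative Colitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated pipeline for grading ulcerative colitis severity from
    colon capsule endoscopy still pictures. Stills are tiled into overlapping
    128x128 patches at a 32-pixel stride over the optical field of view,
    uninterpretable patches are excluded by exact intensity rules, each patch
    is assigned one of six categories (Mayo endoscopic subscore 0-3,
    inadequate quality, ileal mucosa), per-still severity is expressed as
    percent-area fractions of per-class pixel unions, and serial profiles are
    assembled into a topographic severity map along four colorectal segments.
    Includes a training harness for the patch classifier, an oracle classifier
    and synthetic-still generator for end-to-end verification without patient
    data, and confusion-matrix evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
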