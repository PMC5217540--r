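Package: readsmoke
Title: Life-Course Smoking Status from Coded Primary-Care Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assigns a patient's smoking status (never, ex, relapsed, likely
    or current smoker) at any census date from longitudinal Read-coded
    general-practice records, resolving temporal conflicts such as
    never-smoker codes recorded after evidence of smoking. Includes two
    comparison variants (no temporal checking; nearest status code),
    GP-versus-survey agreement analysis via contingency tables and Cohen's
    kappa with large-sample confidence intervals, annual smoking-prevalence
    estimation, and a seeded synthetic cohort generator emulating
    initiation/quit/relapse trajectories, sporadic GP recording and survey
    misreport, so the whole pipeline is testable without access to protected
    health data.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, yaml, e1071, jsonlite
Encoding: UTF-8
Config/testthat/edition: 3
RoxygenNote: 7.3.3
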