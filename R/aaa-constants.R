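# Shared vocabularies (loaded first).

BASE_CATEGORIES <- c("NEVER", "EX", "SMOKER")
CODE_KINDS <- c("status", "intensity", "therapy", "cessation_admin",
                "advice", "parent")
INTENSITY_CLASSES <- c("trivial", "light", "medium", "heavy", "very_heavy")
UNINFORMATIVE <- "UNINFORMATIVE"
STATUS_EXCLUDED_KINDS <- c("therapy", "cessation_admin", "advice")

SMOKING_STATUSES <- c("NO_INFORMATION", "UNKNOWN_SMOKING_STATUS",
                      "NEVER_SMOKER", "EX_SMOKER", "RELAPSED_SMOKER",
                      "LIKELY_SMOKER", "SMOKER")
COLLAPSED_STATUSES <- c("MISSING", "SMOKER", "EX_SMOKER", "NEVER_SMOKER")
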