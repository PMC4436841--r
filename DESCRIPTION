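Package: theatreplan
Title: Surgical Pathway Durations and Waiting-List Driven Operating
    Theatre Block Scheduling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for elective operating-theatre planning under block
    booking.  A parameterised surgical-pathway model converts each
    patient's anesthesia type, risk profile and expected operating time
    into a precise operating-room occupation time.  A 0-1 optimisation
    model then assigns waiting-list patients, prioritised by Urgency
    Related Group and costed in Need Adjusted Waiting Days, to
    specialty-labelled OR blocks of a Master Surgical Schedule over a
    three-phase rolling horizon with penalties for disturbing earlier
    plans.  Includes a synthetic case-mix generator, a first-come
    first-served baseline, utilisation reporting and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
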