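Package: iedose
Title: Immunologically Effective Dose for Radiotherapy Schedules
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the intrinsic immunogenicity of radiotherapy dosing
    schedules with the Immunologically Effective Dose (IED) model, alongside
    the classic linear-quadratic metrics BED and EQD2. A schedule is an
    ordered list of (time, dose) irradiation events; the model convolves
    linear-quadratic cell kill with antigen-release and immune-activation
    kinetics (time scales T_D and T_IR) to obtain the fraction of tumour
    volume converted into immunogenic antigens (IED efficacy) and the
    equivalent single low-dose-rate dose (IED). Includes schedule builders
    (uniform, weekday, hybrid split/bifractionated courses), a compact
    schedule grammar with CSV/JSON readers and writers, interfraction-time
    sweeps, multi-schedule comparison tables, constrained schedule search,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
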