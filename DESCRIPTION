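Package: pvloopr
Title: Non-Invasive Left Ventricular Pressure-Volume Loop Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and analysis of left-ventricular pressure-volume
    loops without catheterization. An individualized LV pressure waveform is
    estimated by scaling a generic normalized reference curve to brachial
    cuff pressures, the mean transaortic gradient, and measured valvular
    event times; combined with an echocardiographic volume-time trace it
    yields stroke work, single-beat end-systolic elastance (V0 = 0),
    arterial elastance, ventriculo-arterial coupling, potential energy,
    pressure-volume area, and ventricular efficiency. Also computes the
    pressure-strain myocardial work index family (GWI, GCW, GWW, GWE),
    method-agreement statistics (Pearson, ICC, ordinary least squares,
    Bland-Altman), and ships a time-varying-elastance beat simulator with
    aortic-stenosis gradients for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
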