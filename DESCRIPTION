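Package: afvtrial
Title: Virtual Antiarrhythmic Drug Trials in Genotype-Aware Atrial Fibrillation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates atrial electrophysiology for in-silico antiarrhythmic drug
    (AAD) screening in atrial fibrillation (AF). Implements the
    Courtemanche-Ramirez-Nattel human atrial myocyte model with conductance
    scaling for genotype (wild-type vs PITX2+/- deficiency), rhythm-state
    remodeling (sinus rhythm vs AF) and class IC / class III drug block; a
    monodomain reaction-diffusion tissue solver on synthetic fibrotic substrates
    built by inverse-distance-weighted voltage interpolation; wave-dynamics
    analysis (APD90, conduction velocity, restitution slope Smax, AF cycle
    length, dominant frequency, phase singularities, AF termination); and
    ensemble trial statistics (Student and paired t tests, Cohen's d,
    termination-rate tables).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
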