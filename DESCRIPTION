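Package: hepatobase
Title: Non-Invasive Baseline Assessment of Liver Function, Perfusion and
    Attenuation in the Healthy Rat
Version: 0.1.0
Authors@R:
    person("Hepatobase", "Developers", email = "maintainer@hepatobase.org",
           role = c("aut", "cre"))
Description: Tools to establish non-invasive baseline (reference) values for
    hepatic assessment in healthy laboratory rats. Implements indocyanine
    green (ICG) plasma-clearance kinetics under a one-compartment elimination
    model (clearance percentages, semilog elimination constant ICG-K, and the
    per-minute decay rate R), Doppler waveform feature extraction and derived
    hemodynamic indices (PSV, EDV, VTI, TAV, resistive index, portal
    congestion index, arterio-portal ratio, cardiac output, renal blood
    flow), Hounsfield-unit threshold segmentation and volume-of-interest
    attenuation statistics on micro-CT volumes, and reference-interval
    aggregation with published-interval flagging. Seeded synthetic generators
    (exponential ICG decay, pulsatile velocity traces, voxelized liver
    phantoms) stand in for animal data so the whole pipeline is testable
    without new experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
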