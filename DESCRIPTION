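Package: doxtherm
Title: Coupled Bioheat and Pharmacokinetic Simulation of Heat-Mediated
    Doxorubicin Delivery to Solid Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of combined thermal and chemotherapeutic
    treatment of a vascularized solid tumor. Solves steady interstitial fluid
    pressure and velocity (Darcy flow with Starling sources), the Pennes
    bioheat equation with magnetic-nanoparticle and focused-ultrasound heat
    sources, CEM43 thermal dose with ablation-zone and perfusion-damage
    classification, multi-compartment pharmacokinetics of free, protein-bound
    and thermosensitive-liposome-encapsulated doxorubicin with
    temperature-triggered intravascular release, convection-diffusion-reaction
    transport in the interstitium, and saturable cell-kill pharmacodynamics.
    Five treatment protocols (classical chemotherapy, thermochemotherapy,
    thermosensitive-liposome therapy, and ablation combined with medication in
    either order) can be run and compared on a one-dimensional spherical tumor
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
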