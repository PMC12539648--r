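Package: aortagnr
Title: Equilibrated Constrained-Mixture Growth and Remodelling of the Aneurysmal Aorta
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanobiologically equilibrated constrained-mixture growth-and-remodelling
    (G&R) simulation of aneurysmal progression in the murine Marfan ascending aorta.
    Models the vessel wall as an elastin / smooth-muscle / four-fibre-family collagen
    mixture (neo-Hookean plus Fung exponential), maps elastin porosity to structural and
    cell-mediated insults (diminished elastic-fibre integrity, dysfunctional
    mechanosensing, dysfunctional mechanoregulation), solves the evolved equilibrated
    vessel state on a uniform thick-walled-ring reduction, and evaluates diastolic
    geometric and mechanical metrics (stored energy, small-on-large stiffness,
    distensibility, diameter, thickness). Includes a derivative-free surrogate management
    framework optimizer (Latin hypercube design, kriging SEARCH, mesh-adaptive POLL) that
    recovers insult parameters from porosity-metric observations, and a synthetic-data
    generator emulating two Marfan genotype groups for end-to-end recovery studies.
License: MIT
Encoding: UTF-8
Imports: stats, utils, lhs, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
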