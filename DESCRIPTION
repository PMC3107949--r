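Package: pedmech
Title: Quasi-Static Rigid-Body Simulation of Flatfoot Deformity and Its
    Surgical Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A parametric rigid-body model of the loaded human foot and ankle
    for studying Stage II adult acquired flatfoot deformity and its corrective
    osteotomies. Bones are rigid bodies tied together by tension-only ligament
    springs (with via-point wrapping) and unilateral penalty contacts; quasi-
    static mid-stance equilibrium under tibial axial load and Achilles tension
    is found by energy minimisation. The package generates synthetic foot
    anatomy, applies a staged ligament-attenuation scheme for flatfoot, models
    three virtual procedures (medializing calcaneal osteotomy, Evans lateral
    column lengthening, calcaneocuboid distraction arthrodesis), and measures
    the standard radiographic alignment angles, ligament strains,
    calcaneocuboid joint contact force, and plantar ground load distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
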