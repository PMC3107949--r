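# pedmech

Quasi-static rigid-body simulation of Stage II adult acquired flatfoot
deformity and its surgical correction.

## The problem

Stage II flatfoot is a flexible collapse of the medial foot arch driven by
posterior tibial tendon dysfunction and attenuation of the medial
soft-tissue restraints (spring ligament complex, plantar fascia, deltoid
portions). Surgeons correct the alignment with a medializing calcaneal
osteotomy (MCO), an Evans anterior-calcaneal opening wedge, or a
calcaneocuboid distraction arthrodesis (CCDA), alone or combined with an
MCO. Each procedure redistributes tension and load through the foot in
ways that are hard to observe clinically — raised calcaneocuboid joint
load after lateral column lengthening is a suspected precursor of
arthritis, and lateral forefoot overload of lateral column pain.

`pedmech` is a computational laboratory for these questions, for
biomechanics researchers and methodologically inclined foot and ankle
surgeons. It simulates a foot standing at mid-stance and reports the
measures a clinician would ask for: radiographic alignment angles,
ligament strains, joint contact force, and plantar load distribution,
across seven standard configurations (normal, flatfoot, and flatfoot
treated with MCO, Evans, CCDA, Evans+MCO, CCDA+MCO).

## The model

Eleven rigid bone units (tibia+fibula, talus, calcaneus, navicular,
cuboid, merged cuneiforms, five rays) interact through

* unilateral articular contacts (penalty springs on facet points, with
  ball-socket points for congruent, deeply bound joints; the subtalar
  joint is an oblique hinge about an Inman-type hindfoot axis),
* 132 tension-only ligament springs `T = k · max(0, L − L0)`, several
  routed over via-point beads that act as pulleys (the spring-ligament
  hammock under the talar head, the plantar fascia windlass, the long
  plantar ligament's cuboid wrap), and
* mid-stance loads: 690 N axially down the tibia and a 345 N Achilles
  tension modeled as a constant-tension cable.

Equilibrium minimises the total potential

```
E(q) = Σ ½ k max(0, L(q) − L0)²  +  Σ (κ/2) δ(q)²  +  ROM stops  −  W_loads(q)
```

over 61 generalized coordinates (the proximal tibia is restrained to
vertical translation), by L-BFGS with analytic gradients and load
ramping. Flatfoot multiplies affected ligament stiffnesses by
(1 − stage fraction) with stages 0/I/II/IV removing 0, 1/8, 3/8, 7/8;
surgery is a rigid transform of a landmark-defined fragment (MCO: 10 mm
medial translation of the tuberosity; Evans/CCDA: internal rotation by
`atan(10/25) = 21.8°` about the medial border of the cut, CCDA also
fusing the calcaneocuboid joint).

Anatomy is synthetic and parametric — a neutrally aligned right-foot
template with seeded landmark jitter — because the cadaver CT behind the
original study is not available. Absolute outputs are anatomy-specific;
the model's content is the *direction and proportion* of changes across
configurations, plus exact reproduction of the published attenuation
scheme and of the derived arithmetic on the published tables (bundled
as reference fixtures under `inst/extdata/`).

See the methods vignette (`vignettes/foot-model-methods.Rmd`) for the
full formulation, conventions, parameter defaults and limitations.

## Worked example

```r
library(pedmech)

suite <- run_suite(default_suite(
  seed = 1,
  solver = solver_options(tolerance = 1, ramp_steps = 5)))
round(suite$table[c("angle_L_T1MT", "angle_AP_TN", "angle_hindfoot",
                    "calcaneocuboid_force", "load_ray5"),
                  c("normal", "flatfoot", "MCO", "Evans")], 1)
```

```
                     normal flatfoot   MCO  Evans
angle_L_T1MT           -7.2    -14.8 -12.3   -6.8
angle_AP_TN           -12.2     -4.4  -2.7   -8.9
angle_hindfoot         96.9    100.7  96.5  100.4
calcaneocuboid_force  564.1   1061.2 966.2 2654.2
load_ray5              54.3     72.9 139.0   91.6
```

Reading the columns: attenuating the flatfoot ligaments drops the
lateral talo–first-metatarsal angle by 7.6° (arch collapse) and everts
the hindfoot by 3.8° of valgus; the MCO corrects the hindfoot back to
the normal level (100.7° → 96.5°) while nearly doubling fifth-ray load;
the Evans procedure raises calcaneocuboid joint force to about 2.5 × the
flatfoot level — the model's echo of the clinical concern about
post-Evans calcaneocuboid arthritis. (Exact values vary by a degree or
so with the anatomy seed and solver schedule.)

Single scenarios, skeleton generation and file I/O are available as
plain functions (`run_scenario()`, `build_skeleton()`,
`skeleton_to_json()`, `export_skeleton_meshes()`), and a thin CLI wraps
them:

```sh
Rscript inst/cli/pedmech.R generate --seed 1 --out anat/ --mesh
Rscript inst/cli/pedmech.R run --config config.yaml --out results/
Rscript inst/cli/pedmech.R compare --results results/
```

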