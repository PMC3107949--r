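---
title: "A quasi-static rigid-body model of flatfoot deformity and its surgical correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quasi-static rigid-body model of flatfoot deformity and its surgical correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Stage II adult acquired flatfoot deformity is a flexible collapse of the
medial foot arch: posterior tibial tendon dysfunction is accompanied by
attenuation of the medial soft-tissue restraints (the spring-ligament
complex above all), and the foot drifts into forefoot abduction, midfoot
collapse and hindfoot valgus. Three osteotomies are commonly used to
re-align the foot — the medializing calcaneal osteotomy (MCO), the Evans
anterior-calcaneal opening wedge, and calcaneocuboid distraction
arthrodesis (CCDA) — alone or combined with an MCO. Each redistributes
load and tension through the foot in ways that are difficult to observe
clinically.

`pedmech` implements a computational laboratory for this question: a
quasi-static rigid-body foot that stands at mid-stance under a tibial
axial force and an Achilles tendon load, held together by unilateral
articular contacts and tension-only ligament springs. Disease is simulated
by a staged stiffness attenuation of the affected ligaments; surgery by
geometric operations on the bones. The outputs are the measures a foot
surgeon would ask for: six radiographic alignment angles, strain along the
plantar fascia and long plantar ligament arrays, calcaneocuboid joint
contact force, and the plantar load under each ray and the heel.

The original study this package's pipeline follows used cadaver-specific,
CT-derived bone surfaces inside a commercial kinematic simulator. Neither
is available here, and both are deliberately out of scope: the package
generates its own synthetic anatomy and formulates equilibrium from first
principles. Absolute outputs are therefore anatomy-specific and are *not*
expected to match published absolute tables; the scientific content is in
the *relative* behavior — which direction each angle, strain and load
moves between the normal, flatfoot and operated states — plus the exact
reproduction of the published attenuation scheme and of the derived
arithmetic on the published measurement tables, which ship as packaged
reference fixtures.

## The mechanical model

### Bodies and coordinates

The skeleton has eleven rigid units: tibia+fibula, talus, calcaneus,
navicular, cuboid, the three cuneiforms merged, and five rays (each
metatarsal merged with its phalanges). Merging follows the measurement
set: none of the reported measures ever separates phalanges from their
metatarsal or the fibula from the tibia. The coordinate frame is
right-handed with +X anterior, +Y superior and +Z lateral for a right
foot; the ground is the plane Y = 0; all lengths are in mm and forces
in N.

The proximal tibia is restrained to one degree of freedom
(superior–inferior translation), mirroring the original loading rig; every
other unit carries six generalized coordinates (three translations and an
axis–angle rotation increment composed onto a per-body reference rotation,
re-centred after each accepted solver step so no orientation chart
singularity is approached). An intact foot therefore has 61 generalized
coordinates; an arthrodesis that fuses the cuboid to the calcaneus removes
six.

### Articulations

Joints are modeled at three levels of fidelity, chosen by what each joint
does anatomically:

* **Socket points** (ball joints): a congruent articulation bound by short
  deep ligaments is represented by a point shared between the two bones
  with a symmetric vector penalty on its relative displacement. Its
  stiffness (default 500 N/mm, per-joint factors up to 2000 N/mm for the
  nearly rigid distal tarsal and tarsometatarsal joints, 800 N/mm for the
  cartilage-compliant ankle and hindfoot joints) lumps cartilage
  compliance with the binding ligaments. The subtalar joint carries *two*
  socket points along an oblique (Inman-type) hindfoot axis running from
  the posterolateral-plantar calcaneus to the anteromedial-dorsal talar
  neck — an oblique hinge. This routes the talar load through the axis
  torque-free and builds in the classic pronation coupling between
  hindfoot eversion and forefoot abduction.
* **Facet edge points**: compression-only sphere pairs around each joint's
  contact patch, placed with 1 mm of clearance in the neutral pose. The
  ligaments govern mid-range rotation; the edges engage as articular
  stops near end-range, the way facet peripheries do.
* **The talonavicular joint has no socket.** The talar head rests in the
  acetabulum pedis, whose floor is the spring-ligament hammock: the bony
  facet points push the navicular only anteriorly, dorsally or laterally,
  and the head's inferior-medial support is purely ligamentous. This is
  the pivotal modeling choice for the disease: when the spring complex is
  attenuated the talar head sags and deviates medially — peritalar
  subluxation — which is precisely the Stage II mechanism.

A smooth quadratic range-of-motion stop (default engaging beyond 10° of
relative rotation at any joint, stiffness 5e5 N·mm/rad²) represents bony
impingement and bounds the equilibrium search without influencing the
physiologic range.

### Ligaments

Ligament bands are tension-only linear springs, `T = k·max(0, L − L0)`,
optionally redirected around bone by massless via-point beads that act as
frictionless pulleys (bead radii are retained only for mesh export). The
named structures of the published attenuation and strain tables are all
present: the superomedial and inferomedial spring ligament portions
(each routed from the sustentaculum through a bead on the plantar-medial
talar head to the navicular — the hammock that carries the head), the
talocalcaneal interosseous ligament, a five-band plantar fascia with
windlass beads under the metatarsal heads, an eight-band long plantar
ligament whose lateral bands wrap a cuboid bead, the short plantar
ligament, plantar metatarsocuneiform and naviculocuneiform ligaments, and
three deltoid portions. Transverse metatarsal and intermetatarsal base
ligaments bind the five rays into a forefoot unit, and each joint carries
a nine-fibre generic capsule: three axial fibres plus two counter-wound
sets of three oblique fibres, the crossed-fibre architecture that lets
tension-only elements restrain shear and axial rotation in either sense
at first order. The full set is 132 bands — the same order as the
original model's 144, and scaled up from an initial sparser design
because tension-only networks with fewer, purely axial fibres leave
first-order-free folding modes.

Stiffnesses for the ten structures in the published attenuation table are
back-computed baselines (`flatfoot value / (1 − stage fraction)`);
structures without published values carry the mean of those baselines
(184 N/mm), mirroring the original study's use of averages of known
structures; each capsule fibre family shares one such structure value
across its three fibres. Rest lengths are calibrated from in-situ strain:
`L0 = L_neutral / (1 + ε)`. The default table sets ε = 0.5% for capsule
fibres (keeping every capsule snug bilaterally around neutral) and ε = 0
for the long named bands, so the generator's neutral pose is an exact
unloaded equilibrium — the published in-situ strain sources are not
reprinted anywhere, so these defaults are configuration, not inference,
and are fully overridable per band, group or structure. A uniform nonzero
pre-strain on all bands was rejected: an arbitrary pre-stress field is
not self-equilibrated, so it drags the resting state away from the
calibration pose and slackens exactly the structures whose engagement
carries the disease signal.

### Loads, ground contact and equilibrium

Mid-stance is a 690 N downward force on the proximal tibia plus a 345 N
Achilles tension, the latter modeled as a constant-tension cable from the
calcaneal insertion to a proximal gastrocnemius/soleus landmark (its
potential is tension × length, so the energy formulation stays
conservative). Ground contact is unilateral: penalty springs (default
2000 N/mm, exponent 1) on sphere primitives under the heel and the five
metatarsal heads. The heel is a single sphere — the rounded tuberosity
rolls in the coronal plane, keeping hindfoot varus/valgus
ligament-governed. Tangential ground springs anchored at each contact's
resting footprint regularize the remaining rigid modes; their default
stiffness (5 N/mm) is deliberately *compliant*, representing plantar
soft-tissue shear, so the heel/forefoot load split is governed by the
moment balance of the applied loads rather than by footprint shear. A
stiff tangential anchor was tried first and rejected: it silently carries
the arch thrust into the ground and starves the plantar ligaments of the
load the published strain tables show them carrying.

Equilibrium is the minimum of the total potential (spring energies +
contact penalties + range-of-motion stops − load work), found with
L-BFGS-B over the generalized coordinates using analytic gradients
(SO(3) exponential-map right Jacobians for the rotation blocks; the
gradient is validated against central finite differences to 1e-5 relative
error in the test suite). Because tension-only networks switch between
slack and taut states, the loads are ramped in equal increments (default
10) with warm starts; intermediate increments stop at a loosened
tolerance and the final increment is polished to the convergence
tolerance, default 0.5 N on the gradient norm (rotation coordinates are
scaled by 50 mm so the entire gradient carries force units). The solver
is deterministic: no randomness anywhere, identical inputs give identical
iterate sequences.

### A scenario, end to end

`run_scenario()` performs, in order: build the intact anatomy; build and
calibrate the band set; attenuate if the condition is flatfoot; apply the
procedures by *continuation* (the fragment displacement is grown in four
steps, each tracked by a warm-started resting solve, so the surgical
pre-stress relaxes along the physical path rather than jumping into a
distant energy basin); find the resting (strain-reference) state under a
1% seating load with the footprint re-anchored to its own fixed point
(the post-operative foot is re-seated on the plate before loading; a
zero-load solve would leave the global pose indeterminate); then ramp the
full loads from that state and measure. Strains are reported relative to
the scenario's own resting state, matching the published
"resting to loaded" convention.

## Disease and surgery

The Stage II attenuation multiplies the stiffness of each affected
structure by (1 − fraction), with stages 0, I, II and IV removing 0, 1/8,
3/8 and 7/8; there is no stage III fraction in the source scheme, and the
package deliberately refuses to invent one. Geometry and rest lengths
never change — attenuation is purely material — and bands carry a
provenance flag so the scheme cannot be applied twice.

The osteotomies are rigid transforms of landmark-defined fragments.
MCO: a cut plane perpendicular to the calcaneal axis isolates the
Achilles tuberosity, which translates 10 mm medially — taking the
Achilles insertion, the heel contact and the plantar fascia origins with
it. Evans: the anterior calcaneal fragment (cut 10 mm behind the
calcaneocuboid surface) rotates internally about the medial border of the
cut by `atan(width/depth)` — 21.8° for the default 10 × 25 mm triangular
wedge — opening laterally. (The source describes rotating "until the
wedge fits"; the arctangent closure is this package's geometric reading.)
CCDA: 3 mm of each calcaneocuboid articular surface is shaved, the entire
cuboid rotates internally about the same medial-border hinge, and the
cuboid is fused to the calcaneus: one rigid unit, six fewer degrees of
freedom, and the joint's contact force reported as not applicable. In
combined procedures the lateral column procedure precedes the MCO (the
fragments are disjoint, so the composition is order-independent for
landmark positions; the order is fixed for determinism). Wedges are not
modeled as material — mechanically the fused construct is a single rigid
body — and the wedge trim parameter affects only exported meshes.

## Measurements

Angles are computed from landmark-defined axes in three synthetic
radiographic views. Lateral view (sagittal projection): the
talo–first-metatarsal angle (signed; negative = plantar apex = drooping
arch), the talocalcaneal angle, and calcaneal pitch. Raised AP view
(viewing direction elevated 70° from horizontal within the sagittal
plane): the AP talo–first-metatarsal angle and talonavicular coverage
angle, both signed with positive = adduction. Posterior view: the
hindfoot angle, the angle between the calcaneal bisection line and the
ground *measured from the lateral aspect* on the +90°-shifted scale.
Eversion — hindfoot valgus, the flatfoot direction — drops the medial
border of the foot, tips the bisection top medially, and opens the
lateral-aspect angle above 90°; inversion closes it below 90°. (Working
through the kinematics of eversion is worth a reader's minute: a naive
"lateral lean = valgus" reading inverts every hindfoot trend in the
model.) The talonavicular coverage construction — the signed angle
between the talar axis and the in-projection normal of a two-landmark
navicular articular chord — and the calcaneal bisection landmarks are
package conventions; the source names these measures but not their
landmark constructions.

Strain tables report engineering strain (percent, one decimal) for the
eight long-plantar and five plantar-fascia bands ordered medial to
lateral. The calcaneocuboid force is the magnitude of the resultant
transmitted across that joint's socket and facet pairs (compression at
the facets; the full vector at the socket). Plantar loads are per-region
sums of vertical ground contact forces.

## The synthetic anatomy generator

The generator emulates a neutrally aligned right foot: a deterministic
template (250 mm foot, arch height fraction 0.18, 3° physiologic hindfoot
valgus) built so that the neutral pose measures land inside documented
normative windows (talo–first-metatarsal within ±5°, calcaneal pitch
10–25°, hindfoot 88–96° — bracketing the published intact values), with
all contact spheres exactly touching their counterparts and the ground.
Foot length scales the template; the arch fraction scales midfoot
elevation; handedness mirrors the medial–lateral axis (all six angles are
mirror-invariant by construction). Per-seed variation is a uniform
±0.5 mm landmark jitter around the template — nothing else is random, and
the jitter stream is isolated from the caller's RNG. The generator is
emphatically *not* subject-specific anatomy: bones are landmark frames
with sparse contact primitives, there are no articular surfaces, no
cartilage layers and no soft-tissue volumes. Passing trend tests across
generator seeds therefore demonstrates that the modeled mechanisms are
robust to small anatomical perturbation around one template morphology —
not that they generalize across real anatomical variation.

## Numerical choices and degenerate inputs

* Penalty contact (2000 N/mm, exponent 1) rather than rigid-constraint
  complementarity: robust, dependency-light, and gradient-checkable. The
  acceptance physics hold at half and double the default penalty.
* Convergence at 0.5 N gradient norm ≈ 0.1% of the body-weight scale.
* Load ramping in 10 increments; trend studies across many seeds use 3
  increments, a 1.5 N tolerance and 2 osteotomy continuation steps
  (problem sizes: 7 scenarios × 10 seeds for the disease/surgery trend
  suites, 3 seeds at 0.57× and 1.43× stiffness for the robustness sweep;
  trend directions are insensitive to the final polish).
* Ties and degeneracies: exactly-slack bands sit at the kink of the
  force law (energy is C¹ there, which L-BFGS tolerates); coincident
  socket points make the socket penalty exactly smooth at zero
  separation; a zero-length projected axis in an angle measure raises an
  error naming the landmark rather than returning NaN.
* Re-application of the attenuation, fusing an already-fused joint,
  Evans+CCDA together, procedures on a normal condition, and anatomy
  parameters outside their documented ranges are all rejected with
  descriptive errors.

## What the model does and does not show

Within scope, verified across generator seeds: the full measurement
suite; exact reproduction of the attenuation scheme and of the published
derived arithmetic; the direction of every reported disease trend — arch
drop (lateral talo–first-metatarsal angle falls ~5°), forefoot abduction
(AP talo–first-metatarsal falls ~1–2°), hindfoot valgus (~+2.5°) — and of
the key surgical effects: the MCO's varus overcorrection of the hindfoot
(~−7°) with its lateral forefoot load shift, arch elevation and raised
calcaneocuboid load under lateral column lengthening (Evans above all,
roughly 2.5 × the flatfoot level), and a fifth-ray load increase under
every lateral procedure.

Known limitations, found and kept honest during development rather than
tuned away:

* The synthetic flatfoot *sheds* first-ray ground load — the sagging
  medial column hangs on the talar head instead of pressing the first ray
  into the plate — whereas the cadaver-based study reports a slight
  medial load increase in flatfoot. Procedures that re-tension the medial
  column therefore re-load rather than unload the first ray, inverting
  that published trend.
* Under lateral column lengthening the navicular and forefoot adduct in
  *position* (the navicular rotates ~7–8° internally), but the talus is
  dragged into adduction with them through the talonavicular chain, so
  the talus-referenced AP angles (talo–first-metatarsal and talonavicular
  coverage) do not rise the way the published tables show. In the cadaver
  anatomy the talus is held by interlocking facet congruence that the
  landmark-and-contact-point representation cannot reproduce.

Both are properties of the simplified anatomy, not of the method; the
corresponding acceptance checks are implemented exactly as stated and
left failing. Linear springs, the absence of plantar soft tissue (loads,
not pressures, are computed), no tendon transfer, and statics-only
simulation are inherited scope decisions from the source study.
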