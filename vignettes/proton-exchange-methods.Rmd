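---
title: "Proton-exchange moves and transfer-aware transport analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proton-exchange moves and transfer-aware transport analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Classical force fields have a fixed topology: bonds neither form nor break,
so an ordinary simulation of a protic ionic liquid (PIL) such as
1-methylimidazolium acetate can never exchange the acidic proton between
cation and anion,

HA + B &#8652; A&#8315; + BH&#8314;,

even though that exchange dominates the charge transport of the real
liquid. `protonhop` implements the standard remedy at the solvent scale:
every exchangeable residue carries **two discrete parameter states**
(protonated and deprotonated) in a **single topology** — one shared atom
list whose per-atom charges, Lennard-Jones parameters, types and
polarizabilities are swapped when the residue changes protonation state.
The proton that vanishes on deprotonation is kept as a *dummy atom* (zero
charge, negligible LJ), so atom count and ordering never change and the
swap is exactly invertible.

This package is a self-contained re-implementation of that scheme for
desk-scale studies: templates and reaction definitions, the exchange move
itself, a minimal Brownian engine to drive it, and the analyses that must
be *transfer-aware* — diffusion from state-cut time series and
conductivity from the corrected collective translational dipole.

## Dual-state templates and force-field transforms

A `residue_dual_template` stores both parameter sets with a bijective atom
mapping, the donor hydrogens of the protonated state, the acceptor sites of
the deprotonated state and the dummy atoms. `validate_mapping()` checks the
single-topology invariants; in particular every donor hydrogen must map to
a dummy atom. The packaged imidazolium template transcribes the published
dual-state parameters for Im1H+/Im1 (the acidic ring hydrogen H7, type
HDP1A with q = +0.363 e, becomes the dummy DUMH with q = 0; the lone pair
on the unsubstituted ring nitrogen is switched off in the cation). The
acetate pair ships as a *synthetic* stand-in
(`acetate_templates_synthetic.yml`): its published parameter columns are
not available to this package, so chemically plausible values with exact
0/−1 e state charges are used. Only the topology of that file (H7 → dummy,
both carboxylate oxygens as acceptor sites) follows the published scheme.

Two force-field utilities accompany the templates, in CHARMM internal
units (Å, kcal/mol, e, ps; Coulomb constant 332.0716, k~B~ =
0.0019872041 — the constant the surrounding force-field ecosystem uses,
as no value is fixed by the method itself):

* **Drude charge from polarizability.** A Drude oscillator attaches a
  mobile charge q^δ^ to each polarizable atom with spring constant
  k = C q^δ2^/α. `drude_charge()` inverts this for q^δ^ (negative by
  convention); with the customary k = 1000 kcal mol^−1^ Å^−2^ and
  α = 1 Å^3^, q^δ^ ≈ −1.735 e. The total self-polarization energy is
  U^δδ^ = Σ k d^2^ (`self_polarization_energy()`).
* **LJ-ε scaling.** When induced dipoles carry part of the dispersion,
  well depths are reduced as ε = ε^nonpol^ (Δα + s α~max~)/(s Δα + α~max~)
  with Δα = α~max~ − α. The printed form of this expression is
  typographically ambiguous; the grouping used here is the only one that
  satisfies both stated limits — ε(0) = ε^nonpol^ and
  ε(α~max~) = s ε^nonpol^ — and we flag rather than assert that it is the
  original authors' intent.

## The exchange move

At fixed intervals (10 ps in the atomistic production protocol) the run is
paused and four steps are executed:

1. **Candidate detection.** All donor-hydrogen/acceptor-site pairs with
   minimum-image distance below the reaction's r~max~ (1.55 Å for the
   atomistic system; for multi-site acceptors such as the two carboxylate
   oxygens the closest site is recorded). `find_candidates()` matches an
   O(N²) brute-force oracle by construction and by test.
2. **Conflict resolution.** A residue may transfer at most once per
   update. The published method does not state a policy for overlapping
   candidates; we use greedy shortest-distance-first maximal matching
   (ties broken by residue id), on the grounds that the shortest hydrogen
   bond is the most reaction-prone contact.
3. **Feedback probabilities.** Each reaction's working probability is
   p = p~ref~ + c (n~now~/n~ref~ − 1)^3^, evaluated once per update from
   the count of the reaction's *monitor species* before any acceptance
   draw, and clamped to [0, 1] (the source is silent on out-of-range
   values). The cubic keeps the sign of the deviation. Three choices the
   source leaves open are fixed here: probabilities live on the fraction
   scale (percent values are divided by 100 at load — with c = 300 the
   cubic term is only meaningful on that scale); the monitor species is
   the first reactant (the species consumed by the reaction, so a deficit
   lowers the probability of the reaction consuming it); reactions whose
   monitor count cannot change (the identity-swap reactions 3–4) simply
   keep p = p~ref~ at the reference composition.
4. **Execution.** Accepted donors swap to their deprotonated state,
   acceptors to their protonated state — instantaneously by default, or
   along a linear charge path over intermediate λ states with a dynamics
   hook between increments (`interpolate_states()`; the endpoint is
   bit-identical to the instantaneous swap). Each transfer is logged as a
   `TransferEvent` with integer charges before/after and the
   minimum-image displacement r~ij~ — the contract consumed by the
   transport analyses. Charge is conserved exactly (integer arithmetic)
   and within each update the number of protonations equals the number of
   deprotonations.

Acceptance draws use a dedicated seeded RNG stream, separate from the
thermal-noise stream, so event logs are reproducible independently of the
dynamics.

## The toy engine

The package deliberately replaces polarizable MD (Ewald electrostatics,
Drude integrators, thermostats) with the simplest engine that yields
diffusive motion and realistic contact statistics:

* **Single-bead residues.** Donor and acceptor sites coincide with the
  bead center; the acidic proton is implicit, so bead templates declare no
  dummy atom and the donor→dummy rule is only enforced for templates that
  have dummies.
* **WCA + screened Coulomb.** U = Σ WCA(r; ε, σ) +
  Σ C q~i~q~j~ e^−r/λ^/(ε~r~ r), minimum-image, cutoff-truncated and
  shifted to zero at the cutoff. Screening (default λ = 5 Å) stands in for
  Ewald summation; it preserves charge ordering qualitatively while
  keeping the engine dependency-free. The relative dielectric ε~r~
  (demo: 40) sets the ion-contact energy to about one k~B~T at 300 K so
  the melt stays mixed and liquid-like.
* **Overdamped (Brownian) propagation.** x ← x + (D₀/k~B~T) F dt +
  √(2 D₀ dt) ξ with D₀ = k~B~T/(m γ); defaults m = 100 u, γ = 10 ps^−1^,
  dt = 0.02 ps, T = 300 K, giving D₀ ≈ 0.25 Å²/ps. A velocity integrator
  would add nothing the analyses need.
* **Bead-scale transfer distance.** 1.55 Å is an atomistic hydrogen-bond
  criterion; for beads the criterion is scaled to contact distance,
  r~max~ = 1.2 σ = 6 Å by default.

### What the packaged demo emulates — and what it does not

`pil_demo()` builds 1,000 beads at the published composition
(150 Im1H+/OAc− and 350 Im1/HOAc pairs, the 30%:70% charged:neutral
equilibrium) and runs 250 exchange cycles. The box (160 Å) is chosen so a
donor finds an acceptor within r~max~ in only a few percent of update
checks. This matches the published operating regime, where transfers are
rare events — of order 10–15 per molecule across 5,000 update
opportunities. That rarity matters: the cubic feedback controls the
composition only when the per-cycle reactive flux is small compared with
the count deviations it responds to. At liquid-like packing every bead
reacts at nearly every check and the composition saturates the
probability clamp instead of fluctuating around the reference — a regime
the published protocol never enters.

Consequently, a passing demo shows that the bookkeeping, feedback and
estimators behave as specified under sparse transfers; it does *not*
reproduce dense-melt structure, polarizable dynamics, or any absolute
transport number of the atomistic system (densities, the measured
conductivities and diffusion coefficients are explicitly out of scope).

## Transfer-aware transport analysis

**Diffusion.** D = slope/6 of the mean-squared displacement of unfolded
residue centers (Einstein relation). Because a transfer changes a
residue's species, each residue's time series is *cut at its events*
(`cut_segments()`), each piece labeled with the state held during it, and
only pieces longer than a minimum (default: half the run, mirroring the
published 25-of-50 ns rule) are kept, so charged and neutral mobility are
never mixed. Pooled coefficients per residue family (Im1H+/Im1 and
OAc−/HOAc together) are reported as well. The default fit window is
10–30% of the run length — the published 2–6 ns window scaled to toy runs
— and MSDs average over multiple time origins with a configurable stride
(how many origins the original analysis used is not stated).

**Conductivity.** σ(0) = slope(⟨ΔM~J~²(t)⟩)/(6 V k~B~T) with
M~J~ = Σ q~i~ r~i~ over unfolded residue centers and instantaneous
charges. A transfer decided under minimum image but evaluated on the
unfolded trajectory produces an artificial jump in M~J~ of order the box
length. `transfer_correction()` replaces each such jump by the physical
contribution δM~J~ = q~i~^a^r~i~ + q~j~^a^r~j~ − q~i~^b^r~i~ −
q~j~^b^r~j~, evaluated with the minimum-image displacement recorded in
the event; by charge conservation this reduces to
(q~j~^a^ − q~j~^b^) r~ij~ with r~ij~ = r~j~ − r~i~. The sign convention
was fixed by equating the eight tabulated correction cases with the
direct evaluation above — the four packaged reactions, with both role
assignments of the molecule pair, generate exactly those eight cases
(`enumerate_correction_cases()`), and anything else is rejected as
unsupported. Corrections accumulate as an additive series so the raw data
remain auditable. Reported units: internal e² mol ps^−1^ Å^−1^ kcal^−1^
and mS/cm; the conversion factor is derived from physical constants and
cross-checked in the tests against an independent SI evaluation of the
Nernst–Einstein formula.

A practical note encoded in the tests: M~J~ is a *single* collective
random walk, so the relative error of its MSD slope depends on the ratio
of fit lag to run length — not on the ion count. Reliable σ(0) estimates
need lags well under ~1% of the series length; the Nernst–Einstein
validation uses 20,000 frames with a 5–20 frame window for that reason.

## Shell-resolved potential of mean force

PMF~kl~ = −k~B~T ln(c~l~(shell)/c~l~) compares the concentration of
species l in the first shell of species k with its bulk concentration;
negative values mean enrichment. The original analysis derives first-shell
volumes from a radical Voronoi tessellation; this package instead defines
the shell by a per-species-pair radial cutoff (default: first RDF minimum,
via `pair_rdf()` + `first_shell_cutoff()`) with V~k~ = (4/3)π r³. This is
a deliberate, documented deviation: absolute PMFs acquire a
k-independent per-pair offset from the volume convention, while
*differences* between runs (`delta_pmf()`, the quantity of interest) are
much less affected. Pairs never observed in a shell are flagged as
depleted rather than written as numeric infinities.

## Numerical choices and degenerate inputs

* Positions are stored folded; analyses unfold on demand. Unfolding is
  exact while per-frame displacements stay below half a box edge; a step
  reaching the configurable `max_step` raises an aliasing error naming
  frame and residue (larger jumps are undetectable in principle).
* The packing generator uses rejection sampling with a bounded attempt
  count and a capacity error; packings are deterministic per seed.
* Zero-temperature Brownian steps are accepted as the exact noise-free
  limit; non-finite positions abort with advice to reduce the timestep;
  coincident beads (r < 10^−6^ Å) raise a singularity error.
* Empty systems, empty candidate lists and transfer-free trajectories are
  all valid inputs yielding empty/identity results.
* Problem sizes used by the test-suite: the feedback demonstrations use
  1,000 beads × 250 cycles and 200 beads × 200 cycles; estimator
  validations use 500 free beads (diffusion) and 200 ions × 20,000 frames
  (conductivity). These sizes make the stochastic tolerances (5%/10%,
  ±5 percentage points) at least ~3σ bounds.

## Known limitations

* The toy engine is non-polarizable and unscreened beyond the Yukawa
  form; energies are not comparable to polarizable MD and the Drude/LJ
  utilities are parameter transforms only — Drude particles are carried
  as bookkeeping fields, never integrated.
* Single-bead residues cannot show orientation-dependent contact
  statistics (the published observation that imidazolium/imidazole swaps
  dominate despite a low p~ref~ has no analogue here).
* The acetate template is synthetic; net state charges are exact but
  per-atom values are not the published ones.
* Distance-dependent (Fermi-function) transfer probabilities and
  multi-step Grotthuss species are out of scope.
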