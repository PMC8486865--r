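---
title: "Models and methods behind doxtherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind doxtherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`doxtherm` simulates five treatments of a vascularized solid tumor that
combine doxorubicin chemotherapy with heat: classical chemotherapy,
thermochemotherapy (free drug plus one hour of mild magnetic-nanoparticle
hyperthermia), thermosensitive-liposome (ThermoDox-type) therapy with the
same heating, and thermal ablation by focused ultrasound combined with a
medication phase in either order. This vignette describes the models, the
numerical choices, and every calibration, in the package's own terms.

## Geometry and vascular zoning

The tumor is a 5 mm sphere embedded in a 5 mm shell of normal tissue,
discretized on a uniform radial grid (0.1 mm spacing, 101 nodes; the
builder refuses grids that resolve the tumor radius with fewer than 50
nodes). Geometry is static: the simulated day is short against the
time-scale of tumor growth. Three tumor zones are defined by radius —
hypoxic core (r/R < 1/3), quiescent mid-region (1/3–2/3) and proliferative
rim (2/3–1) — ordered by microvessel density. Vascular surface density S/V
is 0.1x, 0.5x and 1.0x of a nominal 2×10⁴ m⁻¹ (a standard poroelastic-tumor
magnitude); normal tissue has 7×10³ m⁻¹. Functional lymphatics exist only
in normal tissue. The tumor radius and the zone radii are not constrained
by any printed value; they are exposed in the configuration.

Injected surface doses map to initial plasma concentrations through a
single linear factor, 3.82×10⁻⁴ (kg·m⁻³)/(mg·m⁻²), so that 50 mg/m² gives
0.0191 kg/m³ and 150 mg/m² gives 0.0573 kg/m³. No body-surface-area
bookkeeping is attempted; the mapping itself is the datum.

## Interstitial fluid flow

Steady Darcy flow with a Starling transvascular source and a lymphatic
sink:

$$\nabla\cdot(-K\nabla p) = L_p \tfrac{S}{V}\bigl(p_v - p - \sigma(\pi_v -
\pi_i)\bigr) - k_L\,p,$$

with p = 0 in far normal tissue and regularity at r = 0. Fluid parameters
are Baxter–Jain-scale: the plateau interstitial fluid pressure comes out at
~1.79 kPa, within 1.2% of the effective filtration pressure, flat to ~0.6%
over the inner half-radius, and the interstitial velocity peaks at the rim
at ~0.8 µm/s — the classic high-IFP picture in which convection is
negligible inside the tumor. Discretization is a conservative second-order
finite-volume operator with harmonic face conductivities; the linear system
is solved directly, and the discrete mass balance closes to ~10⁻¹⁴.
Steady flow is justified because pressure equilibrates in minutes while the
pharmacokinetics play out over a day; flow is re-solved whenever an
ablation damage map rescales $L_p S/V$ node-wise.

## Thermal response functions

Two pure functions of local temperature scale the biology, both equal to 1
at 37 °C, both piecewise-linear up to 43 °C and held constant above (mild
hyperthermia ends there; higher temperatures act through perfusion damage
instead):

* the transmembrane multiplier scales cellular uptake and efflux alike;
  its 43 °C plateau (2.5) is fixed algebraically by the requirement that it
  equal 2.4 at 42.6 °C, the peak mild-hyperthermia temperature;
* the permeability multiplier scales the vessel-wall diffusive permeability
  and the convective sieving factor $(1-\sigma_f)$ (capped at 1), reaching a
  configurable maximum of 2.0 at 43 °C — the pore-size interpretation of
  heat-enhanced extravasation.

A linear ramp through the printed anchor is the minimal monotone choice;
the functional form is swappable in configuration.

## Magnetic-nanoparticle hyperthermia

Heating uses the linear-response (Rosensweig) dissipation of 18 nm
maghemite particles, $P = \pi\mu_0\chi''(f)\,f H^2$, with the imaginary
susceptibility from Debye relaxation at the effective Néel + Brownian
relaxation time (τ ≈ 2.8×10⁻⁸ s with the default anisotropy 4.7×10³ J/m³,
M_s = 3×10⁵ A/m, 1 nm coating, 10⁻³ Pa·s solvent). The default field is
13 kA/m at 300 kHz for one hour. Clusters are pre-accumulated uniformly
over the tumor.

The Pennes equation is integrated implicitly (unconditionally stable Euler,
1 s steps during heating) with Dirichlet 37 °C far-field and the same zone
perfusion used by the drug model — one perfusion truth source, scaled by
any ablation damage. Because the problem is linear in the source, the MNP
volume fraction is calibrated with a single reference solve: the
temperature rise scales exactly with the fraction, giving
φ = 1.29×10⁻³ for a 42.6 °C peak at the end of the hour (the value shipped
as the default). The heated hour is quasi-steady — the spatial peak drifts
by < 0.1 °C over the final 10 minutes — and never reaches 43 °C. The
discrete energy audit closes to ~10⁻⁹.

## Focused-ultrasound ablation

The single-element bowl (32 mm aperture, 64 mm focal length — typical
preclinical geometry, configurable) is evaluated by direct Rayleigh
integration over the curved surface with a complex wavenumber (absorption
5 Np·m⁻¹·MHz⁻¹). The bowl quadrature must resolve the phase: arc spacing
of at most λ/6 is enforced, and the on-axis field agrees with the O'Neil
closed form to well under 3% away from nulls. At 30 W and 1.44 MHz the
focal pressure is ≈5.3 MPa (≈880 W/cm²).

Heating during the 60 s sonication is integrated explicitly on the
axisymmetric grid (0.5 × 1 mm cells on the reduced test grid; the time step
is checked against the diffusive stability limit), with the temperature
history stored at 0.5 s resolution for dosimetry. Thermal dose is standard
CEM43 (R = 0.5 at or above 43 °C, 0.25 below). Zones follow the
Sapareto–Dewey convention plus the 45 °C bound for the vulnerable-vessel
periphery: coagulative core α at ≥ 240 min, sublethal β at ≥ 30 min *or* a
peak above 45 °C (so the band between 45 °C and a damaging dose is not left
unclassified and the zones nest), γ where the peak reached 43–45 °C, else
untouched. Perfusion retention is 0 / 0.2 / 0.5 / 1 in α/β/γ/none — the
0.2 realizes the "< 25% in β" rule.

The 2D lesion is mapped onto the radial treatment grid through
volume-equivalent spherical radii of the cumulative α, α+β, α+β+γ regions.
At the full 30 W the lesion engulfs most of the 5 mm tumor (sustained
~880 W/cm² for 60 s is a large exposure); the combined-protocol analyses of
the recurrence signature therefore use a reduced power (6 W) at which the
necrotic core sits strictly inside the tumor, which is the regime those
protocols are about. Nesting and the monotone shrinkage of all three zones
with power hold throughout.

## Plasma pharmacokinetics

Two plasma pools — systemic (V_Sp = 5×10⁻⁵ m³) and tumor microvessel
(V_Tp/V_Sp = 10⁻³, i.e. a ~9.5% vascular volume fraction, consistent with
S/V = 2×10⁴ m⁻¹ and ~10 µm capillaries) — each carry liposomal (T), free
(F) and protein-bound (B) drug. Binding follows dB/dt = k_aF − k_dB with
k_a = 1.5×10⁻³ s⁻¹, k_d = 5×10⁻⁴ s⁻¹: a 25% equilibrium free fraction
(bound ≈ 3× free) with an ~8 min relaxation time; the per-step update is
the exact exponential, conserving F+B to machine precision. A bolus mixes
instantaneously and — because the binding algebra is treated as fast
against the infusion — enters pre-equilibrated (25% free) when the agent is
free drug, or fully encapsulated when it is liposomal.

Clearance removes free and bound drug at k_el,F = 5×10⁻⁴ s⁻¹ (measured
systemic free-drug half-life ≈ 23 min, inside the sub-30-min constraint)
and liposomes at k_el,T = 3×10⁻⁵ s⁻¹ plus a leak release k_leak =
3.9×10⁻⁵ s⁻¹ — carriers are unstable in blood, losing ~30% of payload over
2.5 h at 37 °C, while retaining multi-hour circulation. Above the lipid
melting range the release rate ramps linearly from k_leak (below 39 °C) to
a burst k_burst = 0.06 s⁻¹ at 41 °C, releasing 95% of the payload in 50 s.
Tumor microvessels exchange plasma with the systemic pool at Q_perf =
2.8×10⁻³ s⁻¹ (vessel-volume basis) and lose drug to endothelial uptake at
10⁻⁴ s⁻¹. With the default volume ratio the tumor vessel perturbs systemic
concentrations by < 1% even during burst release.

For free-drug protocols the two plasma pools are treated as one — the
distinction only matters when intravascular release localizes free drug in
the heated tumor — so the tumor wall exchanges directly with systemic
plasma; liposome protocols keep the distinct compartment. Inside the
coupled march the six plasma states are advanced by RK4 with ≤ 1 s
substeps, with the transvascular losses linear in the plasma states and
their time integrals carried in augmented states so that plasma and field
bookkeeping agree exactly; the standalone `simulate_plasma_pk()` uses a
stiff adaptive integrator (`deSolve::lsoda`).

## Interstitial transport

Each species obeys a convection–diffusion–reaction equation on the radial
grid: implicit conservative diffusion (D_F = 1.6×10⁻¹⁰, D_B = D_F/3,
D_T = 2×10⁻¹³ m²/s — the carrier barely diffuses and stays at the
periphery), explicit upwind advection by the Darcy velocity (a minor
transport route here), Patlak transvascular exchange, interstitial binding,
local release at k_rel of the local temperature, cellular exchange, and
lymphatic removal in normal tissue (fluid drainage plus a baseline solute
clearance of 5×10⁻⁴ s⁻¹, since normal-tissue pressure — and hence the
convective lymph flux — is nearly zero).

The transvascular flux is the Patlak/Kedem–Katchalsky form

$$J = P\,\tfrac{S}{V}\,f_p(T)\,(C_v - C_i)\,\frac{Pe}{e^{Pe}-1}
      + \phi_v (1-\sigma_f)_{\mathrm{eff}} C_v,$$

evaluated with a series expansion below |Pe| < 10⁻⁸; it matches a numerical
membrane-transport oracle to 10⁻⁶. Permeabilities are P_F = 2×10⁻⁸ m/s in
tumor (6×10⁻⁹ in normal tissue) and P_T = 2×10⁻⁹ m/s for the 100 nm carrier
in tumor only — normal vessel-wall pores (5–6 nm) exclude it entirely.
Bound drug crosses neither the vessel wall nor cell membranes. Cellular
uptake and efflux (ξ = ε = 1.3×10⁻³ s⁻¹, both scaled by the transmembrane
multiplier) are applied as an exact conservative exchange; the rates were
calibrated so the tumor-average intracellular peak lags the extracellular
free-drug peak by ~21 min in the classical pipeline.

Operator splitting at 1 s steps during heating and 10 s elsewhere keeps
every sub-update conservative; the whole-system mass audit (plasma +
interstitium + cells + clearance + endothelial uptake + lymph + boundary
outflow vs injected mass) closes to ~10⁻¹⁴ at every output time.

## Pharmacodynamics

Cell survival follows dN/dt = (k_p − k_deg − ω(C_int)) N per node, with
proliferation k_p = 3×10⁻⁶ s⁻¹ and physiological degradation k_deg =
2.6×10⁻⁶ s⁻¹, chosen so drug-free tissue regrows by ≈12% over 80 h (the
only printed constraint on the net rate: "more than 10%"). The kill rate is
saturable, ω = f_max C_int/(EC50 + C_int), with f_max = 1.8×10⁻⁵ s⁻¹ and
EC50 = 2×10⁻⁴ kg/m³ calibrated jointly so classical chemotherapy destroys
≥ 11% of tumor cells within 6 h at every permissible dose (15.5% at
50 mg/m², rising with dose) and the liposome protocol kills ≥ 40% (≈49%) by
24 h. Ablated α-zone cells are removed instantly; β-zone cells are treated
as recovering with full proliferative capacity — the worst case for
recurrence — with a configurable instant-kill fraction.

## Protocol orchestration

`run_protocol()` executes the stages in order with strictly one-way
physics: flow (re-solved per perfusion state), temperature (independent of
concentrations), then PK/transport/survival on the stored temperature
schedule. Ablation-first protocols apply the lesion, its perfusion damage
and the α-zone kill before the medication phase begins immediately;
medication-first protocols apply the ablation kill at the end of the
window. Time resolution is 1 s during heating (plus a 10 min cool-down)
and 60 s output cadence; the default horizon is 24 h. Everything is
deterministic: identical configurations give bit-identical results.

## What the model does and does not reproduce

The simulated conditions reproduce the anchors of the underlying treatment
model: the 25% free fraction, the sub-30-min free-drug half-life, the
~20 min intracellular lag, the 42.6 °C hyperthermia peak bounded by 43 °C,
the ≥ 95%-in-60 s release trigger, the ≥ 2.6-fold free-drug gain of
intravascular release (≈3.7 here), the 11%/40% kill anchors, the focal
ablation above 65 °C, the α/β/γ perfusion rules, and the protocol ordering
of kill and growth-onset delay.

Two quantitative behaviors deviate, both traceable to the spatially
resolved washout of this implementation. First, intracellular drug in
classical chemotherapy falls to ~22% of its peak 5 h post-injection (below
1% only by ~24 h): the hypoxic and quiescent zones, with 10–50% of the rim's
vascular surface, return drug to the circulation over hours, and the
interstitial bound pool buffers the decline. Second, as a direct
consequence, tumor-average growth onset occurs later than a
fast-washout reading would give (~17 h for classical chemotherapy rather
than ~6 h; the liposome protocol does not regrow within the 24 h horizon).
The orderings — hyperthermia delays onset, the liposome protocol delays it
furthest — are preserved. Similarly, carrier concentration at the tumor rim
exceeds the center throughout the supply phase (first ~4–5 h); at late
times the slowly draining core crosses over.

These are consequences of the chosen zone permeability-surface products,
not of the numerics; all transport links were verified against analytic or
brute-force oracles independently.

## Problem sizes and runtimes

All shipped analyses are desk-scale: 101 radial nodes for flow, bioheat and
transport (a 24 h protocol integrates in ~25 s), a 31×13-node axisymmetric
grid with a 192×128-point bowl quadrature for sonication tests, and full
resolution (61×41) available in configuration. The test suite and the
acceptance script run the complete protocol set at these sizes.
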