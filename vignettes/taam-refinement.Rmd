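---
title: "Transferable aspherical atom refinement: model, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferable aspherical atom refinement: model, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the pseudoatom
model and the conventions it is evaluated under, the refinement
algorithm, the diagnostics, the synthetic fixtures, and the design
decisions taken where more than one defensible choice existed. It states
no empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The pseudoatom model

Each atom's electron density is a Hansen–Coppens pseudoatom

$$\rho(\mathbf r) = P_c\,\rho_{core}(r) + P_v\,\kappa^3\rho_{val}(\kappa r)
 + \sum_{l=0}^{4} \kappa'^3_l R_l(\kappa'_l r)
   \sum_{m=-l}^{l} P_{lm}\, d_{lm}(\hat{\mathbf r}_{local}),$$

with every radial function a Slater sum $R(r) = \sum_i c_i r^{n_i}
e^{-\zeta_i r}$ ($\zeta$ in Å$^{-1}$). The conventions, fixed once and
tested everywhere:

* **Scattering variable.** $|\mathbf h| = 1/d = 2\sin\theta/\lambda$;
  all Fourier kernels are $e^{2\pi i\,\mathbf h\cdot\mathbf r}$.
* **Normalization.** The stored core sum integrates to $N_{core}$
  electrons and the valence shape to exactly 1
  ($4\pi\int\rho r^2 dr$, checked at load to $10^{-6}$); each deformation
  radial is normalized internally to unit radial integral
  ($\int R_l r^2 dr = 1$). $P_c$ therefore *counts core electrons*
  (default $N_{core}$) and $f(0) = P_c + P_v + P_{00}$ is the pseudoatom
  electron count — the sum rule the acceptance suite enforces.
* **Angular functions.** $d_{00} = 1/4\pi$; for $l\ge 1$ the real
  harmonics are density-normalized, $\int |d_{lm}|\,d\Omega = 2$, so a
  population of 1 moves one electron between lobes. The conversion
  constants from orthonormal harmonics are tabulated to machine precision
  and re-verified by kink-aware quadrature in the test suite.
* **$\kappa$ placement.** A real-space contraction $\kappa^3\rho(\kappa r)$
  appears in reciprocal space as $f(h/\kappa)$; the deformation terms use
  $\langle j_l\rangle(h/\kappa'_l)$ with the same radial parameters. The
  brute-force three-dimensional Fourier oracle in the tests pins this
  contract to $10^{-5}$ relative (in practice it agrees to machine
  precision).
* **Transforms.** $\langle j_l\rangle(h) = \int R(r) j_l(2\pi h r) r^2 dr$
  has a closed form from the finite sine/cosine expansion of $j_l$;
  below $2\pi h < \zeta/2$ a power series replaces it to avoid
  cancellation. Orders up to $l = 4$ are supported, requiring
  $n \ge l - 1$.
* **No anomalous dispersion** ($f' = f'' = 0$): form factors are
  Hermitian, $f(-\mathbf h) = \overline{f(\mathbf h)}$, and
  $|F(\mathbf h)| = |F(-\mathbf h)|$ exactly.

Local frames are built from bonded neighbours: the first axis direction
becomes local $z$ exactly, the second is Gram–Schmidt-orthogonalized into
local $x$, $y = z \times x$. Recipes are written in neighbour roles
(`N1` highest-priority neighbour — heaviest element, ties broken by label
sort; `N2` second; `NMEAN` mean of unit neighbour directions; `NN1`
heaviest second-shell atom). A recipe asking for `N2` on a one-neighbour
atom (carbonyl O, hydrogens) falls back to `NN1`. Axes closer than 1° are
rejected. Frames use minimum-image directions between asymmetric-unit
positions; bonded pairs that are only symmetry-related (e.g. polymeric
coordination) are a documented limitation.

## The bank and atom typing

The bank is UTF-8 keyed text (`TAAMBANK 1.0` header, `TYPE ... END`
blocks, `#` comments); `parse_bank()`/`write_bank()` round-trip it
losslessly at validation tolerance. Typing is deliberately simpler than a
full chemical ontology: an atom's signature is the sorted multiset of
`element:heavy-degree` tokens over its bonded neighbours plus its own
ring membership (rings of size 3–7 on the bond graph). Matching is
most-specific-first — exact signature, then wildcard degrees (`*`), then
an element-only fallback (`NEIGHBORS any`) — with ties broken on sorted
type id, so the assignment is independent of atom and bank order.
Unmatched atoms are a *result*, not an error; the form-factor engine
falls back to the spherical reference for them with a warning, mirroring
hybrid practice. For disordered groups an ordered atom bonded to several
alternative conformers counts each disorder pair once (lowest part id),
so both conformations see one substituent.

Electroneutrality: one multiplicative factor on $P_v$ per charge group
makes $\sum_j (P_c + P_v + P_{00})_j - \sum_j Z_j = -q$. The default is a
single neutral group over the whole structure; explicit groups support
the formal-charge parametrization of multi-component crystals (e.g. metal
+1 / organic −1). Per-moiety versus global rescaling is exposed rather
than decided, since either is defensible; both paths are tested.

## Structure factors and symmetry

$$F(\mathbf h) = \sum_s \sum_j m_j\,occ_j\, f_j(R_s^T\mathbf h)\,
  T_j(\mathbf h, s)\, e^{2\pi i \mathbf h\cdot(R_s\mathbf x_j + \mathbf t_s)}$$

Form factors are looked up at symmetry-rotated indices from a table
covering the closure $\{R_s^T\mathbf h\}$ — the `.tsc` mechanism's
asymmetric-unit storage — rather than by rotating frames per image.
Special positions are detected by duplicate-image collapse (fractional
tolerance $10^{-4}$) and handled by the multiplicity factor
$m_j = n_{unique}/n_{symop}$; site-symmetry ADP constraints are *not*
imposed (the fixtures avoid constrained ADPs). Displacement factors:
isotropic $\exp(-8\pi^2 U_{iso} (\sin\theta/\lambda)^2)$; anisotropic
$\exp(-2\pi^2 \sum h'_i h'_j a^*_i a^*_j U^{ij})$ with $h' = R_s^T h$ and
$U^{ij}$ in the CIF reciprocal-basis convention
($U_{cart} = M N U N M^T$, $N = \mathrm{diag}(a^*,b^*,c^*)$). Summation
is direct (no FFT on the model side); at desk-scale reflection counts
($\lesssim 2\times10^4$) this is exact and fast. The strongest
correctness oracle — explicit expansion over all symmetry images — is run
on every fixture at $10^{-10}$ relative.

## Refinement

Minimization target $\sum w (F_o^2 - k|F_c|^2)^2$ with the standard
weighting $w = 1/[\sigma^2 + (aP)^2 + bP]$,
$P = (\max(F_o^2,0) + 2k|F_c|^2)/3$. The defaults $a = 0.01$, $b = 0$ are
a mild conventional choice (no automatic weight optimization).
Reflections below $-3\sigma$ are rejected with a warning; other negative
intensities stay in the F²-based minimization.

* **Inner loop** — damped Gauss–Newton. Derivatives are analytic for the
  scale and the disorder fractions, central finite differences for
  coordinates ($10^{-5}$ fractional) and displacement parameters
  ($10^{-5}$ Å$^2$); a five-point-stencil oracle checks the columns to
  $10^{-6}$. Shifts are capped at 0.2 Å of Cartesian displacement per
  cycle and halved until the fixed-weight objective does not increase
  (monotone descent is asserted, not hoped for). Singular normal matrices
  report the null-space parameter names. Under-determination
  ($n_{obs} < \max(10, 5 n_{par})$) is an error.
* **Outer loop** — regenerate bond graph, types, electroneutrality,
  frames and the form-factor table from the current geometry, then run
  the inner loop; stop when the largest fractional coordinate change
  drops below $10^{-4}$ or after 10 outer cycles (defaults). Convergence
  status is reported honestly. Three consecutive outer-cycle R1
  increases abort with a diagnostic.
* **Origin fixing.** Polar (floating) directions are detected from the
  operator list (translations fixed by every rotation part); the anchor
  atom's coordinates along them are excluded from refinement. Recovery
  scoring (`position_recovery()`) removes the mean displacement along
  floating directions, which is physically indeterminate.
* **Disorder.** Part ids pair consecutively; each pair carries one free
  fraction $p$ with occupancies $(p, 1-p)$, refined analytically and
  clamped to $(0.01, 0.99)$ with a warning at the walls.
* **Uncertainties.** $esd_p = \sqrt{GooF^2 (A^{-1})_{pp}}$ with
  $GooF^2 = \sum w r^2/(n_{obs}-n_{par})$. Calibration is tested, not
  assumed: over independent noise replicates the pull distribution
  $(\hat\theta - \theta)/esd$ must have a standard deviation in
  $[0.8, 1.2]$.
* **Hydrogens** are always refined freely with isotropic displacement
  parameters — never constrained or riding. The spherical reference's
  bonded-H option is a $\kappa$-contracted single-Slater 1s density
  (exponent multiplied by 1.16, configurable).

## Diagnostics

R1 uses $|F_o| = \sqrt{\max(F_o^2, 0)}$ against $\sqrt k |F_c|$, over all
reflections and over the gt subset $F_o^2 > 2\sigma$; wR2 is on F². These
conventions are fixed here and are *not* claimed to match any particular
refinement program bit-for-bit — published residuals differ between
programs for exactly this reason.

The difference synthesis
$\Delta\rho = V^{-1}\sum (|F_o|/\sqrt k - |F_c|) e^{i\phi_c} e^{-2\pi i hr}$
is evaluated by FFT on a grid of spacing ≤ 0.2 Å (default 0.1 Å),
Friedel-completed so the map is real, with F(000) excluded (the map is
zero-mean). All reflections enter by default (switchable to gt-only).
Peak/hole positions and heights are refined by a quadratic fit on the
3×3×3 neighbourhood, clamped to one voxel.

The fractal-dimension plot uses isovalue box counting:
$N(\rho_0)$ counts grid cells whose 2×2×2 corner values bracket $\rho_0$
(periodic), and $d^f = 3\ln N/\ln N_{total}$, zero where no cell brackets
the level, over 101 levels spanning the map range. This is the standard
definition for residual-density analysis; a per-bin voxel histogram
cannot reach the documented Gaussian-noise apex $d^f(0) \approx 3$ for
any realistic grid, which is why the box-counting form is used. A
constant map collapses to a single level with $d^f = 3$; a symmetric
two-level map has its maxima at the two levels, not at zero — both are
tested.

Bond reports classify bonds chemically (water O—H, N—H, aromatic and
aliphatic C—H, heavy-heavy element pairs), propagate esds from the
per-atom position blocks of the covariance matrix (cross-atom covariances
neglected — a documented approximation), compare X—H classes against a
small editable neutron-reference table, and report the mean C—C esd as
the precision metric.

## Synthetic fixtures: what they emulate and what they do not

The generator defines the study conditions; its defaults are fixed and
not tuned per experiment:

* `water_P1bar` — one water on a general position under inversion; the
  smallest refinable case, used for fast property tests and the esd
  calibration (50 replicates fit comfortably because a refinement takes
  seconds).
* `amide_water_P21c` — acrylamide·H₂O under a two-fold screw
  (`-x,y+1/2,-z+1/2`): a planar amide (sp² C, N—H₂, C=O), a vinyl group
  and lattice water; the workhorse for recovery and model-contrast
  experiments. Cell 7.5 × 10.0 × 8.5 Å; placements were chosen so no
  symmetry image approaches a bonding distance.
* `two_conformer_chain` — a propanol-like chain whose terminal carbon
  occupies two rotamer sites (parts 1/2) with a shared occupancy
  constraint, generated at 0.65/0.35 by default — the disorder regime in
  which a shared-fraction parameter is the textbook treatment.
* `metal_salt_Pm` — Na⁺, formate and water under a mirror; the hybrid
  (spherical metal + aspherical organics) and formal-charge fixture.

Reflections cover the full sphere to `d_min` (default 0.8 Å — good
small-molecule data) with noise $F_o^2 = k|F_c|^2 + \varepsilon$,
$\varepsilon\sim N(0,\sigma^2)$, $\sigma = 0.01|F_c|^2 + 0.1$: a constant
1 % relative error plus a floor. This is the simplest model consistent
with a reported σ(F²) column. It does **not** emulate counting
statistics' intensity dependence, absorption, extinction, thermal diffuse
scattering, twinning or detector artefacts — so passing tests demonstrate
the *estimator and its uncertainties are correct under the stated noise
model*, not robustness to real-data systematics.

The built-in bank is this package's own: single-ζ Slater-rule radial
densities and bond-concentrating multipole populations (dipoles toward
the bonded neighbour, positive quadrupole/octupole terms along the
primary bond axis). The magnitudes were set so that a spherical
refinement of aspherically generated data leaves residual bond density of
the order seen in real IAM difference maps at this resolution
(~0.1–0.3 e Å⁻³) — i.e. realistic *behaviour*, with no claim of
reproducing any published databank's values, which is out of scope.

## Numerical choices and degenerate inputs

* Duplicate reflections merge by inverse-variance weighted mean; Friedel
  mates are kept separate (they are equal anyway without dispersion —
  tested). How deposited data sets were merged upstream is unknowable
  from a paper; this rule is a convention of the artifact.
* Coordinates wrap to [0,1) on ingest; distances use minimum-image over
  the 27 neighbouring cells. Correctness over speed at this scale.
* $\langle j_l\rangle$ switches from closed form to series at
  $2\pi h = \zeta/2$; both branches agree with adaptive quadrature to
  $10^{-8}$ relative over random parameters.
* `d_spacing` rejects (0,0,0); `slater_fourier_bessel` rejects $l > 4$
  and non-integrable $(n, l)$; empty hkl files parse to an empty set with
  a warning; a constant map yields a one-point fractal curve; a noiseless
  simulation recipe still emits a (tiny) positive σ column because a
  reflection set's uncertainties must be positive.
* Problem sizes used by the tests and the acceptance script — water
  (~1 700 reflections, 18 parameters), amide (~5 200 reflections, 83
  parameters), 25–50 calibration replicates — were chosen so the whole
  pipeline runs in minutes on one core while every statistical check
  retains enough power to fail when wrong.

## Known limitations

* Symmetry comes only from explicit operator lists: no space-group
  symbols, no site-symmetry ADP constraints.
* No restraints language, rigid-body/TLS, twin refinement, extinction or
  solvent masking; anomalous dispersion defaults to zero.
* Local frames and bond graphs use asymmetric-unit minimum-image
  geometry; molecules completed only by symmetry are out of scope for
  typing.
* The typing scheme is first-shell + ring flag — transferability
  *mechanism*, not a full chemical ontology.
* `.tsc` support is a documented compatible-in-spirit text dialect (plus
  lenient reading of external files), not a bit-exact implementation of
  any specific program's writer; the binary dialect is not supported.
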