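---
title: "Linearized scattering datasets for microwave brain-stroke classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linearized scattering datasets for microwave brain-stroke classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microwave imaging offers a portable, low-cost, non-ionizing route to
distinguishing ischemic from haemorrhagic stroke: at around 1 GHz an
ischemic region has a lower complex permittivity than the surrounding
brain, and blood a higher one. A helmet of antennas measures the complex
scattering parameters $S_{pq}$ between every transmitter--receiver pair,
and a classifier can map those measurements directly to a diagnosis
(stroke present or not, which kind, which quadrant of the head) without
solving the full imaging problem.

The bottleneck is training data: full-wave electromagnetic simulation of
each stroke scenario takes hours, and a useful training set needs
thousands of scenarios. `mwistroke` implements the fast alternative: a
*distorted-Born linearized scattering operator* that maps dielectric
perturbations of a reference (healthy) head to differential S-parameters
with a single matrix--vector product per scenario, plus the full
classification harness (SVM, multilayer perceptron, k-nearest
neighbours, confusion-matrix reporting) that consumes the generated
datasets.

## Model

The head occupies a domain discretized into $N$ tetrahedra with
per-tetrahedron complex relative permittivity
$\varepsilon = \varepsilon_r - j\,\sigma/(\omega\varepsilon_0)$
(time convention $e^{+j\omega t}$, so lossy media have a negative
imaginary part). A stroke with permittivity $\varepsilon_s$ inside
background tissue $\varepsilon_b$ creates the dielectric contrast

$$\Delta\chi_n = \frac{\varepsilon_s - \varepsilon_b(n)}{\varepsilon_b(n)}$$

on the tetrahedra it covers and zero elsewhere. Under the distorted Born
approximation (valid for weak, localized perturbations such as early
strokes), the differential scattering parameters
$\Delta S_{pq} = S^t_{pq} - S^b_{pq}$ are linear in the contrast:
$\Delta S \approx \mathbf{S}\,\Delta\chi$, where $\mathbf{S}$ is the
$M \times N$ discretized scattering operator with $M = M_a^2$ antenna
pairs and entries

$$S_{m,n} = -\frac{j\omega\,\varepsilon_0\varepsilon_b(r_n)}{2\,a_p a_q}\;
\mathbf{E}_p^b(r_n)\cdot\mathbf{E}_q^b(r_n)\;\Delta V_n ,$$

with $\mathbf{E}_p^b$ the background field of antenna $p$ at the
barycentre $r_n$, $\Delta V_n$ the tetrahedron volume, $a_p$ the antenna
power waves, and the *unconjugated* dot product, as the
reciprocity-based derivation requires. The operator depends on the
background only, so it is assembled once and every scenario afterwards
costs one sparse matrix--vector product.

Two conventions deserve a note, because the symbol
$\varepsilon_b(r_n)$ in the kernel admits two readings:

* the **absolute** complex permittivity
  ($\varepsilon_0 \times$ relative) is used by default; the relative
  reading is available via `assemble_operator(relative_eps = TRUE)`;
* the wavenumber branch is chosen with $\mathrm{Im}(k) \le 0$ so that
  $e^{-jkr}$ decays in lossy media.

## What stands in for what

The package is a desk-scale emulation of a full measurement chain, and
three of its components are synthetic stand-ins that a production system
would replace through the same interfaces:

* **The head.** A layered anthropomorphic phantom is replaced by nested
  ellipsoidal shells (skin, skull, CSF, grey matter, white-matter core)
  plus a cerebellum lobe at the lower back, meshed by structured
  subdivision of a cube grid (six conforming tetrahedra per cube) at a
  configurable cell size (default 3 mm). `read_mesh()`/`write_mesh()`
  accept Gmsh MSH v2.2 and legacy VTK, so externally meshed heads drop
  in. Tissue dielectric values default to the standard Gabriel-database
  values at 1 GHz; the table is a plain tibble and fully overridable.
  With those values the ischemic contrast magnitude spans 0.08 (white
  matter) to 0.31 (grey matter), and the haemorrhagic one 0.28 (grey)
  to 0.75 (white).
* **The background fields.** A full-wave solver is replaced by an
  analytic infinitesimal-dipole field in a homogeneous lossy coupling
  medium (relative permittivity 18.42, the nominal antenna-brick value,
  with a small conductivity). `field_set()` also accepts precomputed
  per-tetrahedron field tables, which is where full-wave fields would
  enter. The default dipole moment is normalized to radiate 1 W, tying
  field amplitudes to a physically meaningful drive.
* **The background S-parameters.** Off-diagonal entries follow the
  scalar Green's function between antenna positions with a configurable
  coupling constant; the diagonal is a fixed reflection coefficient.
  Reciprocity ($S_{pq}=S_{qp}$) holds by construction. Morphed or
  heterogeneous head models get their own backgrounds through the
  operator itself: $S^b(\text{model}) = S^b(\text{nominal}) +
  \mathbf{S}\chi_{\text{model}}$, treating the model as a weak
  perturbation of the nominal head — the same physics that justifies
  the operator in the first place.

Because the fields, head and backgrounds are synthetic, the *absolute*
classification accuracies obtained here do not transfer to any physical
system; what the tests establish is that the pipeline is internally
consistent (operator = brute-force sum, exact linearity, exact noise
normalization, calibration identity) and that the harness separates the
nine classes when the physics says they are separable.

## Scenario generation

Stroke centres are drawn uniformly among the barycentres of brain
tetrahedra (white matter, grey matter, cerebellum). A stroke of radius
$r$ collects every tetrahedron whose barycentre lies within $r$ of the
centre (quadratic-form membership for ellipsoids); selected tetrahedra
outside the brain are discarded, and the whole placement is rejected and
redrawn if more than half of the initial selection falls outside the
brain ("more than half" counted by tetrahedra, as the discrete analogue
of the rule). Class labels combine the kind (I/H) with the quadrant of
the *centre* — front/back by the sign of $y$, left/right by the sign of
$x$, ties going to front/right — even when the stroke spills across an
axis, which is a deliberate source of label ambiguity near the axes.

Measurement noise is modelled in the contrast domain: i.i.d. circular
complex Gaussian $\delta\chi$ over all tetrahedra, mapped through the
operator ($\delta S = \mathbf{S}\delta\chi$) and scaled so the realized
mean per-element power of $\delta S$ equals $10^{L/10}$ for a level
$L$ drawn uniformly from $\{-110, -105, -95, -90\}$ dB. The dB level is
interpreted as absolute per-element power (the lowest level matching a
medium-quality VNA noise floor); this is a documented reading, since the
reference quantity is not standardized. For bulk generation the package
draws $\delta S$ directly from the factored Gram matrix
$\mathbf{S}\mathbf{S}^H$ (Hermitian eigendecomposition), which for
Gaussian $\delta\chi$ is *identical in distribution* to the contrast
route at a fraction of the cost; `contrast_noise()` keeps the literal
route and a test checks the two agree.

Training sets follow the composition 1000 healthy + 1125 per stroke
class (10,000 records). Features are the upper triangle (including the
diagonal) of the reciprocal $24\times24$ S-matrix: 300 complex elements,
i.e. 600 real features, in row-major $p \le q$ order with Re/Im
adjacent — the ordering is a fixed convention, any fixed order being
equivalent for the classifiers. An amplitude-only mode (300 features)
supports the cheaper-receiver ablation.

Non-nominal systems ("System A/B") perturb each antenna's coupling-brick
permittivity with a normal draw (mean 18.42, s.d. 0.03 or 2.00, redrawn
if unphysical), feed the perturbed values to the field provider and
background generator, and testing records are calibrated back to the
nominal system per antenna pair:
$\tilde S^{t,C} = S^b (\tilde S^b + \delta S_1)^{-1} (\tilde S^t +
\delta S_2)$ elementwise, with independent noise draws at the same
level. On the nominal noiseless system the calibration is exactly the
identity.

## Head-model variation

`expand_tissue()`/`shrink_tissue()` move tissue boundaries one
tetrahedron layer per iteration by relabelling across shared faces —
geometry and connectivity never change, so on a 3 mm mesh two layers
move a boundary by about 6 mm. `heterogeneity()` draws per-tetrahedron
permittivity and conductivity uniformly within $\pm\text{var}\%$ of the
nominal values (per-tet independent draws by default; a per-tissue mode
is provided since the alternative reading — one offset per tissue per
model — is equally defensible). `model_family()` crosses five two-layer
boundary recipes with the heterogeneity settings (0.3% and 5.0% for
training; 2.0% is the intermediate testing value), ten models in total.
The default recipes are all *expansions* (grey matter, cerebellum, CSF,
skull, white matter): the grey-matter and CSF shells are only one or two
cells thick, so a two-layer shrink would consume them entirely, and the
package fails rather than silently emptying a tissue.

## Classifiers

The three algorithms run with the configurations used for the complex
datasets: SVM (libsvm via e1071) with RBF kernel, $\gamma = 0.059$,
$C = 300$; a multilayer perceptron with five hidden layers of 800, 400,
200, 100 and 50 tanh neurons, softmax output, minibatch SGD (batch 200,
momentum 0.9), L2 term $\alpha = 10^{-4}$, epoch cap 200 and an adaptive
learning rate (divided by 5 after two epochs without improvement); and
k-NN with Euclidean metric and $k = 3$. For amplitude-only features the
selected $\gamma$ was 0.11 and the MLP learning rate constant; for
multi-model training the MLP cap was 1000 epochs. The MLP is implemented
in the package (no installed R package provides a multi-hidden-layer
perceptron); the SVM and k-NN are the standard library implementations.
`grid_search()` does exhaustive stratified-CV accuracy search (5 folds
by default — the fold count is not standardized anywhere, 5 is the
common choice) with first-in-grid tie-breaking.

**Feature scaling.** Scaling is fit on the training split only and is
switchable. The default is *global* scaling: centre each feature, then
divide all features by a single pooled scale. The classical per-feature
z-score (`scale = "standard"`) is available but is a poor default for
this data: many antenna pairs barely see the brain, so their features
carry noise only, and forcing every feature to unit variance inflates
those channels until they dominate Euclidean distances and the RBF
kernel. Global scaling preserves the relative physical magnitude of the
channels.

Evaluation produces the 9$\times$9 confusion matrix (rows true, columns
predicted), its row-normalized form, the 3$\times$3 macro-class
aggregation (healthy / ischemic / haemorrhagic) and both accuracies;
`autoplot()` renders the matrix with the macro blocks outlined.

## Numerical choices and problem sizes

* Default working frequency 1 GHz; single frequency throughout.
* Mesh cells default to 3 mm (the boundary-morphing layer thickness).
  The end-to-end dataset/classifier runs in the test suite use 9 mm
  cells ($N \approx 2\times10^4$ tetrahedra) and the unit tests 12 mm —
  deliberate desk-scale choices; the operator code is the same at any
  $N$.
* The Born-error metric $\eta_{pq} = 20\log_{10}|S^{ref}_{pq} -
  S^{lin}_{pq}|$ reports identical entries at a $-300$ dB floor to keep
  it total.
* Degenerate inputs fail loudly: coplanar tetrahedra, shells with
  non-positive semi-axes, coincident antennas, evaluation points on a
  dipole, zero calibration denominators (named by antenna pair),
  contrast vectors of the wrong length.
* k-NN distance ties and `max.col` ties are pinned to the model seed so
  prediction is reproducible.
* The test suite's separation check at full scale (10,000 records,
  lowest noise level) asserts $\ge 95\%$ validation macro-class
  accuracy for all three algorithms; at unit-test scale (a few hundred
  records) the same pipeline is only checked to learn the task well
  above chance, because all three algorithms are sample-hungry at 600
  features.

## Limitations

The generator emulates the *structure* of the measurement chain, not
any specific hardware: absolute S-parameter scales, the background
coupling constant and the dipole normalization are plausible but
synthetic, so accuracy figures obtained on generated data say nothing
quantitative about a physical system. Stroke shapes are spheres and
axis-aligned ellipsoids; there is no vascular-territory placement, no
anatomical geometry, no frequency sweep, and the nonlinear inverse
(imaging) problem is out of scope. The rejection-rate-vs-radius
behaviour of the discard rule is geometry-dependent: it is monotone
while strokes are small against the brain, and saturates on this
phantom at radii comparable to the brain itself.
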