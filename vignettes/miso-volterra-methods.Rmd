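---
title: "Modeling sub- and ultraharmonic microbubble echoes with MISO Volterra series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sub- and ultraharmonic microbubble echoes with MISO Volterra series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misovolterra)
```

## The problem

Ultrasound contrast agents are gas-filled microbubbles a few micrometres in
diameter. Driven near twice their resonance frequency at clinical pressures,
they oscillate nonlinearly and their echo contains, besides harmonics of the
transmit frequency $f_0$, a *subharmonic* at $f_0/2$ and *ultraharmonics* at
$3f_0/2, 5f_0/2, \dots$ Tissue generates harmonics but essentially no
half-integer lines, so sub/ultraharmonic imaging separates agent from tissue
better than second-harmonic imaging. Doing that separation with a parametric
signal model requires a model class that can actually *represent*
half-integer lines.

A discrete Volterra model of order $P$ and memory $M$,

$$\hat y(n) = h_0 + \sum_{k_1} h_1(k_1)\,x(n-k_1)
  + \sum_{k_1,k_2} h_2(k_1,k_2)\,x(n-k_1)x(n-k_2)
  + \sum_{k_1,k_2,k_3} h_3(\cdot)\,x(n-k_1)x(n-k_2)x(n-k_3),$$

is linear in its kernels $h_p$, so the kernels can be identified by least
squares from one input--output record. But products of lagged copies of a
single tone at $f_0$ only contain the frequencies
$\{0, f_0, 2f_0, 3f_0\}$: a single-input (SISO) Volterra model **cannot**
produce output energy at $f_0/2$ no matter how its kernels are chosen. The
package turns this statement into a machine-checked property (the
"spectral closure" tests): for a pure-tone input, the fraction of predicted
energy outside those lines is below $10^{-10}$.

The remedy is structural. Split the excitation into $N$ sub-inputs
$x(n) = \sum_{i=1}^N \alpha_i \Psi_i(n)$ where each $\Psi_i$ is periodic
with period $N/f_0$ -- hence carries a spectral component at $f_0/N$ -- and
feed each sub-input to its own SISO Volterra branch, summing the branch
outputs (a MISO system). With $N = 2$, cubic products of lines at
$\{f_0/2, f_0\}$ reach every half-integer multiple up to $3f_0$, so sub- and
ultraharmonics become representable. A third requirement, easy to overlook,
makes the decomposition useful in practice: the sub-inputs should be
**mutually orthogonal**, so that the joint least-squares problem is well
conditioned and the branches model complementary parts of the signal.

## The two bases

Both bases are exposed as first-class decompositions returning the
components $\Psi_i$, the reconstruction coefficients $\alpha_i$, and an
orthogonality report.

**Gated (rectangular) basis -- `decompose_rect()`, model "MISO1".**
Component $i$ keeps every $N$-th carrier period of $x$, starting at period
$i-1$, and is zero elsewhere; $\alpha_i = 1$. The components partition the
signal sample-by-sample, so reconstruction is exact, and their disjoint
supports make them exactly orthogonal. The published description of this
gate (a rectangular function convolved with a period-$N/f_0$ comb) contains
a typographical slip in its support bounds; we realize it as exact
sample-index gating with period boundaries at multiples of $f_s/f_0$
samples, aligned to the record start. This requires $f_s/f_0$ to be an
integer (15 for the default 4 MHz at 60 MHz); non-integer ratios raise an
error instructing the user to resample rather than silently rounding.

**Hilbert-quadrature basis -- `decompose_hilbert()`, model "MISO2".** With
$\tilde x = \mathcal H(x)$ the Hilbert transform and $\omega_0 = 2\pi f_0$,

$$\Psi_i(n) = x(n) + (-1)^{i-1}\left[x(n)\cos\!\big(\tfrac{N-1}{N}\omega_0 n T_s\big)
 + \tilde x(n)\sin\!\big(\tfrac{N-1}{N}\omega_0 n T_s\big)\right],$$

with $\alpha_i = 1/2$ for $N = 2$. The quadrature pair
$(x\cos + \tilde x\sin)$ shifts a band-limited excitation down to $f_0/N$;
the alternating sign puts the subharmonic parts of the two components in
antiphase, which is why they cancel in the reconstruction and why the
components are orthogonal over an integer number of subharmonic periods.
For a pure cosine and $N=2$ the components reduce to
$A\cos(\omega_0 nT_s) \pm A\cos(\omega_0 nT_s/2)$, a closed form the tests
check to $10^{-10}$.

The analytic signal is computed by the one-sided-FFT method on the full
record, without windowing (no installed package provides it, so the
ten-line primitive is implemented here). For bursts covering an integer
number of carrier periods the transform is exact; for very short or
non-integer records edge effects of order $1/L$ appear, which is a
documented limitation.

Only $N = 2$ is validated: the subharmonic of interest sits at $f_0/2$, and
published reconstruction coefficients exist only for that case. The code
paths accept general $N$; for the quadrature basis $N \ne 2$ warns and uses
$\alpha_i = 1/N$ (exact reconstruction only for even $N$).

## Identification

Kernels are stored in **symmetric-unique** form ($k_1 \le k_2 \le k_3$,
lexicographic; `volterra_terms()` fixes the column order), because the full
product enumeration is rank-deficient by permutation symmetry. The
parameter count is $1 + M + M(M+1)/2 + M(M+1)(M+2)/6$ (1540 at $M = 19$).
`expand_kernels()` reconstructs full symmetric tensors, dividing each
unique coefficient among the distinct permutations of its lag multiset.

The least-squares problem is solved with an SVD pseudo-inverse, relative
singular-value cutoff $10^{-10}$, optional ridge parameter (default 0).
Two numerical choices matter:

* **Column equilibration.** Regressor columns are scaled to unit norm
  before the SVD and coefficients rescaled afterwards. With a drive
  expressed in pascals ($\sim 10^6$), cubic columns are $\sim 10^{12}$
  times larger than linear ones and a relative cutoff would otherwise
  discard the entire linear block. Equilibration leaves the column space --
  hence fitted values and RMSE -- unchanged.
* **Minimum-norm solutions.** For a pure-tone excitation the regressor
  matrix has tiny numerical rank (about 7 for SISO: DC plus quadrature
  pairs at $f_0, 2f_0, 3f_0$), and for $M = 19$ on a 270-sample record the
  matrix is wider than tall. The pseudo-inverse returns the minimum-norm
  kernel set; predictions are the unambiguous quantity, and the spectral
  content of the prediction is what the scientific claims are about.

Valid rows follow the convention $n \in [M-1, L-1]$ (0-based), i.e.
$L-M+1$ rows; predictions before $n = M-1$ are emitted as zeros and flagged
via a `valid_from` attribute, and all error measures are computed over the
valid rows only. (The published index range is ambiguous about whether its
upper bound is the last index or the length; we fix the half-open, 0-based
reading.)

The MISO fit (`fit_miso()`) concatenates the per-branch regressor blocks
and solves one joint least-squares problem by default. With the gated
basis, branch regressors of adjacent gates overlap for up to $M-1$ samples
(memory spill-over), so independent per-branch fits (`fit_mode =
"parallel"`) are only an approximation; the two coincide exactly when the
branch spans are orthogonal, which the tests exhibit with a gated cosine,
$M = 1$, and odd-order kernels. Each branch carries its own constant term,
so only the *total* constant is identifiable in the joint solve (the
minimum-norm solution splits it equally); all non-constant coefficients are
unique. No cross-branch product terms are included by default -- the model
class is strictly $N$ parallel SISO branches -- but `cross_terms = TRUE`
augments the joint design with the mixed monomials for research
comparisons.

**On branch-output orthogonality.** For the gated basis, branch outputs
(beyond their constants) have disjoint supports up to the $M-1$-sample
spill-over and are therefore orthogonal, which the tests verify at
$M = 1$ exactly. For the quadrature basis the analogous statement is *not*
true for arbitrary kernels: a memoryless quadratic branch pair on
$\Psi_{1,2} = \cos(\omega_0 t) \pm \cos(\omega_0 t/2)$ yields a normalized
branch-output inner product of $0.25/2.25 \approx 0.11$ (time averages
$\langle\cos^4\rangle = 3/8$, $\langle c^2 s^2\rangle = 1/4$). Input
orthogonality -- the property the identification actually relies on -- holds
for both bases and is what `check_orthogonality()` certifies; we therefore
do not assert output orthogonality for the quadrature basis.

## The echo simulator

`simulate_echo()` integrates a shell-modified Rayleigh--Plesset equation
for the bubble radius $R(t)$:

$$\rho\big(R\ddot R + \tfrac32 \dot R^2\big)
 = p_0\Big(\frac{r_0}{R}\Big)^{3\kappa} - p_0 - p_i(t)
 - \frac{4\mu_L \dot R}{R}
 - \frac{12\eta\, d_{Se} r_0^2 \dot R}{R^4}
 - \frac{12 G_s d_{Se} r_0^2}{R^3}\Big(1 - \frac{r_0}{R}\Big),$$

the canonical thin-shell form whose parameters match the tabulated agent
description: resting radius $r_0 = 1.5\,\mu$m, shell thickness
$d_{Se} = 1.5$ nm, shell shear modulus $G_s = 10$ MPa, shell viscosity
$\eta = 1.49$ Pa s. Ambient constants are not part of that description and
are set to water at $\rho = 1000$ kg/m$^3$, $\mu_L = 10^{-3}$ Pa s,
$p_0 = 101.325$ kPa, with polytropic exponent $\kappa = 1.07$ (air,
near-adiabatic at this bubble size); all are overridable through
`bubble_params()`. Linearizing about $R = r_0$ gives the undamped
resonance

$$f_{\mathrm{res}} = \frac{1}{2\pi}\sqrt{\frac{3\kappa p_0 + 12 G_s d_{Se}/r_0}{\rho r_0^2}},$$

implemented in `resonance_frequency()`; it reduces to the Minnaert
frequency when the shell terms vanish and evaluates to about 2.24 MHz for
the defaults, so the 4 MHz transmit drives the bubble near twice resonance
-- the classic parametric regime for subharmonic generation.

Numerical choices: integration uses a stiff-capable adaptive solver
(`deSolve::ode`, method `lsodar`) at `rtol = 1e-8`, `atol = 1e-12` on both
$R$ and $\dot R$; the sampled burst is interpolated with a natural cubic
spline for the continuous-time forcing; a root function stops integration
if $R$ falls below 1% of $r_0$ and reports the collapse time; any other
solver failure surfaces its diagnostics rather than returning partial
output. The scattered far-field pressure is
$p_s \propto \rho (R^2\ddot R + 2R\dot R^2)$, the second derivative of the
bubble volume up to the $1/\text{distance}$ factor; since kernel
identification is scale-invariant, the echo is normalized to unit peak by
default (raw scale kept as an attribute). A cloud of $N_b$ bubbles is
modeled as $N_b$ identical non-interacting scatterers (exact linear
scaling, tested).

The burst is $x(t) = p\,\sin(2\pi f_0 t)$ with a rectangular envelope, 18
cycles at $f_0 = 4$ MHz, $p = 1.2$ MPa, $f_s = 60$ MHz (270 samples). The
published description says only "a sinusoidal wave"; we start the sine at
zero to avoid a pressure step at burst onset. 1.2 MPa is the low end of the
pressure window known to generate sub/ultraharmonics while limiting bubble
destruction; destruction itself is not modeled.

**What the simulator does and does not emulate.** It reproduces the
physics that matters for the modeling question: strong harmonics,
period-doubled oscillation with a pronounced subharmonic and
ultraharmonics, and realistic onset transients. It does not include
multi-bubble interaction, polydispersity, shell rupture, tissue
propagation, or transducer bandpass effects. One consequence worth
flagging: the subharmonic *grows* over the burst before saturating, so its
spectral line carries amplitude-modulation sidebands, and harmonics above
$3f_0$ exist; neither is representable by any third-order model driven by
a pure tone (SISO or MISO), so they set the floor of the achievable fit.
Passing tests therefore demonstrate correct identification on echoes with
this structure, not performance on measured agent data.

## Evaluation protocol

The figure of merit is the relative mean square error
$\mathrm{RMSE} = \mathbb E[(\hat y - y)^2] / \mathbb E[y^2]$, estimated by
sample means over the valid rows and reported as $10\log_{10}$ (dB): 0 dB
for a zero prediction, more negative is better. `run_sweep()` executes the
full protocol: simulate the echo once, then for each SNR level and
realization add white Gaussian noise of variance
$\mathrm{var}(y)/10^{\mathrm{SNR}/10}$ to the *output*, fit every method
and memory to the noisy record, and score in-sample. Defaults: memories
$\{2, 5, 10, 19\}$ (a sampled version of the 1..19 grid, dominated by its
end point where all methods are closest to their asymptote), SNR
$\{\infty, 20, 15, 10\}$ dB, 10 realizations, with noise shared across
methods and memories within a realization so comparisons are paired.

Two protocol decisions were genuinely open and are worth recording:

* **Reference under noise.** The RMSE is computed against the *noisy*
  output that was fitted -- an identification protocol, under which every
  method flattens at the noise floor ($-\mathrm{SNR}$ dB) as memory grows.
  The alternative (score against the clean output) is available via
  `reference = "clean"`.
* **In-sample evaluation.** A single backscattered burst is both the
  training and the evaluation record, matching how the model is used;
  the harness accepts arbitrary `x`/`y` overrides so held-out protocols
  can be composed by hand.

Seeds: every noise draw derives deterministically from the config seed, so
identical configs give bit-identical sweep tables (tested). Internally the
sweep caches the SVD of each (method, memory) design -- the excitation is
fixed, so only the projection of each noisy output changes; this is
mathematically identical to refitting per cell and keeps the full protocol
(12 designs, 40 noisy records, 480 cells) around a few seconds.

The headline comparison (`sweep_gap()`) is the difference between the mean
SISO RMSE and the mean RMSE of the *worse* MISO variant at $M = 19$, per
SNR: a conservative summary of what the orthogonal decomposition buys. On
the simulated echo the gated basis also captures part of the
amplitude-modulation sidebands (its gated components are broadband, giving
the joint design a numerical rank near 30, against 13 for the quadrature
basis), so MISO1 typically fits a few dB better than MISO2 at high SNR;
the two model exactly the same half-integer lines, which is the property
that separates both from SISO.

## Problem sizes and runtime

All tests run on signals of at most a few thousand samples. The echo
simulation (270 samples, stiff regime) takes about a second; the largest
least-squares design is $252 \times 3080$ ($M = 19$ MISO), whose SVD is
well under a second; the full evaluation protocol completes in a few
seconds thanks to the design cache. The frequency-sweep resonance check
uses 7 low-amplitude simulations at 30 MHz sampling.

## Known limitations

* Orders above 3 are out of scope (transducer bandwidths rarely admit
  more); recursive/adaptive identification and frequency-domain kernel
  estimation are not provided.
* The quadrature basis assumes a band-limited excitation; heavily
  broadband inputs degrade both the down-shift and the Hilbert transform.
* Only $N = 2$ is validated end-to-end.
* The joint MISO constant is identifiable only in total (see above).
* The simulator is a single-bubble model with linear cloud scaling; it is
  not a calibrated replica of any particular measurement chain, and
  quantitative results on measured echoes will differ.
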