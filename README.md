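# misovolterra

Nonlinear system identification of ultrasound contrast-agent (microbubble)
echoes with Volterra series, for researchers in contrast imaging and
nonlinear acoustics who need a parametric model of the echo that includes
its **sub- and ultraharmonic** content.

## The problem and the model

Microbubbles insonified near twice their resonance frequency respond with
spectral lines at $f_0/2,\ 3f_0/2,\ 5f_0/2,\dots$ in addition to harmonics.
A single-input Volterra model of order $P$ and memory $M$,

$$\hat y(n) = h_0 + \sum_{k_1=0}^{M-1} h_1(k_1)x(n-k_1)
 + \sum_{k_1\le k_2} h_2(k_1,k_2)x(n-k_1)x(n-k_2)
 + \sum_{k_1\le k_2\le k_3} h_3(\cdot)\,x(n-k_1)x(n-k_2)x(n-k_3),$$

identified by least squares, can only place output energy at integer
multiples of a pure-tone input frequency — it structurally cannot model
the half-integer lines. This package implements the multiple-input
single-output (MISO) extension: the excitation is decomposed as
$x = \sum_{i=1}^N \alpha_i \Psi_i$ into periodic, mutually **orthogonal**
sub-inputs with a spectral component at $f_0/N$, each driving its own SISO
Volterra branch. Two decompositions are provided:

* **MISO1** — period-gated (rectangular) basis: component $i$ keeps every
  $N$-th carrier period of $x$ ($\alpha_i = 1$, exactly orthogonal by
  disjoint support);
* **MISO2** — Hilbert-quadrature basis:
  $\Psi_i = x + (-1)^{i-1}\big[x\cos(\tfrac{N-1}{N}\omega_0 nT_s) +
  \tilde x\sin(\tfrac{N-1}{N}\omega_0 nT_s)\big]$ with
  $\tilde x = \mathcal H(x)$ ($\alpha_i = 1/2$ for $N = 2$).

Also included: a shell-modified Rayleigh–Plesset microbubble simulator
(thin-shell elastic and viscous terms, stiff-capable integration, collapse
detection), least-squares kernel identification via a rank-revealing
pseudo-inverse with column equilibration, and an evaluation harness that
sweeps memory and output SNR over repeated noise realizations using the
relative mean square error
$\mathrm{RMSE} = \mathbb E[(\hat y - y)^2]/\mathbb E[y^2]$ in dB.

See the methods vignette (`vignettes/miso-volterra-methods.Rmd`) for the
model details, assumptions, and numerical choices.

## Worked example

```r
library(misovolterra)

burst <- make_burst(f0 = 4e6, pressure = 1.2e6, cycles = 18, fs = 60e6)
echo  <- simulate_echo(burst, bubble_params())   # 1.5 um shelled bubble

resonance_frequency(bubble_params())             # 2.24 MHz: f0 ~ 2 x fres
sp <- signal_spectrum(echo)
10 * log10(band_energy(sp, 2e6) / band_energy(sp, 4e6))
#> -7.1    # strong subharmonic, 7 dB below the fundamental

siso  <- fit_siso(burst, echo, memory = 19)
miso1 <- fit_miso(burst, echo, "rect",    f0 = 4e6, memory = 19)
miso2 <- fit_miso(burst, echo, "hilbert", f0 = 4e6, memory = 19)
c(siso$rmse_db, miso1$rmse_db, miso2$rmse_db)
#> -4.24  -20.67  -10.91
```

The SISO fit stalls at −4.2 dB because roughly 38% of the echo energy sits
on half-integer lines it cannot represent (its glance shows numerical rank
7 out of 1540 parameters: DC plus quadrature pairs at $f_0, 2f_0, 3f_0$).
Both MISO variants model the sub- and ultraharmonic lines and cut the
error by 7–16 dB. `autoplot()` methods display signals, spectra, basis
components, and sweep results; `tidy()`/`glance()` extract kernels and fit
summaries.

The full noise study:

```r
cfg   <- experiment_config(seed = 1)   # M in {2,5,10,19}, SNR {Inf,20,15,10}, 10 realizations
sweep <- run_sweep(cfg)
summarize_sweep(sweep)
sweep_gap(sweep, memory = 19)          # SISO-vs-worse-MISO gap per SNR
autoplot(sweep)
```

A thin CLI over the same functions is installed at
`inst/scripts/misovolterra` (subcommands `simulate`, `decompose`, `fit`,
`sweep`).

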