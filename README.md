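# spatburst

Spatial stochastic modelling of bursty nuclear transcription.

Single-molecule imaging (smFISH and its successors) resolves the
positions of individual mRNA molecules inside the nucleus, but the
standard mechanistic models of gene expression only describe molecular
*counts*. `spatburst` implements a spatial extension of the two-state
(telegraph) transcription model for users who want to connect those
spatial snapshots to kinetic parameters: theorists studying spatial
point-process models of gene expression, and method developers
prototyping inference on subcellular-resolution data.

## The model

Transcripts appear at a gene site $z$ inside a nuclear domain
$\Omega$ at a rate switching between $\lambda$ ("on") and 0 ("off") at
promoter rates $\alpha$ (off→on) and $\beta$ (on→off); they diffuse
with diffusivity $D$, degrade at rate $\gamma$, and are exported at the
boundary with kinetics summarized by $\kappa \in [0, \infty]$
(reflecting → absorbing). A snapshot of the transcript positions
$x_1,\dots,x_n$ is a spatial **Cox process** driven by a stochastically
switching reaction–diffusion equation.

The package provides:

- **Closed forms (1D interval nucleus):** mean intensity
  $\langle u(x)\rangle$, mean count
  $\langle n\rangle = \lambda\rho S_\kappa/\gamma$ with
  $\rho = \alpha/(\alpha+\beta)$, and the retention factor
  $S_\kappa \in [0,1]$ (the probability a transcript is degraded before
  it is exported) for absorbing, Robin and reflecting boundaries.
- **Exact count-variance series** for the absorbing boundary, via the
  odd sine-mode expansion of the switching drive.
- **Poisson-beta approximation** of the full count distribution with
  spatially rescaled parameters
  $(\tilde\lambda,\tilde\alpha,\tilde\beta) =
  (S\lambda,S\alpha,S\beta)/\gamma$, with a numerically stable
  confluent-hypergeometric evaluation and a quadrature cross-check, and
  Jensen–Shannon divergence utilities for distribution comparison.
- **A particle-based stochastic simulator** (C++ core, exact promoter,
  Euler–Maruyama transport, first-passage-corrected absorbing and
  partially-reflected Robin boundaries; 1D, and 2D with heterogeneous
  Itô diffusivity).
- **A steady-state PDE solver** for irregular polygonal nuclei with
  spatially varying diffusivity, yielding the generalized scale factor
  that feeds the same Poisson-beta machinery.
- **Approximate Cox-process likelihood inference** over heterogeneous
  cell populations (per-cell geometry, shared kinetics), with
  Nelder–Mead maximum likelihood and profile-likelihood
  identifiability analysis for
  $\theta = (\lambda,\gamma,\alpha,\beta,\kappa)$ at known $D$.

## Worked example

```r
library(spatburst)
p   <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0.3)
dom <- domain_1d(R = 1)

scale_factor_S(p, dom)        # 0.3226
mean_count(p, dom)            # 1.6128   (non-spatial limit: 5)
var_count(p, dom)             # 3.2603   (exact series)
var_count(p, dom, "poisson_beta")  # 3.194
fano_spatial(p, dom)          # 1.9804   (non-spatial: 2.6667)

set.seed(1)
cts  <- simulate_counts(p, dom, sim_config(n_samples = 5000))
mean(cts)                     # 1.63
S    <- scale_factor_S(p, dom)
pred <- poisson_beta_pmf(spatial_rescale(p, S), n_max = max(cts) + 10)
jensen_shannon(pred, empirical_counts(cts, max(cts)))  # 0.000453
```

Read: with the gene site at $0.3R$ and an absorbing boundary, only 32%
of transcripts are degraded before export, so the mean count drops from
5 to 1.6 and the Fano factor from 2.67 to 1.98 — export removes
molecules before they are counted and suppresses the apparent
burstiness. A non-spatial telegraph fit to these counts would therefore
mis-estimate the promoter kinetics. The Poisson-beta prediction with
the rescaled parameters matches 5000 simulated snapshots to a
Jensen–Shannon divergence of 4.5e-4.

Inference on a heterogeneous synthetic population (each cell its own
radius and gene site, shared kinetics, truth
$\lambda=20,\gamma=1,\alpha=1,\beta=2,\kappa=5$):

```r
spec <- population_spec(M = 200, seed = 5)
pop  <- generate_population(spec)
fit  <- fit_mle(pop$patterns,
                theta0 = c(lam = 15, gamma = 1.4, alpha = 1.3,
                           beta = 1.5, kappa = 3), D_known = 1)
fit  <- profile_likelihood(fit, params = "gamma", n_grid = 13, span = 8)
fit$theta_hat        # lam 24.48, gamma 1.42, alpha 1.23, beta 1.84, kappa 7.82
fit$ci["gamma", ]    # 0.245 .. 2.908  (95% simultaneous, chi-sq 4 df)
```

All five parameters are identifiable from spatial snapshots — the
non-spatial count distribution alone carries only three identifiable
combinations.

A thin command-line front end (`inst/cli/spatburst-cli.R`) exposes
`simulate`, `fit` and `profile` over CSV/YAML files.

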