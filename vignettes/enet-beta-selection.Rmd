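---
title: "Coefficient-based variable selection for spectral calibration"
author: "enetbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coefficient-based variable selection for spectral calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enetbeta)
```

## The problem

Near-infrared (and related vibrational) spectroscopy predicts a reference
concentration $y$ from an absorbance spectrum measured on hundreds of
wavelength channels. Adjacent channels are almost linearly dependent —
correlations of 0.95 and above are routine — and most channels carry more
noise than quality-related information. A calibration model built on all
channels is therefore unstable and hard to interpret; selecting the few
quality-related channels improves both.

This package implements a coefficient-based selection procedure built on
the elastic net, together with the standard comparators a chemometrician
would benchmark it against (PLS, PLS coefficient selection, forward
stepwise selection with BIC), the usual accuracy criteria, and a synthetic
spectrum generator so that every stage can be validated against a known
ground truth.

## Models

All fitting happens after column-wise standardization of $X$ and $y$ to
zero mean and unit sample standard deviation (denominator $n-1$; the same
convention is used everywhere in the package). Standardization statistics
are always estimated on the training data only and reused to transform
test data — anything else leaks held-out information into the model.
Predictions and all reported error criteria are mapped back to the
original concentration units.

**Elastic net.** `fit_enet()` solves the unnormalized naive problem

$$\hat\beta_{\mathrm{naive}} = \arg\min_\beta \;\|y - X\beta\|^2
  + \lambda_1\|\beta\|_1 + \lambda_2\|\beta\|_2^2,$$

and returns $\hat\beta = (1+\lambda_2/n)\,\hat\beta_{\mathrm{naive}}$,
which undoes the extra proportional shrinkage that the ridge term applies
on top of the lasso. The $L_1$ term produces exact zeros; the $L_2$ term
removes the lasso's $p > n$ saturation limit and yields the grouping
effect — strongly correlated channels receive similar coefficients, and
exactly duplicated channels receive equal ones (for $\lambda_2 > 0$).
Note the objective is *not* divided by $2n$: penalty values quoted here
are on the raw residual-sum-of-squares scale, and the all-zero solution
appears at $\lambda_1 \ge 2\max_j |x_j^\top y|$.

The solver is cyclic coordinate descent on the Gram form (covariance
updates), with the inner loop in C++. Convergence requires both a maximum
coefficient change below `tol` ($10^{-8}$) in a full sweep *and* a
subgradient KKT residual below `kkt_tol` ($10^{-7}$), so every returned
solution carries a stationarity certificate; `enet_kkt_residual()`
recomputes it on demand. A full regularization-path algorithm is
deliberately out of scope — solutions at the grid points are identical
optima, with far less machinery.

**PLS.** `fit_pls()` is single-response NIPALS with $X$-deflation: the
weight vector of each component is the normalized covariance $X^\top y$,
scores are orthogonal by construction, and the coefficient vector is
$W(P^\top W)^{-1}q$. With a full set of components PLS reproduces OLS. If
the response residual is exhausted early the achieved components are kept
with a warning. The test suite checks the implementation against the
independent Krylov-subspace characterisation of PLS1.

**OLS and the forward path.** `fit_ols()` solves the normal equations
(QR), with an explicit opt-in pseudo-inverse for rank-deficient designs.
`fss_bic()` runs the greedy forward path — each step adds the channel
producing the largest decrease in residual sum of squares, computed
exactly by Gram–Schmidt orthogonalization against the active set — capped
at $\min(p, n-2)$ variables, and picks the path size minimizing
$\mathrm{BIC} = n\log(\mathrm{SSR}/n) + k\log n$. The intercept-only model
(size 0) is a legitimate winner on pure-noise responses.

## The selection procedure

`enet_beta()` turns the elastic-net coefficients into an explicit,
RMSEP-guided subset choice:

1. fit the elastic net on all $p$ standardized channels;
2. rank channels by decreasing $|\hat\beta_j|$ (ties broken by channel
   index, so the ranking is deterministic);
3. for each prefix of the ranking, refit the elastic net *with the same
   penalties* on the prefix and record its RMSEP;
4. let $i^\*$ be the prefix size minimizing the RMSEP curve (smallest
   size on ties — parsimony);
5. relax: accept the smallest $i \le i^\*$ with
   $\mathrm{RMSEP}(i^\*)/\mathrm{RMSEP}(i) \ge \lambda$, the
   confidence-ratio rule (`ht_reduce()`, default $\lambda = 0.9$);
6. refit on the accepted prefix.

Design choices worth spelling out:

* **Candidate sizes stop at the elastic-net support size** $m$ (the
  number of nonzero coefficients) rather than running to $p$: prefixes
  beyond $m$ add channels the penalty already judged uninformative, and
  their refits only add noise to the curve. `full_path = TRUE` restores
  the literal $1..p$ behavior.
* **The RMSEP curve is cross-validated on the training set by default**
  (9-fold, seeded, per-fold standardization). Scoring the curve on the
  test set — as comparative tables in the calibration literature often
  do — leaks test information into selection; policy `"holdout"` is
  available to mirror that workflow explicitly.
* **Prefix refits reuse the full-fit penalties.** Re-tuning per prefix is
  possible in principle but makes the curve compare different estimators
  at different sizes; keeping $(\lambda_1,\lambda_2)$ fixed isolates the
  effect of the subset.
* **The relaxation rule is implemented literally as the printed ratio
  rule.** It is called "hypothesis testing" in parts of the literature,
  but no null distribution is defined; $\lambda$ acts as an accuracy
  budget: $\lambda = 0.9$ accepts up to an 11% RMSEP increase in exchange
  for a smaller model. `ht_reduce()` never enlarges the subset, returns
  size 1 as $\lambda \to 0^+$, and is monotone in $\lambda$.
* **Zero-valued curve entries** (interpolating fits) define the ratio as
  1 when both entries are zero and 0 otherwise, so degenerate curves
  cannot select an inconsistent size.

`pls_beta()` is the analogous coefficient rule for PLS: keep the shortest
prefix of the $|\beta|$ ranking carrying more than a fraction $\alpha$ of
the coefficient vector's $L_2$ norm. The strict inequality is relaxed to
$\ge$ at the boundary $\alpha = 1$ so selection always terminates with
the full set.

## Tuning parameters

| parameter | default | meaning |
|---|---|---|
| `lambda1` | tuned | $L_1$ weight, raw SSE scale; all-zero at $2\max|x_j^\top y|$ |
| `lambda2` | tuned | $L_2$ weight, raw SSE scale |
| `conf` | 0.9 | accuracy budget of the relaxation step |
| `folds` | 9 | CV folds, used for every cross-validated quantity |
| `alpha` | 0.9 | PLS-BETA norm-ratio threshold |
| `h` | tuned by CV | PLS components, $1 \le h \le \min(n-1, p)$ |

`enet_grid_search()` tunes $(\lambda_1, \lambda_2)$ by K-fold CV RMSEP
over a data-scaled grid: $\lambda_1$ on a log scale below the
full-shrinkage bound $2\max_j|x_j^\top y|$ (seven points spanning three
decades), $\lambda_2$ proportional to the Gram diagonal $n-1$ (ridge
strength relative to unit predictor variance: 0.01, 0.1, 1). Ties within
$10^{-12}$ go to the smallest $\lambda_1$, then the smallest $\lambda_2$
— deterministic, and biased toward the sparser solutions the procedure
exists to find. CV folds are contiguous blocks of a seeded shuffle, so
every cross-validated quantity is reproducible from the seed.

## Evaluation criteria

On the original $y$ scale: $\mathrm{RMSEP} = \sqrt{\sum_i(y_i-\hat
y_i)^2/n}$ (a `root = FALSE` switch reproduces the plain mean square for
comparability with reports that quote it without the radical);
$\mathrm{NMSE} = \sum_i(y_i-\hat y_i)^2 / \sum_i y_i^2$, implemented with
the aggregate denominator since a per-term division explodes at
$y_i = 0$; $R^2 = 1 - \mathrm{SSR}/\mathrm{SST}$. AIC/BIC use the
Gaussian likelihood with the error variance profiled out and shared
constants dropped, so only differences across models fit to the same data
are meaningful; an SSR below the variance floor ($10^{-12} n$) is clamped
with a warning rather than producing $-\infty$ for interpolating fits.

## The synthetic generator

`simulate_spectra()` emulates the regime these methods are designed for,
not any particular instrument:

* **Smooth collinear channels.** Each spectrum is a random mixture of
  densely overlapping Gaussian peak profiles plus stationary AR(1)
  channel noise with autocorrelation `rho`. The peak width is matched to
  `rho` (solving $e^{-1/(4w^2)} = \rho$, the adjacent-channel correlation
  of a squared-exponential channel covariance), so `rho` genuinely is the
  neighbor-correlation dial for both components: at `rho = 0.95` the
  median adjacent correlation is about 0.95, and correlation decays with
  channel distance the way overlapping absorbance bands decay — channels
  two or three apart are markedly less redundant than direct neighbors.
* **Clustered sparse truth.** The true support consists of contiguous
  channel *pairs* near peak centres, constant sign within a pair,
  magnitudes uniform on $[0.5, 1.5]$. Pairs are the minimal grouping
  unit: they exercise the elastic net's grouping effect the way real
  absorbance bands do, while keeping every support channel identifiable.
  Longer contiguous runs at this correlation level are not a fair
  recovery target — a single channel proxies the run at correlation
  0.99+, so no selection method could resolve the interior members.
* **Noise calibrated by variance ratio.** $y = X\beta_{\mathrm{true}} +
  \varepsilon$ with $\mathrm{sd}(\varepsilon)$ set from the sample signal
  variance so that $\mathrm{var(signal)}/\mathrm{var}(\varepsilon)$
  equals the requested `snr`.

What passing tests on this generator do *not* show about real spectra:
there is no baseline drift, no multiplicative scatter, no wavelength
miscalibration, no Beer–Lambert nonlinearity, and the noise is Gaussian
and homoscedastic. Results on real instruments depend on preprocessing
choices this package deliberately does not make (see Limitations).

## Study sizes and what the checks show

The package's own validation works at sizes a single CPU handles in
minutes: the recovery study uses 20 replicate datasets of $n = 400$
samples by $p = 100$ channels with 10 true channels at `snr = 50` and
`rho = 0.95`; the five-method benchmark runs on a 415/108 train/test
split of the same regime, the dimensions of the classic wheat-kernel
protein benchmark. On those conditions the coefficient ranking plus
RMSEP-minimum stages recover the support nearly perfectly (mean
sensitivity about 0.97 at $i^\*$), and the confidence-ratio relaxation
then deliberately trades the two or three weakest pair-partners for a
smaller model — mean sensitivity about 0.78 at $i_{HT}$ with essentially
no false positives. That trade is the rule working as designed: with
$\lambda = 0.9$, any channel whose removal costs less than an 11% RMSEP
increase is expendable, and at `snr = 50` a $|\beta| \approx 0.5$ channel
whose partner is 0.95-correlated costs less than that. Users who need
maximal sensitivity rather than maximal parsimony should read the
selection at $i^\*$ (or raise `conf` toward 1); users who want the
sparsest accurate model are exactly who the relaxation serves.

```{r recovery, eval = FALSE}
sim <- simulate_spectra(n = 400, p = 100, k_true = 10, rho = 0.95,
                        snr = 50, seed = 1)
gs <- enet_grid_search(sim$data, folds = 9, seed = 1)
sel <- enet_beta(sim$data, lambda1 = gs$lambda1, lambda2 = gs$lambda2,
                 conf = 0.9, folds = 9, seed = 1)
score_recovery(sel$selected, sim$truth)
score_recovery(sel$ranking[seq_len(sel$i_star)], sim$truth)
```

## Numerical choices and degenerate inputs

* Sample standard deviations use denominator $n-1$ throughout; the
  convention is stated because "unit variance" alone does not fix it, and
  mixing conventions would silently rescale the penalties.
* Zero-variance channels are an error naming the offending channel, not a
  silent drop; missing values are rejected, not imputed.
* Coordinate-descent convergence is certified by the KKT residual, not
  only by step size; non-convergence is an error reporting the residual.
* Ties: coefficient ranking breaks ties by ascending channel index;
  RMSEP-curve minima go to the smaller size; grid-search ties go to the
  smaller penalties; the forward path breaks SSR ties by ascending
  channel index. Every tie rule is deterministic and tested.
* Seeds control every random partition (splits, folds, the generator);
  repeated calls with the same seed are identical, and the RNG state of
  the session is restored afterwards.

## Limitations

* Single response only; the multi-response extension changes the algebra
  of both PLS and the coefficient rules.
* No spectral preprocessing (SNV, MSC, derivatives, baseline correction);
  apply it upstream if the instrument requires it.
* The elastic net is solved at given penalties; the full LARS-type
  solution path is out of scope.
* AIC/BIC values are comparable only across models fit to the same
  dataset, by construction.
* The generator is a test substrate, not a forward physical model of any
  spectrometer.
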