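---
title: "Training logistic regression on encrypted data with a simplified fixed Hessian"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training logistic regression on encrypted data with a simplified fixed Hessian}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfhe)
```

## The problem

A hospital or a bank wants a cloud service to *train* a binary
classification model on its records without the service ever seeing a single
record. Somewhat-homomorphic encryption (SHE) permits a limited number of
additions and multiplications directly on ciphertexts, so in principle the
server can run a training algorithm on encrypted data and return an
encrypted model that only the data owner can decrypt. In practice, standard
training algorithms are hopeless under SHE: every extra multiplicative level
costs noise budget and parameter size, there is no division, no comparison,
and no sigmoid. `sfhe` implements a training algorithm engineered for this
regime, together with the full encryption stack it runs on.

The model is binary logistic regression with labels $y \in \{-1, +1\}$ and
records $\mathbf{x} = (1, x_1, \dots, x_d)$:

$$\Pr(y \mid \mathbf{x}, \boldsymbol\beta)
  = \sigma(y\,\boldsymbol\beta^T\mathbf{x})
  = \frac{1}{1 + e^{-y \boldsymbol\beta^T \mathbf{x}}},$$

trained by maximising the log likelihood
$\ell(\boldsymbol\beta) = -\sum_i \log(1 + e^{-y_i \boldsymbol\beta^T
\mathbf{x}_i})$.

## The simplified fixed Hessian (SFH) trainer

Newton--Raphson computes
$\boldsymbol\beta_{k+1} = \boldsymbol\beta_k - H^{-1}(\boldsymbol\beta_k)
\nabla \ell(\boldsymbol\beta_k)$, which requires re-evaluating and inverting
the Hessian every iteration — unusable under encryption. Three
simplifications produce the SFH method; each is an exact, testable
mathematical statement rather than a heuristic:

1. **Fixed Hessian bound.** Because $\sigma(1-\sigma) \le \tfrac14$, the
   Hessian satisfies $H(\boldsymbol\beta) \ge \bar H = -\tfrac14 X^TX$ in
   the Loewner ordering for *every* $\boldsymbol\beta$ (Böhning–Lindsay
   lower-bound principle), and a Newton method that replaces $H$ by a fixed
   symmetric negative-definite lower bound still converges.
   `fixed_hessian()` computes $\bar H$.
2. **Diagonalisation by Gerschgorin.** Inverting a dense $(d+1)^2$ matrix
   under encryption is not realistic, so $\bar H$ is replaced by the
   diagonal matrix $\tilde H$ of its *row sums*. For any symmetric matrix
   with non-positive entries, the Gerschgorin circle theorem puts every
   eigenvalue of $\bar H - \tilde H$ at or above zero, so
   $H \ge \bar H \ge \tilde H$ and convergence survives
   (`simplified_hessian_diag()`, `loewner_nonneg()`; the property suite
   checks the chain on random designs). The diagonal is computed row-sum
   first — $\tilde H_{kk} = -\tfrac14 \sum_i x_{ik} r_i$ with
   $r_i = \sum_j x_{ij}$ — which costs $N(d+1)$ scalar multiplications
   instead of the $O(Nd^2)$ of forming $X^TX$.
3. **Division-free inversion and a linear sigmoid.** Each diagonal entry is
   inverted with the multiplicative Newton iteration
   $x_{k+1} = x_k(2 - a x_k)$, which converges to $1/a$ from any
   $0 < a x_0 < 2$ and after one step has relative error exactly
   $(1 - a x_0)^2$ — a start within 30% of the reciprocal gives an answer
   within 9% (`invert_scalar_newton()`). The sigmoid inside the gradient is
   replaced by its tangent at the origin, $\sigma(z) \approx \tfrac12 +
   \tfrac{z}{4}$, making the Taylor gradient affine in $\boldsymbol\beta$:
   $\nabla \ell \approx \tfrac12 X^Ty - \tfrac14 X^TX\boldsymbol\beta$.

`sfh_train()` starts from $\boldsymbol\beta = 0$ (the natural depth-minimal
start: there the Taylor gradient is just $\tfrac12 X^Ty$) and iterates
$\boldsymbol\beta \leftarrow \boldsymbol\beta - \tilde H^{-1}
\nabla_{\textrm{taylor}}\ell(\boldsymbol\beta)$ with $\tilde H$ and its
(exact or one-step-Newton) inverse computed once before the loop. As the
iteration count grows it converges to the fixed point
$\boldsymbol\beta^* = 2 (X^TX)^{-1} X^Ty$ of the Taylor gradient; the
prediction side (`predict_proba()`) always uses the true sigmoid.

The maximum-likelihood reference `irls_reference()` (IRLS via `glm.fit`,
the analogue of Matlab's `glmfit` used in the original experiments) is the
accuracy oracle: models are compared by test-set AUC (`roc_auc()`), the
area under the (FPR, TPR) sweep of the classification threshold
$\tau$ with the inclusive rule "predict $+1$ iff $p \ge \tau$". The AUC
equals the Mann–Whitney statistic and is checked against it, and against
`pROC`, in the tests.

### The Newton start value

The entries of $\tilde H$ scale like $-\tfrac14 N (d+1) \mathbb{E}[x]^2$,
so `newton_x0()` uses $x_0 = -4 / ((d+1) N \mu)$ with $\mu = 1$ for binary
covariates and $\mu = \tfrac12$ for min-max-normalised continuous ones —
public dataset metadata, not secrets. When the encoding base $b_w$ is
supplied, $|x_0|/4$ is snapped to the nearest *power of* $b_w$: the
encrypted circuit then encodes it as a single signed digit (exact) while
moving $x_0$ by at most a factor $\sqrt{b_w}$, deep inside the convergence
basin. The plaintext trainer accepts the same snapped $x_0$, so plaintext
and encrypted runs are comparable to machine precision.

## Fixed-point encoding: w-NIBNAF and CRT splitting

The FV plaintext space is $R_t = \mathbb{Z}_t[X]/(X^D+1)$; real numbers
must become small-coefficient polynomials. `nibnaf_encode()` expands
$\theta$ greedily in a non-integral base $1 < b_w < 2$ with digits in
$\{-1, 0, 1\}$ and at most one nonzero digit in any $w$ consecutive
exponents; negative exponents wrap into the top of the ring with a sign
flip via $X^{-j} = -X^{D-j}$ (`laurent_fold()`), which makes folding a ring
homomorphism — sums and products of encodings decode to sums and products
of the reals, as long as coefficients stay below $t/2$ and the positive and
fractional exponent ranges do not collide. Sparsity is the whole point: it
keeps coefficient growth during computation small, which keeps the
plaintext modulus $t$ small, which (see below) keeps the noise growth of
the scheme small.

Two numerical decisions are worth recording:

* **The base.** Only the constraints $1 < b_w < 2$ plus the digit and
  spacing properties are taken as given; the defining equation of the
  canonical base is not assumed. `nibnaf_base()` bisects for the largest
  base whose greedy expansions satisfy the $w$-spacing property on a probe
  set of worst-case (midpoint) inputs, then backs off by a factor 0.85 on
  $b - 1$. Every correctness test in the package depends only on the
  digit-set, spacing, sparsity and round-trip contracts, never on a
  specific base value.
* **Precision.** Digits below exponent $-P$ are truncated; the truncation
  tail is bounded by $b_w^{-P}/(1 - b_w^{-w})$, and the default $P$ targets
  an absolute round-trip error below $10^{-7}$ on $[-1, 1]$, one decimal
  order inside the $10^{-6}$ contract. Binary covariates, labels and
  integer constants are single-digit or single-coefficient encodings and
  therefore exact.

The noise analysis of the scheme caps the usable single modulus at some
$t_{\max}$ while decoding correctness demands some $t_{\min}$; when the two
are incompatible, $t$ is chosen as a product of small coprime factors and
the whole computation runs independently in each $R_{t_i}$
(`crt_split()` / `crt_join()`, Garner reconstruction with centred
representatives). The shipped presets follow the published
configurations: `"genomic"` ($w = 715$, $t = 5179\cdot5189\cdot5197$,
three-fold CRT) for binary data and `"financial"` ($w = 150$,
$t = 2237\cdot2239$) for continuous data, both at $D = 4096$; `"toy"`
($w = 6$, $t = 65537$, $D = 256$) exists for fast tests.

## The FV layer

`fv_keygen()` / `fv_encrypt()` / `fv_decrypt()` implement the
Fan–Vercauteren scheme over $R_q \times R_q$ with a ternary key
distribution, discrete Gaussian errors ($\sigma = 20$, truncated at
$6\sigma$), $\Delta = \lfloor q/t \rfloor$, and version-1 relinearisation
(base-$2^\omega$ decomposition key switching). Implementation choices:

* $q$ is restricted to powers of two ($q = 2^{186}$ at full scale), making
  the centring $[\cdot]_q$ a bit mask and the tensor scale-and-round
  $\lceil t\,c/q \rfloor$ an exact shift.
* Exact polynomial products (the tensor step needs the *integer* product
  of ciphertext polynomials, up to $\sim 2^{395}$ per coefficient at full
  scale) are computed by CRT over a fixed table of 59-bit NTT-friendly
  primes ($p \equiv 1 \bmod 8192$, supporting negacyclic transforms for
  every $D \le 4096$) and reconstructed with Garner's algorithm into
  512-bit integers. The contract is bit-exactness against a schoolbook
  negacyclic oracle, which the tests enforce at small $D$; this is an
  internal multiplication technique, not a residue-number-system scheme
  variant — ciphertexts are defined and stored mod $q$.
* `fv_noise_budget()` reports $\log_2(\Delta / 2\lVert e\rVert_\infty)$;
  decryption is exact while it is positive. The toy preset was sized
  empirically for the training circuit: its multiplicative depth is 4, and
  with relinearisation noise and a plaintext modulus wide enough for the
  circuit's coefficient growth ($t = 65537$), $q = 2^{140}$ leaves roughly
  60 bits of budget after one full iteration at $D = 256$. A 60-bit toy
  modulus, by contrast, is provably too small for depth 4 — fresh noise
  $\approx 2^{13}$ plus four levels of $\approx 21$ bits each exceeds its
  $\approx 2^{47}$ decryption margin — which is why the toy preset is
  larger than the smallest set on which single multiplications work.
* Security is a property of $(D, q, \sigma)$ asserted by configuration
  (the full-scale set is the published 78-bit configuration); nothing is
  re-estimated at runtime, and the toy set has no security at all.

A ciphertext serialises to exactly $2 D \log_2 q$ bits (`fv_pack()`):
190,464 bytes $\approx$ 186 kB at full scale. An encrypted dataset stores
$T(d+1)N$ ciphertexts — $d$ covariates plus the label per record and CRT
factor; the all-ones intercept column is public and never stored — for
$T(d+1)N \cdot 2D\log_2 q$ bits total (`encrypted_size_bits()`).

## One training iteration as a five-multiplication circuit

`encrypted_sfh_iteration()` evaluates, per CRT factor, the circuit

1. $h_k = \sum_i x_{ik} r_i$ with $r_i = 1 + \sum_j x_{ij}$ — the row-sum
   form of $-4\tilde H$ (stage 1; the $r_i$ themselves are additions only),
2. $G_k = \sum_i y_i x_{ik}$ — the gradient kernel at
   $\boldsymbol\beta = 0$ (stage 2),
3. $u_k = h_k \cdot u_0$ and
4. $\mathit{inv}_k = u_0 \cdot (2 - u_k)$ — one division-free Newton step
   for $1/h_k$ from the public start $u_0 = |x_0|/4 = b_w^{\,e}$
   (stages 3–4),
5. $\beta_k = \mathit{inv}_k \cdot 2G_k$ — the model update (stage 5),

for a total of **five ciphertext–ciphertext multiplication stages**, where
a stage applied elementwise across the $d+1$ coordinates counts once (the
`ct_mult_ops` field of the report counts the elementwise operations,
$2Nd + 3(d+1)$, which grow linearly in both $N$ and $d$). Three details
make the count and the accuracy work:

* **All scalar constants are exact.** The algebra
  $-\tilde H^{-1} \cdot \tfrac12 G \equiv \mathit{inv} \cdot 2G$ folds the
  $\tfrac14$ from the Hessian bound and the $\tfrac12$ from the gradient
  into the single integer 2. Integers embed exactly as constant
  polynomials; encoding $\tfrac14$ or $\tfrac12$ as fixed-point expansions
  would instead add truncation error and inflate the fractional exponent
  span roughly three-fold, past what $D = 4096$ accommodates for the
  continuous preset.
* **The start value is a ciphertext.** $u_0$ is public, but it enters the
  circuit lifted to the trivial ciphertext $(\Delta m, 0)$, so stages 3–5
  are uniform ciphertext–ciphertext multiplications — this is the reading
  under which the advertised count of five is exact and independent of the
  data size.
* **Span bookkeeping.** The fractional exponent span of every intermediate
  is tracked through the circuit (spans add under multiplication), so
  decoding (`decrypt_model()`: per-factor decryption, CRT join, unfold,
  evaluate at $b_w$) knows which top coefficients are fractional and fails
  loudly if the positive and fractional ranges would overlap or a
  coefficient reaches the modulus boundary.

Further iterations re-linearise the Taylor gradient around the current
model: $\boldsymbol\beta \leftarrow \boldsymbol\beta + \mathit{inv}\,(2G -
M)$ with $M_k = \sum_i x_{ik}(\mathbf{x}_i^T\boldsymbol\beta)$, three more
stages each ($\tilde H$ and $\mathit{inv}$ are never recomputed). Depth
grows accordingly; the shipped parameter sets are provisioned for the
single iteration the method is designed around, and the noise budget of
anything deeper should be checked with `fv_noise_budget()` before trusting
the result.

The same circuit runs over plain ring elements in each $R_{t_i}$
(`rt_sfh_iteration()`), with identical topology and instrumentation. This
is both a fast simulator and the package's strongest correctness oracle:
whenever the noise budget stays positive, the decrypted circuit equals the
$R_t$ circuit *coefficient for coefficient*, and the tests assert exactly
that, alongside agreement of the decoded model with the plaintext
Newton-mode `sfh_train()` (exact for binary data, within the encoding
tail for continuous data).

## What the synthetic data does and does not show

Neither study dataset (a cancer-genomics matrix of 1581 records with 103
binary covariates; a fraud table of 20,000 records with 32 min-max-normalised
continuous covariates) is public, so `gen_synthetic()` emulates their
*shapes*: binary covariates are Bernoulli with per-column success
probabilities drawn from $[0.1, 0.5]$, continuous covariates are Uniform on
$[0, 1]$, and labels are drawn from the logistic model itself,
$y_i = +1$ with probability $\sigma(\boldsymbol\beta_{\text{true}}^T
\mathbf{x}_i)$. `gen_beta_true()` draws the true coefficients as zero-sum
Gaussian contrasts with zero intercept, scaled so the linear predictor's
standard deviation is 5 for continuous data and 1 for binary data. Those
calibrations are chosen to land the maximum-likelihood reference in the AUC
regimes of the two applications being emulated (roughly 0.93–0.97 for the
financial-style shape, weaker for the genomic-style shape) with balanced
class prevalence; the zero-sum centring puts the signal into covariate
*contrasts* rather than the overall covariate mean.

Two honest caveats, both visible in the test suite:

* A *single* SFH iteration estimates the update direction from
  $\tfrac12 X^Ty$ scaled by a diagonal. The realised class imbalance of a
  finite training sample ($\sum_i y_i \sim \sqrt{N}$ even at balanced
  prevalence) enters that direction as a common offset along the
  covariate-mean direction, which a full-matrix (or iterated) method
  cancels through the intercept. With mean-$\tfrac12$ uniform covariates
  this offset is material: across random seeds the one-iteration model's
  test AUC typically tracks the IRLS reference closely but falls
  noticeably behind on seeds with larger sampled imbalance, while running
  more iterations closes the gap in every seed (the accuracy-parity test
  records both effects). Real covariates with small means — sparse
  financial features — are correspondingly less affected, which is
  consistent with the small one-iteration gaps reported for the original
  (private) data.
* Synthetic covariates are independent within a record. Real genomic or
  financial covariates are correlated, which changes how well a diagonal
  Hessian bound approximates the true curvature; passing tests here do not
  quantify that effect.

## Problem sizes used by the checks

The test suite and the acceptance script are sized for a single CPU:
scheme-level cases run at $D = 64$–256 with hundreds of random cases
against the schoolbook oracle; the end-to-end full-scale check encrypts
$N = 30$, $d = 5$ binary records under the genomic preset
($D = 4096$, $q = 2^{186}$, three CRT factors, ~540 encryptions and ~950
ciphertext multiplications) and finishes in about two minutes; the
accuracy-parity study uses 20 seeds of $N_{\text{train}} = 1000$,
$N_{\text{test}} = 5000$, $d = 31$ continuous records. The two published
full-scale dataset shapes (1581 × 103 binary, 20,000 × 32 continuous) are
generated and trained in plaintext as part of the suite.

## Limitations

* One-ciphertext-per-value layout: no SIMD batching of records into
  polynomial slots, no residue-number-system ciphertext arithmetic, no
  bootstrapping — the scheme is *somewhat* homomorphic and the circuit is
  budgeted for few iterations.
* Binary classification only; no regularisation, standard errors or
  p-values.
* The evaluating server learns dataset dimensions $(N, d)$, the data kind
  (through $\mu$ in the public start value) and the encoding
  configuration; these are treated as public metadata.
* Key material is held in one object for convenience;
  `fv_evaluation_keys()` strips the secret key for the server side, but no
  key-distribution protocol is provided.
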