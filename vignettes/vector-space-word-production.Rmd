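---
title: "A vector-space model of word production in verbal fluency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A vector-space model of word production in verbal fluency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfspace)
```

## The model

In a verbal fluency (VF) task a participant produces as many words as
possible from a given semantic category, and the cumulative word count
`n(t)` is analysed as a function of time. Two classical growth curves —
Bousfield's exponential and the hyperbolic alternative — are special
cases of the three-parameter *fused Bousfieldian function* (FBF)

$$n(t) = c\left[1 - \left(1 + \frac{\alpha r t}{c}\right)^{-1/\alpha}\right],$$

with asymptote $c$ (words), rate $r$ (reciprocal of the elementary
sampling-process duration, s$^{-1}$) and dimensionless shape factor
$\alpha$. When $c$ and $\alpha$ grow together with $k = c/\alpha$ fixed,
the FBF degenerates to the logarithmic curve

$$n(t) = k \ln(1 + r t / k),$$

which clinical VF datasets follow strikingly often. Under a
sampling-with-replacement account of retrieval, the time course encodes
the per-item retrieval probabilities through $p_{n+1} = n'(t_n)/r$, the
slope at the moment the $n$-th word is produced divided by the sampling
rate. For the logarithmic curve this sequence is exactly geometric,
$p_{n+1} = e^{-n/k}$, and a geometric probability sequence with ratio
$1/2$ is what a semantic store organised as *all* non-ordered tuples of
$i$ items delivers: after $n$ productions, $2^{i-n}$ of the $2^i$
tuples remain admissible (disjoint from the produced words, the empty
tuple included), so the per-draw success probability is $2^{-n}$.

The same power-of-two combinatorics appears in the Theory of
Connectivity, where a functional connectivity motif over $i$ inputs
comprises $2^i - 1$ neural cliques — the same enumeration minus the
empty ("inactive") tuple. The package treats the two countings as one
basis with a flag (`include_empty`), because including the inactive
state is precisely what unifies the two theories: it is the state the
production process rotates into, and it is what makes the initial state
factorizable.

### State space

`tuple_basis(items)` enumerates the $2^i$ tuples in ascending decimal
order, where bit $b$ of the index marks membership of the item at
position $b+1$ (the first item is the least-significant bit — the only
assignment consistent with the printed transcription table, which puts
$\{A\} = 1$, $\{B\} = 2$, $\{C\} = 4$). Activation states are unit
vectors over this basis: normalization $\sum_k |c_k|^2 = 1$ is a hard
invariant of every constructor, because produced words become
*inadmissible* (coefficient zero) while their representations remain
part of the network — the state's magnitude is conserved throughout.
Coefficients are signed reals; nothing in the model requires complex
phases, and they are deliberately out of scope.

A note on normalizers: the uniform three-item initial state has all
eight coefficients equal to $1/\sqrt 8$, the post-production state
$|x_C\rangle$ has four coefficients of $1/\sqrt 4$, and the minimal
matrix has entries $\pm 1/\sqrt 2$ — the square roots are forced by the
unit-norm constraint and by orthogonality, respectively.

### Rotations from one minimal matrix

Producing word $w$ is an orthogonal rotation $R_w$: on every coordinate
pair (tuple without $w$, same tuple plus $w$) it acts as

$$\rho = \frac{1}{\sqrt 2}\begin{pmatrix}1 & 1\\ -1 & 1\end{pmatrix},$$

and it touches nothing else; equivalently $R_w$ is a Kronecker product
of identities with $\rho$ on the factor of $w$ (the quantum-logic-gate
analogy). This blockwise construction is pinned to the worked examples:
it is the norm-preserving map that sends the uniform state to
$|x_C\rangle = (\tfrac12,\tfrac12,\tfrac12,\tfrac12,0,0,0,0)$ and, at
the end of the chain $R_C, R_B, R_A$, leaves the pure empty-tuple state
with coefficient $+1$ ("complete activation" of the inactive state).
The row orientation of $\rho$ — equal pairs map to (positive, 0) — is
the unique choice (up to global sign) consistent with those
non-negative printed states. Because the $R_w$ act on disjoint tensor
factors they commute, every one of them has the spectrum of $\rho$
($e^{\pm i\pi/4}$, each at multiplicity $2^{i-1}$), and all of them lie
in one similarity class: one minimal matrix drives the entire
production sequence. The similarity test compares spectra only, which
is sufficient because orthogonal matrices are normal; constructing an
explicit conjugating matrix is not needed and not attempted.

Operators are materialized as dense matrices up to $i = 12$
($4096^2$ entries); beyond that they stay matrix-free — application is
blockwise either way, and the spectrum is known analytically.

### Separability

Normalization constrains only magnitudes, so
$|\bar x\rangle$ — the uniform state with the empty-tuple coefficient
negated — is an equally valid initial state. The two differ in kind:
the uniform state factorizes into $i$ per-item factors
$(1/\sqrt2)(|0\rangle + |1\rangle)$, while $|\bar x\rangle$ admits no
rank-1 tensor factorization. `is_separable()` reshapes the coefficient
vector as an $i$-way tensor of extent 2 and declares separability when
the second singular value of every mode unfolding is below a tolerance
(default $10^{-9}$, appropriate for exactly-constructed
double-precision states; override it for states produced by long
floating-point pipelines). Factors are the leading singular vectors
with a fixed sign convention — first nonzero entry of each factor
non-negative, residual global sign absorbed into the last factor — and
a reconstruction check guards against accepting a near-rank-1 tensor
whose factors do not actually reproduce the coefficients.

## Fitting policy

The model family is fitted to a record of word onsets by unweighted
least squares of word index $j$ against onset $t_j$ — the traditional
plotting convention (time on the abscissa, word number on the
ordinate). The source material reports *that* datasets were classified
by curve family but not the objective function or the classification
statistic, so both are package policy, chosen to be the simplest
faithful reading of the Bousfield tradition:

* candidates: `fbf`, `logarithmic`, `exponential`, `hyperbolic`;
* optimizer: bounded Levenberg–Marquardt (`minpack.lm::nlsLM`), all
  parameters in $(10^{-6}, 10^6)$, fits ending on a bound flagged;
* starting values: $r_0 = 2/t_2$ from the first onsets,
  $c_0 = 1.5\times$ the observed word count, a grid over
  $\alpha_0 \in \{0.01, 0.1, 1, 10\}$ (FBF) and over
  $k_0 \in \{0.5, 1/\ln 2, 5, 20, n/2\}$ (logarithmic), best
  refined start kept;
* selection: minimum AICc computed from the Gaussian-SSE likelihood
  with $K = \#\text{parameters} + 1$; a candidate with fewer than
  $K + 2$ points gets an infinite criterion and cannot be selected, so
  meaningful four-way selection needs roughly six or more productions.
  Selection is by minimum only; no significance test is attached.

Word times are inverted from the monotone curves in closed form for the
logarithmic model ($t_n = (k/r)(e^{n/k} - 1)$) and by bisection
otherwise; `retrieval_probabilities()` then evaluates the analytic
derivative at those times. Bounded models refuse probability sequences
that run past their asymptote.

## The simulator

`simulate_run()` realises the sampling account directly: time advances
in elementary steps of exactly $1/r$ seconds per draw (no inter-draw
jitter), a draw at stage $n$ succeeds with probability $2^{-n}$
(`uniform_tuple` mode; the admissible-over-total tuple count) or $q^n$
(`geometric` mode, for arbitrary decay ratio $q \in (0,1)$), and a
success produces one still-unproduced word, chosen uniformly — the
source account never says *which* word an admissible tuple yields, and
by symmetry the choice cannot affect the timing law, so the uniform
rule is an explicit interpretation, not a fact of the model. Waiting
draws are sampled from the matching geometric distribution, which is
exactly equivalent to drawing tuples one by one. A per-run draw budget
(default $10^6$) bounds the exponentially growing waiting times; a run
that exhausts it is flagged `truncated`, never silently clipped. The
geometric mode exists because empirically fitted $k$ values differ from
$1/\ln 2$; setting $q = e^{-1/k}$ generalizes the admissibility decay
while preserving the geometric-sequence structure.

The continuum limit of the process is the rate equation
$dn/dt = r q^n$, i.e. the logarithmic curve with $k = 1/\ln(1/q)$
(`theoretical_curve()`); uniform-tuple sampling means
$k = 1/\ln 2 \approx 1.4427$ words.

### What the simulator does and does not emulate

Simulated records reproduce the timing law of the tuple model:
stage-wise success frequencies $2^{-n}$, mean onsets
$(2^n - 1)/r$, and a cumulative curve whose fitted $k$ recovers
$1/\ln 2$ closely. They contain no semantic content (labels `w1..wi`),
no clusters or switches, no perseverations or intrusions, and no
between-participant variability; a passing end-to-end test therefore
validates the retrieval-timing mechanism, not the package's fitness to
describe any particular clinical population.

### A known, deliberate discrepancy: the fitted rate

One bias is intrinsic and worth stating precisely. The discrete
process's expected onsets are left Riemann sums of the continuum
integral: $E[t_n] = \tfrac1r\sum_{m=0}^{n-1} 2^m = (2^n-1)/r$, whereas
the continuum curve with the same $r$ has
$t_n = k(2^n - 1)/r$. Because the success probability halves with every
word, the sum and the integral differ by a factor approaching
$1/\ln 2 \approx 1.44$ — far outside stochastic noise. Consequently,
fitting the logarithmic (or FBF) curve to simulated uniform-tuple data
recovers $k$ essentially unbiased but recovers a rate close to
$r/\ln 2$, about 44% above the configured draw rate. This is not a
defect of the fit or of the simulator: within the sampling account the
fitted $r$ *is* the continuum rate, and the retrieval probabilities it
implies, $e^{-n/k} = 2^{-n}$, are exactly the simulator's success
probabilities. The test suite asserts the $k$ recovery and documents
the rate relation; an expectation that the fitted rate match the draw
rate within 10% under uniform-tuple sampling cannot hold and is left
failing by design rather than weakened. For gentler decays
($q \to 1$) the bias vanishes.

## Problem sizes and numerical choices

Property suites run exhaustively for $i \le 8$ (basis round-trips,
orthogonality) and $i \le 6$ (operator spectra, subset-enumeration
oracles), which already covers 256-dimensional operators; the
separability oracle is exhaustive over all 256 sign patterns at
$i = 3$. Monte-Carlo checks use 2000–3000 runs at $i \in \{6,7\}$ and a
500-run end-to-end experiment at $i = 12$, sizes at which binomial
3-standard-error bands are tight enough to be informative while the
whole suite stays interactive. Tolerances: $10^{-12}$ for exact linear
algebra (orthogonality, norms, worked-example states), $10^{-9}$ for
eigenvalue multisets and the separability SVD, $10^{-6}$ for
probability-law consistency against numerical differentiation, 1% for
noise-free parameter recovery, 10% for stochastic recovery of $k$.
Ties in model selection cannot arise generically (AICc is continuous);
`which.min` keeps the first-listed candidate in the degenerate case.

## Limitations

The package is a faithful implementation of a theoretical model. The
prevalence of logarithmic time courses in clinical data is an empirical
claim about datasets the package does not ship and makes no statement
about; the barcode and basis machinery is pure combinatorics with no
anatomical claims; and the rotation operators are pinned to the
printed worked examples rather than to a general synthesis procedure
for arbitrary source/target state pairs, which the model does not
define.
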