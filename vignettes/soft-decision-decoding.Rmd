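---
title: "Soft-decision decoding for composite DNA letter storage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-decision decoding for composite DNA letter storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdlcodec)
```

## The channel and its model

A composite DNA letter stores information in the *mixture ratio* of the
four nucleotides at one sequence position: σ = (σ_A, σ_C, σ_G, σ_T),
with resolution k = Σσ_i. The full alphabet Φ_k contains every 4-part
composition of k — C(k+3, 3) letters — and a power-of-two subset of it
maps cleanly onto bits (6 bits/letter for |Σ| = 64, 8 for 256).

Reading a stored position means sampling N sequencing reads and counting
bases: X = (X_A, X_C, X_G, X_T), ΣX_i = N. The package models the whole
synthesis/storage/sequencing pipeline with two effects:

1. a lumped per-base substitution-style error rate `p_error` (default
   0.01), giving expected base frequencies
   q_i = (σ_i/k)(1 − p) + (p/3)(1 − σ_i/k);
2. multinomial sampling of N reads from q.

Positions are independent, and error types are not distinguished: indels
are folded into the single substitution-style rate, and the simulator
performs no alignment (reads correspond position by position). These are
deliberate simplifications — real composite synthesis and PCR introduce
neighbor correlations and type-specific error profiles that this model,
and therefore any test built on its simulator, does not probe.

## MAP letter inference

With a uniform prior over the alphabet, inferring the stored letter from
X is maximum likelihood: σ* = argmax_σ Σ_i X_i log q_i(σ). The package
scores the whole alphabet exhaustively (one matrix product per batch of
positions) up to 84 letters; for 128+ letters it first solves the
continuous maximizer in ratio space — σ̂ ∝ k·max(0, (X/N − p/3)/(1 −
4p/3)), the error-adjusted frequency estimate — and scores only the
nearest lattice letters (five by default). The pruned and exhaustive
paths are required to agree; a property test enforces this on both the
full Φ_8 alphabet and the 256-letter codec subset, and the exhaustive
path remains available everywhere as the reference.

A second, finite-copy-number scoring mode (`log_score(..., mode =
"exact")`) treats each base count as a draw without replacement from
F_i = f·q_i molecules and scores Σ_i log C(F_i, X_i). The physical copy
number f is not identifiable from count data, so the multinomial form —
its large-f limit — is the default; the exact mode is kept as a
configurable cross-check and the two are verified to select the same
letter on simulated draws at f = 10^6.

Ties (exact score equality) are resolved by smaller observed-frequency
distance, then by the canonical alphabet order (descending lexicographic
on the ratio vector). The canonical order also fixes the letter ↔ RS
symbol bijection, so serialized archives are reproducible. One side
effect is worth knowing: the channel itself is exactly symmetric under
relabeling of the four bases, but a deterministic tie-break cannot be,
so exact transition libraries differ across base relabelings by the
probability mass of score-tied boundary observations (about 1e-4 at
k = 2, N = 10). Determinism was chosen over exact symmetry; the
symmetry property test asserts agreement to that tolerance.

## Transition libraries and letter heterogeneity

Letters differ sharply in how often they are misread: the more mixed the
composition (the higher its entropy), the closer its neighbors in
frequency space and the higher its error rate — (1,1,0,0) errs far more
often than (2,0,0,0) at the same depth. The transition library makes
this quantitative: for each source letter σ_i, the probability that MAP
inference returns σ_j,

    P(σ_i → σ_j) = Σ_{X : MAP(X) = σ_j} Multinomial(X | N, q(σ_i)).

Up to moderate depths the sum is computed exactly over all C(N+3, 3)
observable count vectors (feasibility guard: 10^8 scored pairs); at the
working depths of the large alphabets (N = 190–490) the library is
estimated by Monte Carlo, 2×10^4 draws per letter by default — the
library feeds *rankings* (alternative letters, subset selection), not
precise probabilities, and at this sample size ranking noise is
negligible for the transitions that matter. Libraries are seeded and
reproducible; rows are exactly stochastic in exact mode and verified
against exact values within Monte-Carlo standard error in tests.

Codec alphabets are chosen through the library: the `size` letters with
the lowest error rate at the experiment's target depth (error rates are
depth-dependent, so the library used for selection is built at that
depth). Selection is deterministic — ties break on the canonical order —
and prefix-monotone in `size`.

## The soft-decision decoder

Each RS(45, 41) block protects 41 letters with 4 parity letters; hard
decoding corrects t = 2 symbol errors. When more letters are misread,
the decoder exploits two per-position signals:

* **reliability** — the Euclidean distance between X/N and σ*/k; error
  positions sit near decision boundaries and rank high;
* **alternatives** — the top-m transition targets of the inferred
  letter, the most probable letters it could have been confused with.

The search substitutes alternatives at combinations of the least
reliable positions and re-runs hard decoding: for s = 1, 2, …
substituted positions, the candidate set holds the top-d distances with
d starting at max(4, t+2) and growing by one per failed level (capped at
8 by default); size-s combinations are tried in rank order, and within a
combination, alternative assignments in descending joint transition
probability. One "iteration" is one RS decode attempt, and a block gives
up after `max_iterations` (10^5 default). Syndromes of substituted words
are updated incrementally from the base word's syndromes, so an attempt
costs little beyond the Berlekamp–Massey step.

The start value d = max(4, t+2), the growth-by-one schedule, and the
default m = 2 alternatives per position are design choices on points the
method description leaves open (it illustrates four candidate positions
with two alternatives each and states that the candidate count grows on
failure); all are configurable through `search_limits()`.

## Decoder errors, validation, and the CRC loop

An RS decoder fed more than t errors can *miscorrect*: return a valid
but wrong codeword. Two mechanisms catch this:

1. **Transition-library membership.** Every position where the decoded
   letter differs from the inferred one should carry a plausible
   confusion — a top-`validate_alternatives` library alternative of the
   inferred letter. Miscorrections write essentially arbitrary field
   elements and fail this test with high probability.
2. **CRC32 per matrix.** Ten consecutive blocks carry a 32-bit checksum
   (CRC-32/ISO-HDLC) over the matrix's payload bytes, planted in the
   last 32 information bits of the final block.

How the two interact was a genuinely open design point, and the flow
matters. Validation of the *initial hard decode* only flags the block as
a decoder-error suspect — rejecting it outright would discard true
codewords whose legitimate RS corrections happen to fall outside the
alternative set (measured at ≈2% of error events for the 64-letter
alphabet with the default top-5 validation). Re-decoding is triggered
only when the matrix CRC fails: flagged blocks are then searched again
with their rejected codewords excluded, up to `max_block_passes` rounds.
Inside the substitution search itself the opposite policy holds: an RS
success reached through substitutions is accepted only if plausible,
because there the block is known to hold more than t errors, the
miscorrection risk is high, and search completeness guarantees that the
fully-substituted true solution (whose changed positions are all library
alternatives by construction) remains reachable if the plausible-first
policy rejects intermediate wrong codewords. The first implausible
solution is kept as a flagged fallback so an exhausted search still
returns its best candidate.

The search's substitution net is deliberately narrower than the
validation net (m = 2 versus 5): substitutions multiply the search space
per position, while validation is a single membership test per changed
position, so a wider net there buys false-alarm reduction at no search
cost.

## The byte codec

A matrix holds 10 blocks × 41 information symbols × log2|Σ| bits. The
archive stream is the payload prefixed by its 4-byte big-endian length;
matrices are filled in order and the last is zero-padded. Within a
matrix the last 32 information bits hold the CRC of the matrix's payload
bytes; for 6- and 7-bit letters the information area is not a whole
number of bytes, so the few slack bits between payload and CRC are zero.
Failed matrices are counted and their payload zero-filled rather than
dropped, keeping byte offsets stable.

Non-power-of-two alphabets (the full Φ_6 with 84 letters, the six-letter
k = 2 alphabet) are first-class for simulation, inference and
transition analytics but excluded from the byte codec: RS with
symbol = letter requires n_code ≤ |Σ| − 1, which a 6-letter alphabet
cannot satisfy at block length 45, and the bit mapping requires a power
of two.

## Planted-error fixtures

Correction-capability probes construct blocks with exactly e letter
errors: at e positions the observed counts are drawn from the
distribution of a *wrong* letter whose transition row ranks the true
letter among its top alternatives (re-drawn until the MAP call actually
flips and the position's distance exceeds every clean position's), while
clean positions carry largest-remainder-rounded expected counts. Not
every letter admits such a confusable partner, so fixtures plant errors
only at eligible positions — this is a property of the alphabet's
transition structure, not of the decoder. On such fixtures the soft
decoder recovers all 50 seeded blocks with e = 6 errors per RS(45, 41)
block — triple the hard bound — which the acceptance suite verifies.

## Numerical and scale choices

* Zero expected frequencies (p_error = 0) are floored at the smallest
  positive double in batch scoring, reproducing −∞ semantics without
  NaN from 0·log 0.
* The per-letter Monte-Carlo default of 2×10^4 draws, the 10^5
  iteration budget, and d ≤ 8 candidate positions bound worst-case
  block cost to a few seconds.
* Test and acceptance runs use 20–50 matrices per configuration and
  10^4 simulated letters for accuracy estimates; depth sweeps in the
  test suite use 4 matrices per depth with a reduced iteration budget.
  These sizes are the package's chosen desk-scale study conditions; the
  in vitro datasets of the literature (tens of thousands of matrices)
  are out of scope.
* All randomness flows through explicit integer seeds; identical seeds
  give byte-identical archives, count tables and reports.

## Known limitations

* The channel model omits indels, alignment, PCR amplification bias and
  neighbor correlation; conclusions transfer to real reads only to the
  extent the lumped substitution rate captures them.
* The transition library is built per exact depth; decoding a stream at
  a depth far from the library's degrades the alternative rankings.
* With m = 2 alternatives, the probability that a true letter is offered
  for substitution is high but not near-total for large alphabets
  (≈0.78 at |Σ| = 64, N = 190, against ≈0.98 within the top 5); the
  near-total coverage reported for k = 2 systems reflects their simpler
  confusion structure, where each mixed letter has exactly two dominant
  confusion partners.
* Matrices whose CRC fails after all re-decode passes are zero-filled;
  no erasure-level recovery across matrices is attempted.
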