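#' Log-score of a composite letter given observed counts
#'
#' With a uniform prior over the alphabet, the posterior ranking of letters
#' depends only on `P(X | sigma)`. The default score is the multinomial
#' log-likelihood `sum_i X_i log q_i(sigma)` (terms constant across letters
#' are dropped). `mode = "exact"` instead scores the finite-copy
#' binomial-product model `sum_i log choose(F_i, X_i)` with
#' `F_i = copy_scale_f * q_i`, evaluated via log-gamma; the two agree in
#' the large-copy limit and the exact form is retained as a configurable
#' cross-check because the physical copy number is not identifiable from
#' count data.
#'
#' @param X Observed counts (integer 4-vector).
#' @param letter Integer 4-vector ratio.
#' @param p_error Per-base error probability.
#' @param mode `"multinomial"` (default) or `"exact"`.
#' @param copy_scale_f Effective molecule count for `mode = "exact"`.
#' @return A single numeric log-score (may be `-Inf` when an impossible
#'   base was observed, i.e. `q_i = 0` with `X_i > 0`).
#' @export
log_score <- function(X, letter, p_error,
                      mode = c("multinomial", "exact"),
                      copy_scale_f = 1e6) {
  mode <- match.arg(mode)
  X <- as.numeric(X)
  q <- expected_base_distribution(letter, p_error)
  if (mode == "multinomial") {
    terms <- numeric(4L)
    pos <- X > 0
    terms[pos] <- X[pos] * log(q[pos])  # 0 * log(0) contributes 0
    return(sum(terms))
  }
  f_i <- copy_scale_f * q
  if (any(X > f_i)) return(-Inf)
  sum(lgamma(f_i + 1) - lgamma(X + 1) - lgamma(f_i - X + 1))
}

# Batch multinomial log-score matrix: counts (n x 4) against every letter
# of an alphabet -> n x |Sigma| matrix. Zero expected frequencies are
# floored at the smallest positive double so that X_i = 0 contributes 0
# while X_i > 0 yields a score below any attainable one (-Inf semantics).
score_counts_matrix <- function(counts, alphabet, p_error) {
  Q <- expected_base_matrix(alphabet, p_error)
  counts %*% t(log(pmax(Q, .Machine$double.xmin)))
}

#' Normalized Euclidean reliability distance
#'
#' Distance between the observed base frequencies `X / N` and the letter's
#' nominal frequencies `sigma / k`, both on the probability simplex. Small
#' distances mark reliable calls; the soft decoder ranks candidate error
#' positions by descending distance.
#'
#' @param X Observed counts (integer 4-vector), depth >= 1.
#' @param letter Integer 4-vector ratio.
#' @return Non-negative numeric distance.
#' @export
reliability_distance <- function(X, letter) {
  X <- as.numeric(X)
  if (sum(X) < 1) stop("depth must be >= 1", call. = FALSE)
  sqrt(sum((X / sum(X) - as.numeric(letter) / sum(letter))^2))
}

# argmax with the package's deterministic tie policy: among score ties
# (exact equality), prefer the smaller reliability distance, then the
# earlier letter in canonical alphabet order.
resolve_argmax <- function(scores, X, alphabet) {
  best <- max(scores)
  tied <- which(scores == best)
  if (length(tied) > 1L) {
    d <- vapply(tied, function(j)
      reliability_distance(X, alphabet$letters[j, ]), numeric(1))
    tied <- tied[order(d, tied)]
  }
  tied[1L]
}

#' Infer the composite letter behind observed counts (MAP)
#'
#' Returns the alphabet letter maximizing the posterior score, plus a
#' ranked shortlist of candidates and the reliability distance of the
#' call. Two search strategies are available: exhaustive scoring of the
#' whole alphabet (default for alphabets up to 84 letters, and always
#' available as the reference), and a pruned search for large alphabets
#' that solves the continuous maximizer of the likelihood in ratio space,
#' `sigma_hat proportional to max(0, (X/N - p/3) / (1 - 4p/3))`, then
#' scores only the alphabet letters nearest that extremum.
#'
#' @param X Observed counts (integer 4-vector), depth >= 1.
#' @param alphabet A `composite_alphabet`.
#' @param p_error Per-base error probability.
#' @param n_candidates Number of ranked candidates to retain (3-5).
#' @param method `"auto"` (pruned for alphabets of 128+ letters),
#'   `"exhaustive"`, or `"pruned"`.
#' @return A `letter_call`: list with `index` (alphabet index of the MAP
#'   letter), `letter` (ratio 4-vector), `candidates` (data.frame of
#'   `index`, `log_score` in descending order), and `distance`.
#' @export
infer_letter <- function(X, alphabet, p_error, n_candidates = 5L,
                         method = c("auto", "exhaustive", "pruned")) {
  method <- match.arg(method)
  X <- as.numeric(unclass(X))
  if (sum(X) < 1) stop("no information: observed depth is 0", call. = FALSE)
  n_candidates <- max(1L, min(as.integer(n_candidates), nrow(alphabet$letters)))
  nL <- nrow(alphabet$letters)
  if (method == "auto") method <- if (nL >= 128L) "pruned" else "exhaustive"

  if (method == "exhaustive") {
    pool <- seq_len(nL)
  } else {
    # continuous extremum of the likelihood in ratio space, error-adjusted
    p <- p_error
    sig_hat <- pmax(0, (X / sum(X) - p / 3) / (1 - 4 * p / 3))
    if (sum(sig_hat) == 0) sig_hat <- rep(1, 4L)
    sig_hat <- sig_hat / sum(sig_hat)
    frac <- alphabet$letters / alphabet$k
    d2 <- rowSums((frac - matrix(sig_hat, nL, 4L, byrow = TRUE))^2)
    pool <- order(d2)[seq_len(min(max(5L, n_candidates), nL))]
  }
  scores <- drop(score_counts_matrix(matrix(X, 1L), alphabet, p_error))[pool]
  best_local <- resolve_argmax(scores, X,
                               composite_alphabet_view(alphabet, pool))
  ord <- order(-scores)
  cand <- data.frame(index = pool[ord][seq_len(min(n_candidates, length(pool)))],
                     log_score = scores[ord][seq_len(min(n_candidates, length(pool)))])
  idx <- pool[best_local]
  structure(list(index = idx,
                 letter = alphabet$letters[idx, ],
                 candidates = cand,
                 distance = reliability_distance(X, alphabet$letters[idx, ])),
            class = "letter_call")
}

# lightweight subset view used only for tie resolution
composite_alphabet_view <- function(alphabet, idx) {
  list(k = alphabet$k, letters = alphabet$letters[idx, , drop = FALSE])
}

#' Batch MAP inference over a counts table
#'
#' Vectorized equivalent of [infer_letter()] for whole sequences: one
#' score-matrix product per chunk, exact tie handling identical to the
#' single-call path.
#'
#' @param counts Integer matrix with columns A, C, G, T (one row per
#'   position, constant positive depth not required).
#' @param alphabet A `composite_alphabet`.
#' @param p_error Per-base error probability.
#' @param chunk Rows per scoring chunk (memory control).
#' @return List with `index` (integer vector of MAP alphabet indices) and
#'   `distance` (reliability distance of each call).
#' @export
infer_letters <- function(counts, alphabet, p_error, chunk = 20000L) {
  n <- nrow(counts)
  idx <- integer(n)
  if (n == 0L) return(list(index = idx, distance = numeric(0L)))
  if (any(rowSums(counts) < 1))
    stop("no information: some positions have observed depth 0", call. = FALSE)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    sc <- score_counts_matrix(counts[rows, , drop = FALSE], alphabet, p_error)
    top <- max.col(sc, ties.method = "first")
    # exact-tie rows get the full deterministic tie policy
    mx <- sc[cbind(seq_along(rows), top)]
    nties <- rowSums(sc == mx)
    for (r in which(nties > 1L)) {
      top[r] <- resolve_argmax(sc[r, ], counts[rows[r], ], alphabet)
    }
    idx[rows] <- top
  }
  frac <- alphabet$letters / alphabet$k
  dist <- sqrt(rowSums((counts / rowSums(counts) -
                          frac[idx, , drop = FALSE])^2))
  list(index = idx, distance = dist)
}

#' @export
print.letter_call <- function(x, ...) {
  cat(sprintf("letter_call: (%s)  distance = %.4f\n",
              paste(x$letter, collapse = ","), x$distance))
  cat(sprintf("  top candidates: %s\n",
              paste(sprintf("#%d (%.3f)", x$candidates$index,
                            x$candidates$log_score), collapse = ", ")))
  invisible(x)
}
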