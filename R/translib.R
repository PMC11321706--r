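#' Enumerate all observable count vectors at a depth
#'
#' All 4-part compositions of `depth_N`: the `choose(N + 3, 3)` possible
#' observed base-count vectors at that depth.
#'
#' @param depth_N Non-negative integer depth.
#' @return Integer matrix, columns A, C, G, T.
#' @export
enumerate_observations <- function(depth_N) {
  compositions4(depth_N)
}

new_transition_library <- function(alphabet, params, trans, method,
                                   n_draws = NULL, seed = NULL) {
  stopifnot(nrow(trans) == nrow(alphabet$letters),
            ncol(trans) == nrow(alphabet$letters))
  structure(list(k = alphabet$k,
                 depth_N = params$depth_N,
                 p_error = params$p_error,
                 alphabet = alphabet,
                 trans = trans,
                 error_rate = 1 - diag(trans),
                 method = method,
                 n_draws = n_draws,
                 seed = seed),
            class = "transition_library")
}

#' Build a transition library by exact enumeration
#'
#' For each source letter sigma_i, the probability of being read as
#' sigma_j is accumulated over every possible observed count vector X at
#' depth N: `P(i -> j) = sum over { X : MAP(X) = sigma_j } of
#' P(X | sigma_i)` with P(X | sigma_i) the multinomial likelihood under
#' the channel. Rows are exactly stochastic. The per-letter error rate is
#' one minus the diagonal entry. Feasible only while
#' `choose(N+3, 3) * |Sigma| <= 1e8`; beyond that use
#' [build_library_mc()].
#'
#' @param alphabet A `composite_alphabet`.
#' @param params A `channel_params` (depth and error rate of the library).
#' @return A `transition_library` with `method = "exact"`.
#' @export
build_library_exact <- function(alphabet, params) {
  stopifnot(inherits(alphabet, "composite_alphabet"),
            inherits(params, "channel_params"))
  N <- params$depth_N
  nL <- nrow(alphabet$letters)
  n_obs <- choose(N + 3, 3)
  if (n_obs * nL > 1e8)
    stop("exact enumeration infeasible (", format(n_obs * nL, big.mark = ","),
         " scored pairs); use build_library_mc()", call. = FALSE)
  obs <- enumerate_observations(N)
  inferred <- infer_letters(obs, alphabet, params$p_error)$index
  Q <- expected_base_matrix(alphabet, params$p_error)
  # multinomial log-likelihood of every observation under every source
  lchoose_term <- lgamma(N + 1) - rowSums(lgamma(obs + 1))
  logQ <- log(pmax(Q, .Machine$double.xmin))
  trans <- matrix(0, nL, nL)
  for (i in seq_len(nL)) {
    lp <- lchoose_term + drop(obs %*% logQ[i, ])
    # impossible observations (q = 0 floored) have lp ~ -1e300; exp -> 0
    p <- exp(lp)
    trans[i, ] <- vapply(seq_len(nL), function(j) sum(p[inferred == j]),
                         numeric(1))
  }
  new_transition_library(alphabet, params, trans, "exact")
}

#' Build a transition library by Monte Carlo simulation
#'
#' Empirical analogue of [build_library_exact()] for depths where the
#' observation space is too large to enumerate (e.g. N = 490): for each
#' source letter, `n_draws` observed count vectors are simulated through
#' the channel and MAP-inferred; transition probabilities are the
#' empirical cluster frequencies.
#'
#' @param alphabet A `composite_alphabet`.
#' @param params A `channel_params`.
#' @param n_draws Simulated observations per source letter (>= 1000).
#'   Default 2e4: the library feeds rankings, not exact probabilities.
#' @param seed Integer seed (falls back to `params$seed`, then 1).
#' @return A `transition_library` with `method = "monte_carlo"`.
#' @export
build_library_mc <- function(alphabet, params, n_draws = 20000L,
                             seed = NULL) {
  stopifnot(inherits(alphabet, "composite_alphabet"),
            inherits(params, "channel_params"))
  n_draws <- as.integer(n_draws)
  if (n_draws < 1000L)
    stop("`n_draws` must be >= 1000 per letter", call. = FALSE)
  seed <- if (!is.null(seed)) seed else
    if (!is.null(params$seed)) params$seed else 1L
  set.seed(seed)
  nL <- nrow(alphabet$letters)
  Q <- expected_base_matrix(alphabet, params$p_error)
  trans <- matrix(0, nL, nL)
  for (i in seq_len(nL)) {
    X <- t(stats::rmultinom(n_draws, params$depth_N, Q[i, ]))
    inferred <- infer_letters(X, alphabet, params$p_error)$index
    trans[i, ] <- tabulate(inferred, nbins = nL) / n_draws
  }
  new_transition_library(alphabet, params, trans, "monte_carlo",
                         n_draws = n_draws, seed = seed)
}

#' Ranked alternative letters for a source letter
#'
#' The top-`m` non-identity transition targets of `letter`, in descending
#' transition probability (ties broken by canonical alphabet order).
#' These are the substitution candidates the soft decoder tries at a
#' position whose MAP call is `letter`.
#'
#' @param library A `transition_library`.
#' @param letter Alphabet index (integer) or ratio 4-vector.
#' @param m Number of alternatives (default 2).
#' @return Data frame with columns `index` (alphabet index) and `prob`.
#' @export
alternatives <- function(library, letter, m = 2L) {
  stopifnot(inherits(library, "transition_library"))
  i <- if (length(letter) == 1L) as.integer(letter)
       else letter_index(library$alphabet, letter)
  if (is.na(i) || i < 1L || i > nrow(library$trans))
    stop("letter not present in library", call. = FALSE)
  m <- as.integer(m)
  if (m < 0L) stop("`m` must be >= 0", call. = FALSE)
  row <- library$trans[i, ]
  others <- setdiff(seq_along(row), i)
  ord <- others[order(-row[others], others)]
  take <- ord[seq_len(min(m, length(ord)))]
  data.frame(index = take, prob = row[take])
}

# Precompute top-m alternative indices and probabilities for every letter:
# list(index = m x |Sigma| matrix, prob = m x |Sigma| matrix). Hot path of
# the soft decoder.
alternatives_table <- function(library, m) {
  nL <- nrow(library$trans)
  idx <- matrix(NA_integer_, m, nL)
  prob <- matrix(0, m, nL)
  for (i in seq_len(nL)) {
    a <- alternatives(library, i, m)
    take <- seq_len(nrow(a))
    idx[take, i] <- a$index
    prob[take, i] <- a$prob
  }
  list(index = idx, prob = prob)
}

#' @export
print.transition_library <- function(x, ...) {
  cat(sprintf(
    "transition_library: k = %d, %d letters, depth N = %d, p_error = %g\n",
    x$k, nrow(x$trans), x$depth_N, x$p_error))
  cat(sprintf("  method = %s%s; error rate range [%.4g, %.4g]\n",
              x$method,
              if (!is.null(x$n_draws))
                sprintf(" (%d draws/letter, seed %d)", x$n_draws,
                        as.integer(x$seed)) else "",
              min(x$error_rate), max(x$error_rate)))
  invisible(x)
}

#' Serialize / deserialize a transition library as JSON
#'
#' Metadata (k, depth, error rate, method, draws, seed), the alphabet, and
#' per-source rows as `[[target_index, probability], ...]` sorted by
#' descending probability (1-based indices, zero entries omitted).
#'
#' @param library A `transition_library`.
#' @param path File path.
#' @return `library_from_json` returns a `transition_library`.
#' @export
library_to_json <- function(library, path) {
  rows <- lapply(seq_len(nrow(library$trans)), function(i) {
    row <- library$trans[i, ]
    nz <- which(row > 0)
    nz <- nz[order(-row[nz], nz)]
    lapply(nz, function(j) list(j, row[j]))
  })
  jsonlite::write_json(
    list(k = library$k, depth_N = library$depth_N,
         p_error = library$p_error, method = library$method,
         n_draws = library$n_draws, seed = library$seed,
         letters = unname(apply(library$alphabet$letters, 1L, identity,
                                simplify = FALSE)),
         rows = rows),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname library_to_json
#' @export
library_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  letters <- do.call(rbind, lapply(obj$letters, unlist))
  alphabet <- composite_alphabet(obj$k, letters)
  nL <- nrow(letters)
  trans <- matrix(0, nL, nL)
  for (i in seq_along(obj$rows)) {
    for (entry in obj$rows[[i]]) {
      trans[i, entry[[1]]] <- entry[[2]]
    }
  }
  params <- channel_params(p_error = obj$p_error, depth_N = obj$depth_N)
  new_transition_library(alphabet, params, trans, obj$method,
                         n_draws = obj$n_draws, seed = obj$seed)
}
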