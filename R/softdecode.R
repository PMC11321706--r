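#' Per-position evidence for one RS block
#'
#' Bundles, for each of the `n_code` positions of a block, the observed
#' base counts, the MAP letter call and its reliability distance. This is
#' the input of the soft-decision decoder.
#'
#' @param counts Integer matrix (`n_code` x 4, columns A, C, G, T).
#' @param alphabet A `composite_alphabet`.
#' @param p_error Per-base error probability used for inference.
#' @param inferred,distance Optional precomputed MAP indices / distances
#'   (as from [infer_letters()]); computed when omitted.
#' @return An object of class `block_evidence`: list with `counts`,
#'   `inferred` (1-based alphabet indices), `distance`, `alphabet`,
#'   `p_error`.
#' @export
block_evidence <- function(counts, alphabet, p_error,
                           inferred = NULL, distance = NULL) {
  stopifnot(is.matrix(counts), ncol(counts) == 4L)
  if (is.null(inferred) || is.null(distance)) {
    call <- infer_letters(counts, alphabet, p_error)
    inferred <- call$index
    distance <- call$distance
  }
  stopifnot(length(inferred) == nrow(counts),
            length(distance) == nrow(counts), all(distance >= 0))
  structure(list(counts = counts, inferred = as.integer(inferred),
                 distance = distance, alphabet = alphabet,
                 p_error = p_error),
            class = "block_evidence")
}

#' Iteration limits for the soft-decision search
#'
#' @param max_positions Cap on the candidate-position set size (default 8).
#' @param max_alternatives Alternatives per position, m, tried by the
#'   substitution search (default 2).
#' @param max_iterations Cap on RS decode attempts per block (default 1e5);
#'   blocks beyond the budget are given up as `exhausted`.
#' @param max_block_passes Matrix-level re-decode rounds after a CRC
#'   failure (default 3).
#' @param validate_alternatives Alternatives per position admitted by the
#'   decoder-error membership check (default 5). Validation inspects every
#'   position the RS decoder changed - not only the substituted ones - so
#'   it uses a wider net than the search: a miscorrected letter is
#'   essentially a random field element and stays unlikely to fall in the
#'   top 5, while a genuine correction rarely falls outside them.
#' @return An object of class `search_limits`.
#' @export
search_limits <- function(max_positions = 8L, max_alternatives = 2L,
                          max_iterations = 100000L, max_block_passes = 3L,
                          validate_alternatives = 5L) {
  stopifnot(max_positions >= 1L, max_alternatives >= 1L,
            max_iterations >= 1L, max_block_passes >= 0L,
            validate_alternatives >= 1L)
  structure(list(max_positions = as.integer(max_positions),
                 max_alternatives = as.integer(max_alternatives),
                 max_iterations = as.integer(max_iterations),
                 max_block_passes = as.integer(max_block_passes),
                 validate_alternatives = as.integer(validate_alternatives)),
            class = "search_limits")
}

#' Rank candidate error positions of a block
#'
#' The `d` positions with the largest reliability distance, in descending
#' distance order; ties broken by ascending position index.
#'
#' @param evidence A `block_evidence`.
#' @param d Number of positions, 1 <= d <= block length.
#' @return Integer vector of `d` positions (1-based).
#' @export
rank_candidate_positions <- function(evidence, d) {
  stopifnot(inherits(evidence, "block_evidence"))
  n <- length(evidence$distance)
  d <- as.integer(d)
  if (d < 1L || d > n) stop("need 1 <= d <= block length", call. = FALSE)
  order(-evidence$distance, seq_len(n))[seq_len(d)]
}

#' Canonical key of a codeword
#'
#' Comma-separated 0-based symbols; the format used by the soft decoder's
#' `excluded_solutions` sets.
#'
#' @param symbols Integer vector of field symbols.
#' @return Character scalar.
#' @export
codeword_key <- function(symbols) paste(symbols, collapse = ",")

#' Soft-decision decoding of one RS block
#'
#' Implements the iterative substitute-and-redecode search: (1) hard-decode
#' the MAP letters; on success return with no substitutions. (2) Otherwise,
#' for a growing number of substituted positions s = 1, 2, ..., rank the
#' top-d positions by reliability distance (d starts at
#' `max(4, t_correct + 2)` and grows by one per failed level, capped at
#' `max_positions`), enumerate size-s combinations of candidate positions
#' in rank order, and for each combination try every assignment of
#' transition-library alternatives in descending joint transition
#' probability; each attempt substitutes the letters and hard-decodes.
#' Solutions whose key is in `excluded` (previously rejected codewords)
#' are skipped. (3) The search gives up (`status = "exhausted"`) when the
#' RS-decode budget `max_iterations` is spent or all levels are tried.
#'
#' @param evidence A `block_evidence` for the block.
#' @param library A `transition_library` matching the evidence's alphabet
#'   and the experiment's depth.
#' @param spec An `rs_spec` with `n_code` equal to the block length.
#' @param limits A `search_limits`.
#' @param excluded Character vector of codeword keys to reject
#'   (see [codeword_key] format: comma-separated symbols).
#' @return A `soft_decode_result`: list with `status`
#'   (`"decoded"`/`"exhausted"`), `codeword` (1-based letter indices, when
#'   decoded), `substitutions` (data.frame `position`, `from`, `to` letter
#'   indices applied by the soft search), `n_rs_corrected`,
#'   `iterations_used`, `decoder_error_suspect` (set by the caller's
#'   validation), `excluded_solutions`.
#' @export
derrick_cp_decode <- function(evidence, library, spec, limits = search_limits(),
                              excluded = character()) {
  stopifnot(inherits(evidence, "block_evidence"),
            inherits(library, "transition_library"),
            inherits(spec, "rs_spec"), inherits(limits, "search_limits"))
  n <- length(evidence$inferred)
  if (n != spec$n_code)
    stop("evidence length does not match n_code", call. = FALSE)
  if (!identical(library$alphabet$letters, evidence$alphabet$letters))
    stop("library alphabet does not match evidence alphabet", call. = FALSE)
  symbols <- evidence$inferred - 1L
  iterations <- 0L
  no_subs <- data.frame(position = integer(), from = integer(),
                        to = integer())
  result <- function(status, codeword = NULL, subs = no_subs,
                     n_rs = NA_integer_) {
    structure(list(status = status,
                   codeword = codeword,
                   substitutions = subs,
                   n_rs_corrected = n_rs,
                   iterations_used = iterations,
                   decoder_error_suspect = FALSE,
                   excluded_solutions = excluded),
              class = "soft_decode_result")
  }

  base_synd <- rs_syndromes(symbols, spec)
  iterations <- iterations + 1L
  hd <- rs_decode_hard(symbols, spec, synd = base_synd)
  if (hd$ok && !(codeword_key(hd$codeword) %in% excluded))
    return(result("decoded", hd$codeword + 1L, n_rs = hd$n_corrected))

  alt_tab <- alternatives_table(library, limits$max_alternatives)
  # wider membership table for in-search decoder-error screening: an RS
  # success reached through substitutions is only accepted if every
  # changed position carries a plausible alternative; implausible
  # solutions are excluded and the search continues, falling back to the
  # first of them (flagged) if nothing better turns up
  val_tab <- alternatives_table(library, limits$validate_alternatives)
  plausible <- function(codeword_sym) {
    chg <- which(codeword_sym + 1L != evidence$inferred)
    all(vapply(chg, function(p) {
      (codeword_sym[p] + 1L) %in% val_tab$index[, evidence$inferred[p]]
    }, logical(1)))
  }
  fallback <- NULL
  d_start <- min(max(4L, spec$t_correct + 2L), limits$max_positions, n)
  d <- d_start - 1L
  for (s in seq_len(min(limits$max_positions, n))) {
    d <- min(max(s, d + 1L), limits$max_positions, n)
    if (s > d) break
    cand <- rank_candidate_positions(evidence, d)
    combos <- utils::combn(d, s)
    for (ci in seq_len(ncol(combos))) {
      pos <- cand[combos[, ci]]
      src <- evidence$inferred[pos]
      alt_idx <- alt_tab$index[, src, drop = FALSE]   # m x s
      alt_prob <- alt_tab$prob[, src, drop = FALSE]
      n_alt <- colSums(!is.na(alt_idx))
      if (any(n_alt == 0L)) next
      grid <- as.matrix(expand.grid(lapply(n_alt, seq_len),
                                    KEEP.OUT.ATTRS = FALSE))
      jlp <- rowSums(matrix(
        log(alt_prob[cbind(as.vector(t(grid)),
                           rep(seq_len(s), nrow(grid)))]),
        nrow(grid), s, byrow = TRUE))
      ord <- do.call(order, c(list(-jlp), lapply(seq_len(s),
                                                function(j) grid[, j])))
      for (g in ord) {
        new_idx <- alt_idx[cbind(grid[g, ], seq_len(s))]
        new_sym <- new_idx - 1L
        iterations <- iterations + 1L
        if (iterations > limits$max_iterations) return(result("exhausted"))
        synd <- rs_syndromes_update(base_synd, symbols[pos], new_sym, pos,
                                    spec)
        word <- symbols
        word[pos] <- new_sym
        hd <- rs_decode_hard(word, spec, synd = synd)
        if (!hd$ok) next
        if (codeword_key(hd$codeword) %in% excluded) next
        subs <- data.frame(position = pos, from = evidence$inferred[pos],
                           to = new_idx)
        subs <- subs[subs$from != subs$to, , drop = FALSE]
        if (!plausible(hd$codeword)) {
          excluded <- c(excluded, codeword_key(hd$codeword))
          if (is.null(fallback)) {
            fallback <- result("decoded", hd$codeword + 1L, subs = subs,
                               n_rs = hd$n_corrected)
            fallback$decoder_error_suspect <- TRUE
          }
          next
        }
        return(result("decoded", hd$codeword + 1L, subs = subs,
                      n_rs = hd$n_corrected))
      }
    }
  }
  if (!is.null(fallback)) {
    fallback$iterations_used <- iterations
    fallback$excluded_solutions <- excluded
    return(fallback)
  }
  result("exhausted")
}

#' Validate a decoded block against the transition library
#'
#' A decoded codeword is plausible when every position where the decoded
#' letter differs from the MAP-inferred letter carries a letter that is
#' among the top-`m` transition-library alternatives of the inferred one.
#' A `FALSE` verdict marks a likely RS decoder error (miscorrection): the
#' caller should flag the block, add the codeword to the excluded set and
#' re-decode.
#'
#' @param result A decoded `soft_decode_result`.
#' @param evidence The block's `block_evidence`.
#' @param library A `transition_library`.
#' @param m Alternatives per position used for the membership test.
#' @return Logical scalar.
#' @export
validate_against_library <- function(result, evidence, library, m = 2L) {
  stopifnot(inherits(result, "soft_decode_result"),
            result$status == "decoded")
  changed <- which(result$codeword != evidence$inferred)
  if (length(changed) == 0L) return(TRUE)
  alt_tab <- alternatives_table(library, m)
  all(vapply(changed, function(p) {
    result$codeword[p] %in% alt_tab$index[, evidence$inferred[p]]
  }, logical(1)))
}

#' Decode one block and flag suspected decoder errors
#'
#' Runs [derrick_cp_decode()] (or plain hard-decision decoding when
#' `mode = "hard"`), then applies [validate_against_library()]. A failed
#' validation does not reject the solution outright - the membership test
#' has false alarms - it flags the block `decoder_error_suspect = TRUE`
#' and records the codeword in `excluded_solutions`, so that a
#' matrix-level CRC failure can send the block back here with that
#' codeword excluded from the search.
#'
#' @param evidence A `block_evidence`.
#' @param library A `transition_library` (ignored in hard mode).
#' @param spec An `rs_spec`.
#' @param limits A `search_limits`.
#' @param mode `"soft"` or `"hard"`.
#' @param excluded Character vector of codeword keys to reject a priori.
#' @return A `soft_decode_result`.
#' @export
decode_block <- function(evidence, library, spec, limits = search_limits(),
                         mode = c("soft", "hard"), excluded = character()) {
  mode <- match.arg(mode)
  if (mode == "hard") {
    symbols <- evidence$inferred - 1L
    hd <- rs_decode_hard(symbols, spec)
    return(structure(list(
      status = if (hd$ok) "decoded" else "exhausted",
      codeword = if (hd$ok) hd$codeword + 1L else NULL,
      substitutions = data.frame(position = integer(), from = integer(),
                                 to = integer()),
      n_rs_corrected = hd$n_corrected,
      iterations_used = 1L,
      decoder_error_suspect = FALSE,
      excluded_solutions = excluded), class = "soft_decode_result"))
  }
  res <- derrick_cp_decode(evidence, library, spec, limits, excluded)
  if (res$status == "decoded" &&
      !validate_against_library(res, evidence, library,
                                limits$validate_alternatives)) {
    res$decoder_error_suspect <- TRUE
    res$excluded_solutions <- union(excluded,
                                    codeword_key(res$codeword - 1L))
  }
  res
}

#' @export
print.soft_decode_result <- function(x, ...) {
  cat(sprintf("soft_decode_result: %s, %d substitution(s), %s RS-corrected, %d iteration(s)%s\n",
              x$status, nrow(x$substitutions),
              ifelse(is.na(x$n_rs_corrected), "?", x$n_rs_corrected),
              x$iterations_used,
              if (isTRUE(x$decoder_error_suspect)) " [decoder-error suspect]"
              else ""))
  invisible(x)
}
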