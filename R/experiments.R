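#' Seeded pseudo-random byte payload
#' @param n_bytes Number of bytes.
#' @param seed Integer seed.
#' @return Raw vector.
#' @export
random_payload <- function(n_bytes, seed = 1L) {
  set.seed(seed)
  as.raw(sample.int(256L, n_bytes, replace = TRUE) - 1L)
}

#' Logical density of an alphabet (bits per letter)
#' @param alphabet A `composite_alphabet`.
#' @return `log2` of the alphabet size (not restricted to integers).
#' @export
logical_density <- function(alphabet) {
  log2(nrow(alphabet$letters))
}

#' Density gain of one alphabet over another
#'
#' Ratio of logical densities, e.g. a 256-letter alphabet stores
#' `log2(256) / log2(64) = 1.33` times more information per position than
#' a 64-letter one.
#'
#' @param alphabet,baseline `composite_alphabet`s.
#' @return Numeric ratio.
#' @export
density_gain <- function(alphabet, baseline) {
  logical_density(alphabet) / logical_density(baseline)
}

#' Deterministic expected counts for a letter (largest-remainder rounding)
#'
#' The integer count vector closest to `depth_N` times the letter's
#' expected base distribution, summing exactly to `depth_N`. Used for the
#' noise-free positions of constructed test blocks.
#'
#' @param letter Integer 4-vector ratio.
#' @param p_error Per-base error probability.
#' @param depth_N Integer depth.
#' @return Integer 4-vector.
#' @export
rounded_expected_counts <- function(letter, p_error, depth_N) {
  q <- expected_base_distribution(letter, p_error)
  x <- floor(depth_N * q)
  rem <- depth_N - sum(x)
  if (rem > 0) {
    frac <- depth_N * q - x
    bump <- order(-frac)[seq_len(rem)]
    x[bump] <- x[bump] + 1
  }
  as.integer(x)
}

# Pick, for a true letter t, a wrong letter w such that the transition row
# of w ranks t first among alternatives (falling back to rank <= m).
# Returns NA when no such partner exists: not every letter can host a
# plantable error, so fixture constructors must check eligibility.
# Deterministic given the library.
confusable_wrong_letter <- function(library, t_idx, m = 2L) {
  by_prob <- alternatives(library, t_idx, m = nrow(library$trans))$index
  for (rank_cap in c(1L, seq_len(m)[-1L])) {
    for (v in by_prob) {
      a <- alternatives(library, v, rank_cap)
      if (t_idx %in% a$index) return(v)
    }
  }
  NA_integer_
}

#' Construct a block with a planted number of letter errors
#'
#' Builds one RS codeword of random information symbols and plants `e`
#' letter errors: at `e` random positions the observed counts are drawn
#' from the distribution of a wrong letter whose transition row ranks the
#' true letter first (guaranteeing both the inference error and that the
#' truth is a top library alternative); all other positions carry
#' deterministic rounded expected counts, so the erroneous positions
#' dominate the reliability-distance ranking.
#'
#' @param e Number of planted letter errors.
#' @param alphabet The codec `composite_alphabet`.
#' @param library A `transition_library` at the evaluation depth.
#' @param spec An `rs_spec`.
#' @param seed Integer seed.
#' @param alt_rank Required rank of the truth among the wrong letter's
#'   alternatives (default 2: within the search's default top-m).
#' @param truth Optional fixed codeword (1-based letter indices) to plant
#'   errors on; a fresh random codeword is drawn when omitted.
#' @return List with `evidence` (a `block_evidence`), `truth` (letter
#'   indices), `error_positions`, `wrong_letters`.
#' @export
make_error_block <- function(e, alphabet, library, spec, seed = 1L,
                             alt_rank = 2L, truth = NULL) {
  stopifnot(e >= 0L, e <= spec$n_code)
  set.seed(seed)
  n <- spec$n_code
  N <- library$depth_N
  p <- library$p_error
  # letters eligible to carry a planted error: those with a confusable
  # partner whose alternatives (top alt_rank) contain them
  partner <- rep(NA_integer_, nrow(alphabet$letters))
  fixed_truth <- !is.null(truth)
  for (attempt in 1:50) {
    if (!fixed_truth) {
      info <- sample.int(spec$field_order, spec$k_info, replace = TRUE) - 1L
      truth <- rs_encode(info, spec) + 1L
    }
    need <- unique(truth)
    for (t_idx in need[is.na(partner[need])]) {
      w <- confusable_wrong_letter(library, t_idx, alt_rank)
      partner[t_idx] <- if (is.na(w)) -1L else w
    }
    eligible <- which(partner[truth] > 0L)
    if (length(eligible) >= e || fixed_truth) break
  }
  if (length(eligible) < e)
    stop("could not find ", e, " eligible error positions", call. = FALSE)
  counts <- t(vapply(truth, function(i)
    rounded_expected_counts(alphabet$letters[i, ], p, N), integer(4L)))
  err_pos <- eligible[sample.int(length(eligible), e)]
  # planted observations must both flip the MAP call to the wrong letter
  # and out-rank every clean position in reliability distance
  clean_max <- if (e > 0L && e < n) {
    frac <- alphabet$letters / alphabet$k
    d0 <- sqrt(rowSums((counts / N - frac[truth, , drop = FALSE])^2))
    max(d0[-err_pos])
  } else 0
  wrong <- integer(0L)
  for (pos in err_pos) {
    w <- partner[truth[pos]]
    wrong <- c(wrong, w)
    qw <- expected_base_distribution(alphabet$letters[w, ], p)
    w_frac <- alphabet$letters[w, ] / alphabet$k
    planted <- FALSE
    for (try in 1:100) {
      X <- as.integer(stats::rmultinom(1L, N, qw))
      d <- sqrt(sum((X / N - w_frac)^2))
      if (d > clean_max &&
          infer_letter(X, alphabet, p, method = "exhaustive")$index == w) {
        counts[pos, ] <- X
        planted <- TRUE
        break
      }
    }
    if (!planted) {
      # fallback: place the observation near the decision boundary
      # between truth and wrong letter (always far from clean noise)
      qt <- expected_base_distribution(alphabet$letters[truth[pos], ], p)
      for (alpha in seq(0.55, 0.95, by = 0.05)) {
        X <- rounded_expected_counts_vec(alpha * qw + (1 - alpha) * qt, N)
        if (infer_letter(X, alphabet, p, method = "exhaustive")$index == w) {
          counts[pos, ] <- X
          planted <- TRUE
          break
        }
      }
    }
    if (!planted) stop("could not plant an inference error at position ",
                       pos, call. = FALSE)
  }
  colnames(counts) <- BASES
  list(evidence = block_evidence(counts, alphabet, p),
       truth = truth, error_positions = sort(err_pos),
       wrong_letters = wrong[order(err_pos)])
}

rounded_expected_counts_vec <- function(q, depth_N) {
  q <- q / sum(q)
  x <- floor(depth_N * q)
  rem <- depth_N - sum(x)
  if (rem > 0) {
    frac <- depth_N * q - x
    bump <- order(-frac)[seq_len(rem)]
    x[bump] <- x[bump] + 1
  }
  as.integer(x)
}

#' Decoding success rate on constructed e-error blocks
#'
#' Builds `n_fixtures` blocks with exactly `e` planted letter errors (see
#' [make_error_block()]) and reports the fraction that the chosen decoder
#' recovers exactly. In soft mode the full block procedure applies,
#' including the decoder-error path: a result flagged by the
#' transition-library membership check is re-decoded with the flagged
#' codeword excluded (up to `max_block_passes` rounds), exactly as a
#' matrix-level CRC failure would trigger in the codec.
#'
#' @param e Number of planted errors per block.
#' @param n_fixtures Number of blocks.
#' @param alphabet,library,spec,limits As elsewhere.
#' @param mode `"soft"` or `"hard"`.
#' @param seed Base seed; fixture i uses `seed + i`.
#' @param verify `"block"` measures the block search alone (with the
#'   decoder-error flag-and-retry); `"matrix"` embeds each fixture as the
#'   first block of a CRC-protected matrix and runs the complete decode
#'   procedure, so plausible miscorrections - undetectable at block
#'   level by construction - are caught by the checksum and re-decoded.
#'   Matrix verification requires a power-of-two alphabet.
#' @return List with `success_rate`, `n_fixtures`, `decoded` (logical
#'   vector).
#' @export
run_capability_probe <- function(e, n_fixtures, alphabet, library, spec,
                                 limits = search_limits(),
                                 mode = c("soft", "hard"), seed = 1L,
                                 verify = c("block", "matrix")) {
  mode <- match.arg(mode)
  verify <- match.arg(verify)
  decoded <- logical(n_fixtures)
  layout <- if (verify == "matrix") matrix_layout(alphabet, spec)
  for (i in seq_len(n_fixtures)) {
    if (verify == "block") {
      blk <- make_error_block(e, alphabet, library, spec, seed = seed + i)
      res <- decode_block(blk$evidence, library, spec, limits, mode = mode)
      if (mode == "soft") {
        pass <- 0L
        while (isTRUE(res$decoder_error_suspect) &&
               pass < limits$max_block_passes) {
          pass <- pass + 1L
          res <- decode_block(blk$evidence, library, spec, limits,
                              mode = mode,
                              excluded = res$excluded_solutions)
        }
      }
      decoded[i] <- res$status == "decoded" &&
        identical(res$codeword, blk$truth)
    } else {
      probe <- NULL
      for (sub in 0:9) {  # a payload can lack e eligible positions
        payload <- random_payload(layout$payload_bytes - 4L,
                                  seed = seed + i + 7919L * sub)
        archive <- encode_bytes(payload, layout)
        probe <- tryCatch(
          make_error_block(e, alphabet, library, spec, seed = seed + i,
                           truth = archive[[1]][seq_len(spec$n_code)]),
          error = function(err) NULL)
        if (!is.null(probe)) break
      }
      if (is.null(probe)) stop("could not construct probe matrix",
                               call. = FALSE)
      counts <- t(vapply(archive[[1]], function(li)
        rounded_expected_counts(alphabet$letters[li, ], library$p_error,
                                library$depth_N), integer(4L)))
      counts[seq_len(spec$n_code), ] <- probe$evidence$counts
      colnames(counts) <- BASES
      dec <- decode_counts(counts, layout, library, limits, mode = mode)
      decoded[i] <- identical(dec$payload, payload)
    }
  }
  list(success_rate = mean(decoded), n_fixtures = n_fixtures,
       decoded = decoded)
}

#' Depth sweep: failed matrices and accuracies per depth and mode
#'
#' For each depth, encodes a seeded random payload into matrices,
#' simulates the channel at that depth, builds (or reuses) a Monte-Carlo
#' transition library, decodes in the requested modes and tabulates the
#' failed-matrix counts plus the three ground-truth accuracy metrics.
#'
#' @param alphabet The codec `composite_alphabet` (power-of-two size).
#' @param spec An `rs_spec` with matching field order.
#' @param depths Integer vector of sequencing depths.
#' @param p_error Per-base error probability (default 0.01).
#' @param n_matrices Matrices per depth (default 20).
#' @param modes Subset of `c("hard", "soft")`.
#' @param limits A `search_limits`.
#' @param n_draws Monte-Carlo draws per letter for each depth's library.
#' @param seed Base seed; payload, channel and library seeds derive from
#'   it.
#' @param libraries Optional named list of prebuilt `transition_library`
#'   objects keyed by depth (as character), overriding the MC build.
#' @return `data.frame` with columns `depth`, `mode`, `matrices`,
#'   `failed_matrices`, `letter_inference_accuracy`,
#'   `position_prediction_accuracy`, `true_letter_prediction_accuracy`.
#' @export
run_depth_sweep <- function(alphabet, spec, depths, p_error = 0.01,
                            n_matrices = 20L, modes = c("hard", "soft"),
                            limits = search_limits(), n_draws = 20000L,
                            seed = 1L, libraries = NULL) {
  layout <- matrix_layout(alphabet, spec)
  payload <- random_payload(layout$payload_bytes * n_matrices - 4L,
                            seed = seed)
  archive <- encode_bytes(payload, layout)
  letters <- archive_letters(archive)
  rows <- list()
  for (depth in depths) {
    key <- as.character(depth)
    lib <- if (!is.null(libraries) && !is.null(libraries[[key]]))
      libraries[[key]]
    else build_library_mc(alphabet,
                          channel_params(p_error, depth),
                          n_draws = n_draws, seed = seed + depth)
    counts <- simulate_sequence(letters,
                                channel_params(p_error, depth,
                                               seed = seed + depth + 1L))
    for (mode in modes) {
      dec <- decode_counts(counts, layout, lib, limits, mode = mode,
                           ground_truth = archive)
      r <- dec$report
      rows[[length(rows) + 1L]] <- data.frame(
        depth = depth, mode = mode, matrices = r$matrices_total,
        failed_matrices = r$matrices_failed,
        letter_inference_accuracy = r$letter_inference_accuracy,
        position_prediction_accuracy =
          if (is.null(r$position_prediction_accuracy)) NA_real_
          else r$position_prediction_accuracy,
        true_letter_prediction_accuracy =
          if (is.null(r$true_letter_prediction_accuracy)) NA_real_
          else r$true_letter_prediction_accuracy)
    }
  }
  do.call(rbind, rows)
}

#' Build the standard alphabet / library stack for a codec configuration
#'
#' The full resolution-k alphabet is enumerated; a Monte-Carlo transition
#' library at the target depth ranks its letters by error rate; the
#' lowest-error `size` letters become the codec alphabet; a second
#' library is then built on that subset (inference during decoding is
#' restricted to the subset, so its transition structure differs from the
#' full alphabet's).
#'
#' @param k_res Resolution.
#' @param size Codec alphabet size (power of two for the byte codec).
#' @param depth_N Target sequencing depth.
#' @param p_error Per-base error probability.
#' @param n_draws Monte-Carlo draws per letter.
#' @param seed Integer seed.
#' @return List with `full` (alphabet), `alphabet` (subset), `library`
#'   (subset library), `full_library`.
#' @export
build_alphabet_stack <- function(k_res, size, depth_N, p_error = 0.01,
                                 n_draws = 20000L, seed = 1L) {
  full <- enumerate_full_alphabet(k_res)
  params <- channel_params(p_error, depth_N)
  full_library <- build_library_mc(full, params, n_draws = n_draws,
                                   seed = seed)
  sub <- if (size == nrow(full$letters)) full
         else select_low_error_subset(full, size, full_library)
  library <- if (size == nrow(full$letters)) full_library
             else build_library_mc(sub, params, n_draws = n_draws,
                                   seed = seed + 1L)
  list(full = full, alphabet = sub, library = library,
       full_library = full_library)
}
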