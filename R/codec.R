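#' Archive layout: RS blocks, matrices and CRC32
#'
#' The archive groups `blocks_per_matrix` RS codewords into a matrix
#' protected by one CRC32. Each matrix carries
#' `blocks_per_matrix * k_info * m` information bits (m = bits per
#' letter); the final 32 bits hold the CRC of the matrix's payload bytes,
#' the leading `payload_bytes` bytes hold payload, and any slack bits in
#' between are zero. The alphabet size must equal the RS field order so
#' that symbol = letter index.
#'
#' @param alphabet A power-of-two `composite_alphabet`.
#' @param spec An `rs_spec` with `field_order == |alphabet|`.
#' @param blocks_per_matrix Blocks jointly protected by one CRC32
#'   (default 10).
#' @return An object of class `matrix_layout` with derived fields
#'   `bits_per_letter`, `info_bits` (per matrix), `payload_bytes` (per
#'   matrix), `letters_per_matrix`.
#' @export
matrix_layout <- function(alphabet, spec, blocks_per_matrix = 10L) {
  stopifnot(inherits(alphabet, "composite_alphabet"),
            inherits(spec, "rs_spec"))
  m <- bits_per_letter(alphabet)  # errors on non-power-of-two sizes
  if (nrow(alphabet$letters) != spec$field_order)
    stop("alphabet size must equal the RS field order (symbol = letter)",
         call. = FALSE)
  blocks_per_matrix <- as.integer(blocks_per_matrix)
  stopifnot(blocks_per_matrix >= 1L)
  info_bits <- blocks_per_matrix * spec$k_info * m
  if (info_bits < 40L)  # 32 CRC bits + at least one payload byte
    stop("matrix too small to carry a CRC32 and payload", call. = FALSE)
  structure(list(alphabet = alphabet, spec = spec,
                 blocks_per_matrix = blocks_per_matrix,
                 bits_per_letter = m,
                 info_bits = info_bits,
                 payload_bytes = (info_bits - 32L) %/% 8L,
                 letters_per_matrix = blocks_per_matrix * spec$n_code),
            class = "matrix_layout")
}

# ---- bit plumbing (big-endian bit order throughout) ----

bytes_to_bits <- function(bytes) {
  if (length(bytes) == 0L) return(integer(0L))
  as.vector(matrix(as.integer(rawToBits(bytes)), nrow = 8L)[8:1, ])
}

bits_to_bytes <- function(bits) {
  stopifnot(length(bits) %% 8L == 0L)
  if (length(bits) == 0L) return(raw(0L))
  packBits(as.vector(matrix(as.integer(bits), nrow = 8L)[8:1, ]), "raw")
}

bits_to_symbols <- function(bits, m) {
  stopifnot(length(bits) %% m == 0L)
  weights <- 2^((m - 1L):0L)
  as.integer(colSums(matrix(bits, nrow = m) * weights))
}

symbols_to_bits <- function(symbols, m) {
  out <- matrix(0L, m, length(symbols))
  v <- as.integer(symbols)
  for (j in m:1L) {
    out[j, ] <- v %% 2L
    v <- v %/% 2L
  }
  as.vector(out)
}

#' Pack letters into bytes and back
#'
#' Each letter of a power-of-two alphabet contributes
#' `log2(|alphabet|)` bits, big-endian, left-to-right across positions.
#' `letters_to_bytes` requires the total bit count to be a whole number
#' of bytes.
#'
#' @param letters Integer vector of 1-based letter indices.
#' @param bytes A raw vector.
#' @param alphabet A power-of-two `composite_alphabet`.
#' @return `letters_to_bytes`: raw vector; `bytes_to_letters`: integer
#'   vector of letter indices.
#' @export
letters_to_bytes <- function(letters, alphabet) {
  m <- bits_per_letter(alphabet)
  bits_to_bytes(symbols_to_bits(as.integer(letters) - 1L, m))
}

#' @rdname letters_to_bytes
#' @export
bytes_to_letters <- function(bytes, alphabet) {
  m <- bits_per_letter(alphabet)
  bits_to_symbols(bytes_to_bits(bytes), m) + 1L
}

# ---- encoding ----

#' Encode a byte payload into composite-letter matrices
#'
#' The payload is prefixed with its 4-byte big-endian length, chunked into
#' matrices (zero-padding the last), and per matrix: the CRC32 of the
#' matrix's payload bytes is planted in the last 32 information bits, the
#' information bits are split into `k_info`-symbol groups, each group is
#' RS-encoded, and symbols map to letters.
#'
#' @param payload Raw vector (non-empty).
#' @param layout A `matrix_layout`.
#' @return List of class `letter_archive`: one integer vector of 1-based
#'   letter indices per matrix (`blocks_per_matrix * n_code` letters,
#'   blocks concatenated in order), with the layout attached as attribute
#'   `layout`.
#' @export
encode_bytes <- function(payload, layout) {
  stopifnot(inherits(layout, "matrix_layout"))
  if (!is.raw(payload) || length(payload) == 0L)
    stop("payload must be a non-empty raw vector", call. = FALSE)
  if (length(payload) > 2^31 - 1)
    stop("payload too large for the 4-byte length prefix", call. = FALSE)
  len <- length(payload)
  prefix <- as.raw(c(bitwAnd(bitwShiftR(len, 24L), 255L),
                     bitwAnd(bitwShiftR(len, 16L), 255L),
                     bitwAnd(bitwShiftR(len, 8L), 255L),
                     bitwAnd(len, 255L)))
  stream <- c(prefix, payload)
  P <- layout$payload_bytes
  n_mat <- ceiling(length(stream) / P)
  stream <- c(stream, raw(n_mat * P - length(stream)))
  spec <- layout$spec
  m <- layout$bits_per_letter
  out <- vector("list", n_mat)
  for (i in seq_len(n_mat)) {
    mbytes <- stream[((i - 1L) * P + 1L):(i * P)]
    info_bits <- c(bytes_to_bits(mbytes),
                   integer(layout$info_bits - 32L - 8L * P),
                   bytes_to_bits(crc32(mbytes)))
    info_sym <- bits_to_symbols(info_bits, m)
    letters <- integer(layout$letters_per_matrix)
    for (b in seq_len(layout$blocks_per_matrix)) {
      blk <- info_sym[((b - 1L) * spec$k_info + 1L):(b * spec$k_info)]
      letters[((b - 1L) * spec$n_code + 1L):(b * spec$n_code)] <-
        rs_encode(blk, spec) + 1L
    }
    out[[i]] <- letters
  }
  structure(out, layout = layout, class = "letter_archive")
}

#' Letters of an archive as one matrix of ratios
#' @param archive A `letter_archive`.
#' @return Integer matrix of letters (one row per position, all matrices
#'   concatenated).
#' @export
archive_letters <- function(archive) {
  layout <- attr(archive, "layout")
  idx <- unlist(archive, use.names = FALSE)
  layout$alphabet$letters[idx, , drop = FALSE]
}

#' Write / read a letter archive as TSV
#'
#' Columns `matrix`, `block`, `pos` (all 0-based), `letter_index`
#' (0-based symbol) and `ratio_string`.
#'
#' @param archive A `letter_archive`.
#' @param path File path.
#' @param layout A `matrix_layout` (for reading).
#' @return `read_archive_tsv` returns a `letter_archive`.
#' @export
write_archive_tsv <- function(archive, path) {
  layout <- attr(archive, "layout")
  n_code <- layout$spec$n_code
  rows <- lapply(seq_along(archive), function(i) {
    idx <- archive[[i]]
    data.frame(matrix = i - 1L,
               block = rep(seq_len(layout$blocks_per_matrix) - 1L,
                           each = n_code),
               pos = rep(seq_len(n_code) - 1L, layout$blocks_per_matrix),
               letter_index = idx - 1L,
               ratio_string = letter_labels(
                 layout$alphabet$letters[idx, , drop = FALSE]))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_archive_tsv
#' @export
read_archive_tsv <- function(path, layout) {
  df <- utils::read.delim(path)
  df <- df[order(df$matrix, df$block, df$pos), ]
  out <- lapply(split(df$letter_index + 1L, df$matrix), as.integer)
  names(out) <- NULL
  structure(out, layout = layout, class = "letter_archive")
}

# ---- decoding ----

#' Decode a stream of observed counts back to bytes
#'
#' The full decode loop: per block, MAP-infer letters, hard-decode, soft
#' decode on failure, validate against the transition library; per
#' matrix, verify the CRC32 and, on failure, re-decode blocks flagged as
#' decoder-error suspects with their failed codewords excluded (up to
#' `max_block_passes` rounds). Matrices that still fail are counted and
#' their payload zero-filled.
#'
#' @param counts Integer matrix (columns A, C, G, T), one row per
#'   position; `nrow` must equal matrices x blocks x n_code.
#' @param layout A `matrix_layout`.
#' @param library A `transition_library` built on the layout's alphabet at
#'   the stream's depth.
#' @param limits A `search_limits`.
#' @param mode `"soft"` (default) or `"hard"` (pure hard-decision
#'   baseline: no substitution search, no library validation).
#' @param ground_truth Optional `letter_archive` (or list of letter-index
#'   vectors) with the transmitted letters; enables the accuracy fields
#'   of the report.
#' @return List with `payload` (raw vector) and `report` (a
#'   `decode_report`): counts of matrices total/failed, blocks soft
#'   decoded, decoder errors detected, iteration totals, and - when
#'   ground truth is given - `letter_inference_accuracy`,
#'   `position_prediction_accuracy`, `true_letter_prediction_accuracy`
#'   plus the tallies behind them.
#' @export
decode_counts <- function(counts, layout, library, limits = search_limits(),
                          mode = c("soft", "hard"), ground_truth = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "matrix_layout"))
  spec <- layout$spec
  lpm <- layout$letters_per_matrix
  if (nrow(counts) %% lpm != 0L)
    stop("counts length is not a whole number of matrices", call. = FALSE)
  n_mat <- nrow(counts) %/% lpm
  if (!identical(library$alphabet$letters, layout$alphabet$letters))
    stop("library alphabet does not match layout alphabet", call. = FALSE)
  truth <- if (!is.null(ground_truth)) unlist(ground_truth, use.names = FALSE)
  if (!is.null(truth) && length(truth) != nrow(counts))
    stop("ground truth length does not match counts", call. = FALSE)

  call <- infer_letters(counts, layout$alphabet, library$p_error)
  n_code <- spec$n_code
  bpm <- layout$blocks_per_matrix
  m <- layout$bits_per_letter
  P <- layout$payload_bytes

  payload <- vector("list", n_mat)
  failed <- 0L
  soft_blocks <- 0L
  decoder_errors <- 0L
  iter_total <- 0L
  # ground-truth tallies for the soft-path metrics
  gt_err_in_soft <- 0L     # truly erroneous positions in soft-decoded blocks
  gt_err_covered <- 0L     # ... that made it into the final candidate set
  gt_alt_hit <- 0L         # covered ones whose alternative set holds truth
  alt_tab <- if (mode == "soft")
    alternatives_table(library, limits$max_alternatives)

  for (mi in seq_len(n_mat)) {
    rows <- ((mi - 1L) * lpm + 1L):(mi * lpm)
    block_res <- vector("list", bpm)
    block_ev <- vector("list", bpm)
    excluded <- rep(list(character()), bpm)
    for (b in seq_len(bpm)) {
      brows <- rows[((b - 1L) * n_code + 1L):(b * n_code)]
      ev <- block_evidence(counts[brows, , drop = FALSE], layout$alphabet,
                           library$p_error,
                           inferred = call$index[brows],
                           distance = call$distance[brows])
      block_ev[[b]] <- ev
      res <- decode_block(ev, library, spec, limits, mode = mode)
      iter_total <- iter_total + res$iterations_used
      if (mode == "soft" && (nrow(res$substitutions) > 0L ||
                             res$status != "decoded"))
        soft_blocks <- soft_blocks + 1L
      if (isTRUE(res$decoder_error_suspect))
        decoder_errors <- decoder_errors + 1L
      excluded[[b]] <- res$excluded_solutions
      block_res[[b]] <- res
      if (!is.null(truth) && mode == "soft" &&
          (nrow(res$substitutions) > 0L || res$status != "decoded")) {
        t_idx <- truth[brows]
        err_pos <- which(ev$inferred != t_idx)
        gt_err_in_soft <- gt_err_in_soft + length(err_pos)
        d_final <- min(limits$max_positions, n_code)
        cand <- rank_candidate_positions(ev, d_final)
        cov <- intersect(err_pos, cand)
        gt_err_covered <- gt_err_covered + length(cov)
        for (p in cov) {
          if (t_idx[p] %in% alt_tab$index[, ev$inferred[p]])
            gt_alt_hit <- gt_alt_hit + 1L
        }
      }
    }

    assemble <- function() {
      # returns list(ok, bytes) from the current block results
      if (any(vapply(block_res, function(r) r$status != "decoded",
                     logical(1))))
        return(list(ok = FALSE))
      info_sym <- unlist(lapply(block_res, function(r)
        (r$codeword - 1L)[seq_len(spec$k_info)]), use.names = FALSE)
      bits <- symbols_to_bits(info_sym, m)
      mbytes <- bits_to_bytes(bits[seq_len(8L * P)])
      crc_bits <- bits[(layout$info_bits - 31L):layout$info_bits]
      ok <- identical(bits_to_bytes(crc_bits), crc32(mbytes))
      list(ok = ok, bytes = mbytes)
    }

    res_m <- assemble()
    if (!res_m$ok && mode == "soft" && limits$max_block_passes > 0L) {
      for (pass in seq_len(limits$max_block_passes)) {
        suspects <- which(vapply(block_res, function(r)
          isTRUE(r$decoder_error_suspect) || r$status != "decoded",
          logical(1)))
        if (length(suspects) == 0L) {
          # no flagged block: distrust every block the decoder changed
          suspects <- which(vapply(block_res, function(r)
            r$status == "decoded" &&
              (nrow(r$substitutions) > 0L ||
                 !is.na(r$n_rs_corrected) && r$n_rs_corrected > 0L),
            logical(1)))
        }
        if (length(suspects) == 0L) break
        for (b in suspects) {
          prev <- block_res[[b]]
          if (prev$status == "decoded")
            excluded[[b]] <- union(excluded[[b]],
                                   codeword_key(prev$codeword - 1L))
          res <- decode_block(block_ev[[b]], library, spec, limits,
                              mode = "soft", excluded = excluded[[b]])
          iter_total <- iter_total + res$iterations_used
          if (isTRUE(res$decoder_error_suspect))
            decoder_errors <- decoder_errors + 1L
          excluded[[b]] <- res$excluded_solutions
          block_res[[b]] <- res
        }
        res_m <- assemble()
        if (res_m$ok) break
      }
    }
    if (res_m$ok) {
      payload[[mi]] <- res_m$bytes
    } else {
      failed <- failed + 1L
      payload[[mi]] <- raw(P)
    }
  }

  stream <- do.call(c, payload)
  len <- sum(as.integer(stream[1:4]) * c(2^24, 2^16, 2^8, 1))
  payload_out <- if (len <= length(stream) - 4L)
    stream[4L + seq_len(len)] else stream[-(1:4)]

  report <- list(matrices_total = n_mat,
                 matrices_failed = failed,
                 blocks_soft_decoded = soft_blocks,
                 decoder_errors_detected = decoder_errors,
                 rs_decode_attempts = iter_total)
  if (!is.null(truth)) {
    report$letter_inference_accuracy <- mean(call$index == truth)
    report$position_prediction_accuracy <-
      if (gt_err_in_soft > 0L) gt_err_covered / gt_err_in_soft else NA_real_
    report$true_letter_prediction_accuracy <-
      if (gt_err_covered > 0L) gt_alt_hit / gt_err_covered else NA_real_
    report$soft_error_positions <- gt_err_in_soft
    report$soft_error_positions_covered <- gt_err_covered
  }
  class(report) <- "decode_report"
  list(payload = payload_out, report = report)
}

#' @export
print.decode_report <- function(x, ...) {
  cat(sprintf("decode_report: %d/%d matrices failed, %d block(s) soft-decoded, %d decoder error(s) detected\n",
              x$matrices_failed, x$matrices_total, x$blocks_soft_decoded,
              x$decoder_errors_detected))
  if (!is.null(x$letter_inference_accuracy))
    cat(sprintf("  letter inference %.4f | positions prediction %s | true letters prediction %s\n",
                x$letter_inference_accuracy,
                format(x$position_prediction_accuracy, digits = 4),
                format(x$true_letter_prediction_accuracy, digits = 4)))
  invisible(x)
}
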