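#' Channel parameters for the composite-letter storage channel
#'
#' The channel lumps synthesis, storage, PCR and sequencing into two
#' effects: a per-base substitution-style error rate `p_error` applied to
#' the nominal mixture ratios, and multinomial sampling of `depth_N` reads
#' per position. `copy_scale_f` is the effective molecule count used only
#' by the exact binomial-product scoring oracle (the number of molecules
#' carrying each position before down-sampling to `depth_N` reads).
#'
#' @param p_error Per-base error probability in `[0, 1)`. Default 0.01.
#' @param depth_N Integer sequencing depth (reads per position), >= 0.
#' @param copy_scale_f Effective molecule count for the exact-mode scoring
#'   oracle; must be >= `depth_N`. Default 1e6.
#' @param seed Optional integer RNG seed for sampling operations.
#' @return An object of class `channel_params`.
#' @export
channel_params <- function(p_error = 0.01, depth_N, copy_scale_f = 1e6,
                           seed = NULL) {
  if (p_error < 0 || p_error >= 1)
    stop("`p_error` must satisfy 0 <= p_error < 1", call. = FALSE)
  depth_N <- as.integer(depth_N)
  if (is.na(depth_N) || depth_N < 0L)
    stop("`depth_N` must be a non-negative integer", call. = FALSE)
  if (copy_scale_f < depth_N)
    stop("`copy_scale_f` must be >= depth_N", call. = FALSE)
  structure(list(p_error = p_error, depth_N = depth_N,
                 copy_scale_f = copy_scale_f, seed = seed),
            class = "channel_params")
}

#' Expected base distribution of a composite letter under the channel
#'
#' The probability that one sampled read shows base i for a letter with
#' ratio sigma at resolution k is
#' `q_i = (sigma_i / k) (1 - p_error) + (p_error / 3) (1 - sigma_i / k)`:
#' a base is either read faithfully from the mixture or substituted
#' uniformly by one of the other three bases.
#'
#' @param letter Integer 4-vector ratio (its sum is the resolution k).
#' @param p_error Per-base error probability in `[0, 1)`.
#' @return Numeric probability 4-vector summing to 1.
#' @export
expected_base_distribution <- function(letter, p_error) {
  letter <- as.numeric(letter)
  stopifnot(length(letter) == 4L, all(letter >= 0), sum(letter) >= 1)
  frac <- letter / sum(letter)
  frac * (1 - p_error) + (p_error / 3) * (1 - frac)
}

# Row-wise expected distributions for a whole alphabet: |Sigma| x 4 matrix.
expected_base_matrix <- function(alphabet, p_error) {
  frac <- alphabet$letters / alphabet$k
  frac * (1 - p_error) + (p_error / 3) * (1 - frac)
}

#' Sample observed base counts for one letter
#'
#' One multinomial draw of `depth_N` reads from the letter's expected base
#' distribution.
#'
#' @param letter Integer 4-vector ratio.
#' @param params A `channel_params`.
#' @return An `observed_counts` object: integer 4-vector of counts (A, C,
#'   G, T) with attribute `depth_N`.
#' @export
sample_observed <- function(letter, params) {
  stopifnot(inherits(params, "channel_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  q <- expected_base_distribution(letter, params$p_error)
  x <- if (params$depth_N == 0L) integer(4L) else
    as.integer(stats::rmultinom(1L, params$depth_N, q))
  observed_counts(x)
}

#' Observed base counts at one position
#' @param counts Integer 4-vector (A, C, G, T) of read counts.
#' @return Integer 4-vector of class `observed_counts` with names A,C,G,T.
#' @export
observed_counts <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) != 4L || anyNA(counts) || any(counts < 0L))
    stop("counts must be 4 non-negative integers", call. = FALSE)
  structure(counts, names = BASES, class = "observed_counts")
}

#' Simulate observed counts for a letter sequence
#'
#' Positions are treated as independent: each row of the output is one
#' multinomial draw of `depth_N` reads from the corresponding letter's
#' expected base distribution.
#'
#' @param letters Integer matrix of letters (one row per position) or a
#'   single 4-vector.
#' @param params A `channel_params` (its `seed`, when non-NULL, makes the
#'   simulation reproducible).
#' @return Integer matrix with columns A, C, G, T; one row per position.
#' @export
simulate_sequence <- function(letters, params) {
  stopifnot(inherits(params, "channel_params"))
  if (is.null(dim(letters))) letters <- matrix(letters, nrow = 1L)
  n <- nrow(letters)
  out <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  if (n == 0L || params$depth_N == 0L) return(out[seq_len(n), , drop = FALSE])
  if (!is.null(params$seed)) set.seed(params$seed)
  # group identical letters so each group is one vectorized rmultinom call
  lab <- letter_labels(letters)
  for (g in unique(lab)) {
    rows <- which(lab == g)
    q <- expected_base_distribution(letters[rows[1L], ], params$p_error)
    out[rows, ] <- t(stats::rmultinom(length(rows), params$depth_N, q))
  }
  out
}

#' Write / read a per-position base-count table (TSV)
#'
#' Tab-separated table with header `pos A C G T`; positions are 0-based.
#'
#' @param counts Integer matrix with columns A, C, G, T.
#' @param path File path.
#' @return `read_counts_tsv` returns the counts matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(pos = seq_len(nrow(counts)) - 1L, counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("pos", BASES) %in% names(df)))
  m <- as.matrix(df[order(df$pos), BASES])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

#' Export simulated reads as FASTA
#'
#' Renders `depth_N` standard-nucleotide reads consistent with a simulated
#' count table: at each position the counted bases are dealt across reads
#' in a seeded random order, so column tallies reproduce the counts
#' exactly and there is exact positional correspondence (no alignment
#' step).
#'
#' @param counts Integer matrix with columns A, C, G, T (constant row sum).
#' @param path Output FASTA path.
#' @param seq_id Identifier stem; reads are named `sim_<seq_id>_<r>`.
#' @param seed Integer seed for the per-position shuffle.
#' @return Invisibly, the path.
#' @export
write_reads_fasta <- function(counts, path, seq_id = "seq", seed = 1L) {
  depth <- unique(rowSums(counts))
  if (length(depth) != 1L)
    stop("all positions must have the same depth", call. = FALSE)
  set.seed(seed)
  reads <- matrix("", nrow = depth, ncol = nrow(counts))
  for (p in seq_len(nrow(counts))) {
    reads[, p] <- sample(rep(BASES, counts[p, ]))
  }
  lines <- character(2L * depth)
  lines[c(TRUE, FALSE)] <- sprintf(">sim_%s_%d", seq_id, seq_len(depth))
  lines[c(FALSE, TRUE)] <- apply(reads, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}
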