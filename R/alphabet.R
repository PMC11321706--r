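BASES <- c("A", "C", "G", "T")

#' Enumerate all 4-part integer compositions of a total
#'
#' Returns every non-negative integer 4-vector summing to `n`, ordered
#' lexicographically descending on (A, C, G, T). Used both for composite
#' alphabets (compositions of the resolution k) and for the space of
#' observable base-count vectors at a sequencing depth N.
#'
#' @param n Non-negative integer total.
#' @return Integer matrix with 4 columns (A, C, G, T), one row per
#'   composition; `choose(n + 3, 3)` rows.
#' @keywords internal
compositions4 <- function(n) {
  stopifnot(length(n) == 1L, n >= 0L)
  n <- as.integer(n)
  rows <- vector("list", choose(n + 3L, 3L))
  r <- 0L
  for (a in n:0L) for (b in (n - a):0L) for (cc in (n - a - b):0L) {
    r <- r + 1L
    rows[[r]] <- c(a, b, cc, n - a - b - cc)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- BASES
  m
}

#' Construct a composite alphabet
#'
#' A composite letter is a position-level mixture of the four nucleotides in
#' a fixed integer ratio sigma = (sigma_A, sigma_C, sigma_G, sigma_T); the
#' resolution k is the sum of the four parts. An alphabet is an ordered set
#' of distinct letters sharing one resolution; the order fixes the
#' letter-to-symbol mapping, so it is kept deterministic (lexicographic
#' descending on the ratio vector).
#'
#' @param k_res Integer resolution (sum of ratio parts), >= 1.
#' @param letters Integer matrix with 4 columns, one letter per row. Rows
#'   must be distinct and sum to `k_res`. They are re-sorted into the
#'   canonical descending lexicographic order.
#' @return An object of class `composite_alphabet` with elements `k`
#'   (resolution) and `letters` (integer matrix, columns A, C, G, T).
#' @export
composite_alphabet <- function(k_res, letters) {
  k_res <- as.integer(k_res)
  if (length(k_res) != 1L || is.na(k_res) || k_res < 1L)
    stop("`k_res` must be a single integer >= 1", call. = FALSE)
  letters <- as.matrix(letters)
  storage.mode(letters) <- "integer"
  if (ncol(letters) != 4L)
    stop("letters must have exactly 4 parts (A, C, G, T)", call. = FALSE)
  if (any(letters < 0L) || any(rowSums(letters) != k_res))
    stop("each letter must be a non-negative 4-vector summing to k_res",
         call. = FALSE)
  letters <- letters[lex_order_desc(letters), , drop = FALSE]
  if (anyDuplicated(letter_labels(letters)))
    stop("letters must be distinct", call. = FALSE)
  colnames(letters) <- BASES
  rownames(letters) <- NULL
  structure(list(k = k_res, letters = letters),
            class = "composite_alphabet")
}

# order() permutation for descending lexicographic order on rows
lex_order_desc <- function(m) {
  order(-m[, 1L], -m[, 2L], -m[, 3L], -m[, 4L])
}

#' Ratio-string labels for letters ("1,1,0,0")
#' @param letters Integer matrix of letters (rows) or a single 4-vector.
#' @return Character vector of comma-separated ratio strings.
#' @export
letter_labels <- function(letters) {
  if (is.null(dim(letters))) letters <- matrix(letters, nrow = 1L)
  apply(letters, 1L, paste, collapse = ",")
}

#' Full composite alphabet at resolution k
#'
#' Enumerates every 4-part composition of `k_res` exactly once: the alphabet
#' Phi_k of size `choose(k_res + 3, 3)` (10 letters at k = 2, 84 at k = 6,
#' 286 at k = 10).
#'
#' @param k_res Integer resolution >= 1.
#' @return A `composite_alphabet`.
#' @examples
#' nrow(enumerate_full_alphabet(2)$letters)  # 10
#' @export
enumerate_full_alphabet <- function(k_res) {
  if (length(k_res) != 1L || is.na(k_res) || k_res < 1L)
    stop("`k_res` must be a single integer >= 1", call. = FALSE)
  composite_alphabet(k_res, compositions4(k_res))
}

#' Select the lowest-error-rate subset of an alphabet
#'
#' Picks the `size` letters with the smallest per-letter error rate under a
#' transition library built for the same alphabet at the target sequencing
#' depth, breaking ties by the canonical lexicographic order. The result is
#' re-indexed as its own alphabet (canonical order preserved), so the size-s
#' subset is always contained in the size-(s+1) subset for a fixed library.
#'
#' @param full The full `composite_alphabet` the library was built for.
#' @param size Number of letters to keep (<= alphabet size).
#' @param library A `transition_library` built on `full` (same k, same
#'   letters, at the experiment's target depth).
#' @return A `composite_alphabet` of `size` letters.
#' @export
select_low_error_subset <- function(full, size, library) {
  stopifnot(inherits(full, "composite_alphabet"),
            inherits(library, "transition_library"))
  size <- as.integer(size)
  if (size < 1L || size > nrow(full$letters))
    stop("`size` must be between 1 and the alphabet size", call. = FALSE)
  if (library$k != full$k ||
      !identical(library$alphabet$letters, full$letters))
    stop("library was not built for this alphabet", call. = FALSE)
  # alphabet rows are already in canonical order, so order() tie-breaks by
  # that order automatically
  keep <- sort(order(library$error_rate)[seq_len(size)])
  composite_alphabet(full$k, full$letters[keep, , drop = FALSE])
}

#' Bits encoded per letter by an alphabet
#'
#' The byte codec maps fixed-width bit groups to letters, so it requires a
#' power-of-two alphabet size; other sizes remain usable for simulation,
#' inference and transition analytics.
#'
#' @param alphabet A `composite_alphabet`.
#' @return Integer log2 of the alphabet size.
#' @export
bits_per_letter <- function(alphabet) {
  stopifnot(inherits(alphabet, "composite_alphabet"))
  n <- nrow(alphabet$letters)
  m <- as.integer(round(log2(n)))
  if (bitwShiftL(1L, m) != n)
    stop("alphabet size ", n, " is not a power of two: ",
         "unsupported for the byte codec", call. = FALSE)
  m
}

#' Index of given letters within an alphabet
#' @param alphabet A `composite_alphabet`.
#' @param letters Letter matrix (rows) or single 4-vector.
#' @return Integer indices (1-based); error if a letter is absent.
#' @export
letter_index <- function(alphabet, letters) {
  idx <- match(letter_labels(letters), letter_labels(alphabet$letters))
  if (anyNA(idx)) stop("letter not present in alphabet", call. = FALSE)
  idx
}

#' @export
print.composite_alphabet <- function(x, ...) {
  cat(sprintf("composite_alphabet: k = %d, %d letters\n",
              x$k, nrow(x$letters)))
  n <- nrow(x$letters)
  shown <- letter_labels(x$letters[seq_len(min(6L, n)), , drop = FALSE])
  cat("  ", paste(shown, collapse = "  "),
      if (n > 6L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize an alphabet as JSON
#'
#' Format: `{"k": k, "letters": [[sA,sC,sG,sT], ...]}` in canonical order.
#'
#' @param alphabet A `composite_alphabet`.
#' @param path File path.
#' @return `alphabet_from_json` returns a `composite_alphabet`.
#' @export
alphabet_to_json <- function(alphabet, path) {
  stopifnot(inherits(alphabet, "composite_alphabet"))
  jsonlite::write_json(
    list(k = alphabet$k,
         letters = unname(apply(alphabet$letters, 1L, identity,
                                simplify = FALSE))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname alphabet_to_json
#' @export
alphabet_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  composite_alphabet(obj$k, obj$letters)
}

#' IUPAC shorthand for k = 2 letters where unambiguous
#'
#' For resolution-2 alphabets the mixed letters coincide with IUPAC
#' two-base ambiguity codes (e.g. M = (1,1,0,0), K = (0,0,1,1)); pure
#' letters render as A/C/G/T.
#'
#' @param letters Letter matrix (k = 2 rows) or single 4-vector.
#' @return Character vector; NA where no single-character code exists.
#' @export
iupac_shorthand <- function(letters) {
  if (is.null(dim(letters))) letters <- matrix(letters, nrow = 1L)
  codes <- c("2,0,0,0" = "A", "0,2,0,0" = "C", "0,0,2,0" = "G",
             "0,0,0,2" = "T", "1,1,0,0" = "M", "1,0,1,0" = "R",
             "1,0,0,1" = "W", "0,1,1,0" = "S", "0,1,0,1" = "Y",
             "0,0,1,1" = "K")
  unname(codes[letter_labels(letters)])
}
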