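# Galois field GF(2^m) arithmetic via log/antilog tables.
#
# Field elements are integers 0..(2^m - 1). The primitive polynomials are
# fixed per field order so that encodings are bit-exact across runs:
#   GF(8):   x^3 + x + 1                 (0x0B)
#   GF(16):  x^4 + x + 1                 (0x13)
#   GF(32):  x^5 + x^2 + 1               (0x25)
#   GF(64):  x^6 + x + 1                 (0x43)
#   GF(128): x^7 + x^3 + 1               (0x89)
#   GF(256): x^8 + x^4 + x^3 + x^2 + 1   (0x11D)

GF_PRIM_POLY <- c(`8` = 0x0BL, `16` = 0x13L, `32` = 0x25L, `64` = 0x43L,
                  `128` = 0x89L, `256` = 0x11DL)

gf_tables <- function(field_order, prim_poly = NULL) {
  q <- as.integer(field_order)
  m <- as.integer(round(log2(q)))
  if (bitwShiftL(1L, m) != q || m < 2L || m > 8L)
    stop("field_order must be 2^m with 2 <= m <= 8", call. = FALSE)
  if (is.null(prim_poly)) prim_poly <- GF_PRIM_POLY[[as.character(q)]]
  exp_tab <- integer(2L * (q - 1L))
  log_tab <- integer(q)  # log_tab[a + 1]; log of 0 unused
  x <- 1L
  for (i in 0:(q - 2L)) {
    exp_tab[i + 1L] <- x
    log_tab[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= q) x <- bitwXor(x, prim_poly)
  }
  exp_tab[q:(2L * (q - 1L))] <- exp_tab[1:(q - 1L)]
  list(q = q, m = m, prim_poly = prim_poly, exp = exp_tab, log = log_tab)
}

# vectorized multiply / divide / power in GF(2^m)
gf_mul <- function(a, b, gf) {
  out <- integer(max(length(a), length(b)))
  a <- rep_len(a, length(out)); b <- rep_len(b, length(out))
  nz <- a != 0L & b != 0L
  out[nz] <- gf$exp[gf$log[a[nz] + 1L] + gf$log[b[nz] + 1L] + 1L]
  out
}

gf_inv <- function(a, gf) {
  if (any(a == 0L)) stop("division by zero in GF", call. = FALSE)
  gf$exp[(gf$q - 1L) - gf$log[a + 1L] + 1L]
}

gf_pow_alpha <- function(e, gf) {
  # alpha^e for any integer exponent e (vectorized)
  gf$exp[(e %% (gf$q - 1L)) + 1L]
}

# polynomial helpers; coefficient vectors are low-degree first
gf_poly_mul <- function(p1, p2, gf) {
  out <- integer(length(p1) + length(p2) - 1L)
  for (i in seq_along(p1)) {
    if (p1[i] == 0L) next
    seg <- gf_mul(p1[i], p2, gf)
    idx <- i:(i + length(p2) - 1L)
    out[idx] <- bitwXor(out[idx], seg)
  }
  out
}

gf_poly_eval <- function(p, x, gf) {
  # Horner, vectorized over x; p low-degree first
  res <- integer(length(x))
  for (i in rev(seq_along(p))) {
    res <- bitwXor(gf_mul(res, x, gf), p[i])
  }
  res
}

#' Reed-Solomon code specification
#'
#' A systematic RS code over GF(2^m) with codeword length `n_code` and
#' `k_info` information symbols; the hard-decision decoder corrects up to
#' `t_correct = floor((n_code - k_info) / 2)` symbol errors. Symbols are
#' composite-letter indices, so the supported codec alphabets are the
#' power-of-two sizes 64, 128 and 256 (plus small fields for toy codes in
#' tests), with the default RS(45, 41) valid whenever
#' `n_code <= field_order - 1`.
#'
#' @param field_order Field size 2^m (one of 8, 16, 32, 64, 128, 256).
#' @param n_code Codeword length in symbols (default 45).
#' @param k_info Information symbols per codeword (default 41).
#' @param fcr First consecutive root exponent of the generator (default 1:
#'   roots alpha^1 .. alpha^(2t)).
#' @param prim_poly Primitive polynomial override (integer bit mask).
#' @return An object of class `rs_spec`.
#' @export
rs_spec <- function(field_order, n_code = 45L, k_info = 41L, fcr = 1L,
                    prim_poly = NULL) {
  gf <- gf_tables(field_order, prim_poly)
  n_code <- as.integer(n_code); k_info <- as.integer(k_info)
  if (n_code > gf$q - 1L)
    stop("n_code must be <= field_order - 1", call. = FALSE)
  if (k_info >= n_code || k_info < 1L)
    stop("need 1 <= k_info < n_code", call. = FALSE)
  n_par <- n_code - k_info
  t_correct <- n_par %/% 2L
  # generator g(x) = prod_{j=0}^{n_par-1} (x - alpha^(fcr + j))
  g <- 1L
  for (j in 0:(n_par - 1L)) {
    g <- gf_poly_mul(g, c(gf_pow_alpha(fcr + j, gf), 1L), gf)
  }
  # syndrome evaluation matrix: S_j = sum_p c_p * alpha^((fcr+j-1)*(n-p))
  # where c_p is the p-th transmitted symbol (coefficient of x^(n-p))
  deg <- n_code - seq_len(n_code)               # x-degree of each position
  synd_pow <- outer(fcr + 0:(n_par - 1L), deg)  # exponent matrix
  synd_mat <- matrix(gf_pow_alpha(synd_pow, gf), n_par, n_code)
  structure(list(gf = gf, field_order = gf$q, n_code = n_code,
                 k_info = k_info, t_correct = t_correct, fcr = fcr,
                 generator = g, synd_mat = synd_mat, deg = deg),
            class = "rs_spec")
}

#' @export
print.rs_spec <- function(x, ...) {
  cat(sprintf("rs_spec: RS(%d, %d) over GF(%d), t = %d, prim poly 0x%X\n",
              x$n_code, x$k_info, x$field_order, x$t_correct,
              x$gf$prim_poly))
  invisible(x)
}

#' Systematic Reed-Solomon encoding
#'
#' Information symbols first, then `n_code - k_info` parity symbols (the
#' remainder of `info(x) * x^(n-k)` modulo the generator polynomial).
#'
#' @param info Integer vector of `k_info` field elements.
#' @param spec An `rs_spec`.
#' @return Integer codeword of `n_code` symbols.
#' @export
rs_encode <- function(info, spec) {
  stopifnot(inherits(spec, "rs_spec"))
  info <- as.integer(info)
  if (length(info) != spec$k_info)
    stop("info must have exactly k_info symbols", call. = FALSE)
  if (any(info < 0L | info >= spec$field_order))
    stop("info symbols must be field elements", call. = FALSE)
  n_par <- spec$n_code - spec$k_info
  gf <- spec$gf
  # long division: work buffer holds info followed by n_par zeros,
  # high-degree first
  buf <- c(info, integer(n_par))
  g_desc <- rev(spec$generator)  # monic, high-degree first
  for (i in seq_len(spec$k_info)) {
    coef <- buf[i]
    if (coef != 0L) {
      idx <- i:(i + n_par)
      buf[idx] <- bitwXor(buf[idx], gf_mul(coef, g_desc, gf))
    }
  }
  c(info, buf[(spec$k_info + 1L):(spec$k_info + n_par)])
}

rs_syndromes <- function(received, spec) {
  # S_j over the received word; vectorized via the precomputed power matrix
  n_par <- spec$n_code - spec$k_info
  s <- integer(n_par)
  nz <- which(received != 0L)
  if (length(nz) == 0L) return(s)
  gf <- spec$gf
  for (j in seq_len(n_par)) {
    prods <- gf_mul(received[nz], spec$synd_mat[j, nz], gf)
    s[j] <- Reduce(bitwXor, prods)
  }
  s
}

# Update syndromes after substituting symbols at `positions` (1-based):
# delta contributions are linear.
rs_syndromes_update <- function(synd, old_sym, new_sym, positions, spec) {
  gf <- spec$gf
  delta <- bitwXor(old_sym, new_sym)
  keep <- delta != 0L
  if (!any(keep)) return(synd)
  delta <- delta[keep]; positions <- positions[keep]
  for (j in seq_along(synd)) {
    prods <- gf_mul(delta, spec$synd_mat[j, positions], gf)
    synd[j] <- bitwXor(synd[j], Reduce(bitwXor, prods))
  }
  synd
}

# Berlekamp-Massey: error locator polynomial from syndromes
# (coefficients low-degree first, Lambda[1] = 1).
rs_berlekamp_massey <- function(synd, spec) {
  gf <- spec$gf
  n_par <- length(synd)
  len <- n_par + 1L
  Lambda <- c(1L, integer(n_par))
  B <- c(1L, integer(n_par))
  L <- 0L
  b <- 1L
  m <- 1L
  for (r in seq_len(n_par)) {          # r is 1-based; syndrome S_r
    d <- synd[r]
    if (L > 0L) for (i in seq_len(min(L, r - 1L))) {
      d <- bitwXor(d, gf_mul(Lambda[i + 1L], synd[r - i], gf))
    }
    if (d == 0L) {
      m <- m + 1L
    } else {
      coef <- gf_mul(d, gf_inv(b, gf), gf)
      shiftB <- c(integer(m), B)[seq_len(len)]   # x^m * B(x), truncated
      Tn <- bitwXor(Lambda, gf_mul(coef, shiftB, gf))
      if (2L * L <= r - 1L) {
        B <- Lambda
        b <- d
        L <- r - L
        m <- 1L
      } else {
        m <- m + 1L
      }
      Lambda <- Tn
    }
  }
  list(Lambda = Lambda, L = L)
}

#' Hard-decision Reed-Solomon decoding
#'
#' Syndrome computation, Berlekamp-Massey, Chien search and Forney's
#' algorithm. If at most `t_correct` symbols are wrong, the transmitted
#' codeword is recovered; with more errors the decoder either fails or
#' commits a decoder error (miscorrection to a different valid codeword),
#' so a success is *unverified* from the decoder's point of view and
#' callers needing certainty must validate externally (transition-library
#' membership, CRC32).
#'
#' @param received Integer vector of `n_code` symbols.
#' @param spec An `rs_spec`.
#' @param synd Optional precomputed syndromes of `received`.
#' @return List with `ok` (logical), `codeword` (if `ok`), and
#'   `n_corrected` (number of symbols changed).
#' @export
rs_decode_hard <- function(received, spec, synd = NULL) {
  stopifnot(inherits(spec, "rs_spec"))
  received <- as.integer(received)
  if (length(received) != spec$n_code)
    stop("received word must have n_code symbols", call. = FALSE)
  if (is.null(synd)) synd <- rs_syndromes(received, spec)
  if (all(synd == 0L))
    return(list(ok = TRUE, codeword = received, n_corrected = 0L))
  gf <- spec$gf
  bm <- rs_berlekamp_massey(synd, spec)
  L <- bm$L
  if (L > spec$t_correct) return(list(ok = FALSE, n_corrected = NA_integer_))
  Lambda <- bm$Lambda[seq_len(L + 1L)]
  # Chien search over the degrees actually used by the code
  inv_loc <- gf_pow_alpha(-spec$deg, gf)        # alpha^(-deg_p) per position
  vals <- gf_poly_eval(Lambda, inv_loc, gf)
  err_pos <- which(vals == 0L)
  if (length(err_pos) != L) return(list(ok = FALSE, n_corrected = NA_integer_))
  # Forney: Omega(x) = S(x) Lambda(x) mod x^(2t)
  n_par <- length(synd)
  omega_full <- gf_poly_mul(c(synd), Lambda, gf)
  Omega <- omega_full[seq_len(min(n_par, length(omega_full)))]
  Xl <- gf_pow_alpha(spec$deg[err_pos], gf)      # error locators
  Xl_inv <- gf_inv(Xl, gf)
  # Lambda'(x): formal derivative (odd-degree terms)
  dLambda <- Lambda[-1L]
  dLambda[seq_along(dLambda) %% 2L == 0L] <- 0L  # keep even indices of Lambda
  num <- gf_poly_eval(Omega, Xl_inv, gf)
  den <- gf_poly_eval(dLambda, Xl_inv, gf)
  if (any(den == 0L)) return(list(ok = FALSE, n_corrected = NA_integer_))
  mag <- gf_mul(num, gf_inv(den, gf), gf)
  if (spec$fcr != 1L) {
    # magnitude formula carries X_l^(1 - fcr)
    mag <- gf_mul(mag, gf_pow_alpha((1L - spec$fcr) * spec$deg[err_pos], gf),
                  gf)
  }
  if (any(mag == 0L)) return(list(ok = FALSE, n_corrected = NA_integer_))
  corrected <- received
  corrected[err_pos] <- bitwXor(corrected[err_pos], mag)
  # self-consistency: the corrected word must be a true codeword
  if (!all(rs_syndromes(corrected, spec) == 0L))
    return(list(ok = FALSE, n_corrected = NA_integer_))
  list(ok = TRUE, codeword = corrected, n_corrected = length(err_pos))
}
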