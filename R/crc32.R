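# CRC-32/ISO-HDLC (polynomial 0x04C11DB7 reflected to 0xEDB88320,
# init 0xFFFFFFFF, final XOR 0xFFFFFFFF) - the zlib/gzip checksum.
# The running CRC is held in R's 32-bit signed integers; bitwShiftR is a
# logical shift on the bit pattern, so the unsigned algorithm carries over
# unchanged. 0xEDB88320 as a signed 32-bit constant is -306674912.

crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    poly <- -306674912L
    t <- integer(256L)
    for (i in 0:255L) {
      cc <- i
      for (rep in 1:8) {
        cc <- if (bitwAnd(cc, 1L) == 1L)
          bitwXor(bitwShiftR(cc, 1L), poly) else bitwShiftR(cc, 1L)
      }
      t[i + 1L] <- cc
    }
    tab <<- t
    tab
  }
})

#' CRC32 checksum of a byte vector
#'
#' Standard CRC-32/ISO-HDLC as used by zlib: check value of the ASCII
#' string "123456789" is 0xCBF43926; the CRC of the empty byte string is
#' 0x00000000. Used for matrix-level integrity in the codec.
#'
#' @param bytes A raw vector.
#' @return Raw vector of 4 bytes, big-endian (most significant byte
#'   first).
#' @export
crc32 <- function(bytes) {
  stopifnot(is.raw(bytes))
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  as.raw(c(bitwAnd(bitwShiftR(crc, 24L), 255L),
           bitwAnd(bitwShiftR(crc, 16L), 255L),
           bitwAnd(bitwShiftR(crc, 8L), 255L),
           bitwAnd(crc, 255L)))
}

#' @rdname crc32
#' @export
crc32_hex <- function(bytes) {
  paste0("0x", toupper(paste(format(crc32(bytes)), collapse = "")))
}
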