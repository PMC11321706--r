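test_that("CRC32 matches the standard check values", {
  expect_identical(crc32_hex(raw(0)), "0x00000000")
  expect_identical(crc32_hex(charToRaw("123456789")), "0xCBF43926")
  expect_identical(crc32(as.raw(c(0, 0, 0, 0))),
                   as.raw(c(0x21, 0x44, 0xdf, 0x1c)))
})

test_that("letter/byte transcoding round-trips across alphabet sizes", {
  phi10 <- enumerate_full_alphabet(10)
  alpha256 <- composite_alphabet(10, phi10$letters[1:256, ])
  # 256 letters: identity byte mapping
  set.seed(41)
  bytes <- as.raw(sample(0:255, 64, replace = TRUE))
  expect_identical(bytes_to_letters(bytes, alpha256),
                   as.integer(bytes) + 1L)
  expect_identical(letters_to_bytes(as.integer(bytes) + 1L, alpha256),
                   bytes)
  # 64 letters: 4 letters <-> 3 bytes
  alpha64 <- stack64()$alphabet
  letters <- bytes_to_letters(as.raw(c(0xFF, 0x00, 0xAB)), alpha64)
  expect_length(letters, 4L)
  expect_identical(letters_to_bytes(letters, alpha64),
                   as.raw(c(0xFF, 0x00, 0xAB)))
  # random round-trips for 4, 64, 128, 256 letters
  sizes <- list(enumerate_full_alphabet(1), alpha64,
                composite_alphabet(10, phi10$letters[1:128, ]), alpha256)
  for (alpha in sizes) {
    m <- bits_per_letter(alpha)
    n_bytes <- 3L * m  # whole number of letters
    payload <- as.raw(sample(0:255, n_bytes, replace = TRUE))
    expect_identical(letters_to_bytes(bytes_to_letters(payload, alpha),
                                      alpha),
                     payload)
  }
  expect_error(bytes_to_letters(bytes, enumerate_full_alphabet(6)),
               "power of two")
})

test_that("matrix layout derives sizes and guards the symbol mapping", {
  s <- stack64()
  layout <- matrix_layout(s$alphabet, rs_spec(64))
  expect_identical(layout$payload_bytes, (10L * 41L * 6L - 32L) %/% 8L)
  expect_identical(layout$letters_per_matrix, 450L)
  expect_error(matrix_layout(s$alphabet, rs_spec(128)), "field order")
  expect_error(encode_bytes(raw(0), layout), "payload")
})

test_that("noise-free encode/decode round-trips a 10 KiB payload", {
  s <- stack64()
  layout <- matrix_layout(s$alphabet, rs_spec(64))
  payload <- random_payload(10240, seed = 51)
  archive <- encode_bytes(payload, layout)
  letters <- archive_letters(archive)
  # noiseless counts: the expected count table itself
  exact <- t(vapply(seq_len(nrow(letters)), function(i)
    rounded_expected_counts(letters[i, ], 0.01, 190), integer(4L)))
  colnames(exact) <- c("A", "C", "G", "T")
  dec <- decode_counts(exact, layout, s$library, ground_truth = archive)
  expect_identical(dec$payload, payload)
  expect_identical(dec$report$matrices_failed, 0L)
  expect_equal(dec$report$letter_inference_accuracy, 1.0)
  # an error-free channel still has sampling bias; the codec must absorb it
  sim <- simulate_sequence(letters, channel_params(0, 190, seed = 52))
  dec2 <- decode_counts(sim, layout, s$library, ground_truth = archive)
  expect_identical(dec2$payload, payload)
  expect_identical(dec2$report$matrices_failed, 0L)
})

test_that("archives and decode reports are deterministic in the seed", {
  s <- stack64()
  layout <- matrix_layout(s$alphabet, rs_spec(64))
  payload <- random_payload(600, seed = 53)
  a1 <- encode_bytes(payload, layout)
  a2 <- encode_bytes(random_payload(600, seed = 53), layout)
  expect_identical(unclass(a1)[], unclass(a2)[])
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_archive_tsv(a1, f1)
  back <- read_archive_tsv(f1, layout)
  expect_identical(unclass(back)[], unclass(a1)[])
  c1 <- simulate_sequence(archive_letters(a1),
                          channel_params(0.01, 190, seed = 54))
  c2 <- simulate_sequence(archive_letters(a2),
                          channel_params(0.01, 190, seed = 54))
  expect_identical(c1, c2)
  d1 <- decode_counts(c1, layout, s$library, ground_truth = a1)
  d2 <- decode_counts(c2, layout, s$library, ground_truth = a2)
  expect_identical(d1$payload, d2$payload)
  expect_identical(unclass(d1$report), unclass(d2$report))
})

test_that("soft decoding recovers payloads the hard decoder loses", {
  sw <- sweep64()
  for (N in unique(sw$depth)) {
    hard <- sw$failed_matrices[sw$depth == N & sw$mode == "hard"]
    soft <- sw$failed_matrices[sw$depth == N & sw$mode == "soft"]
    expect_lte(soft, hard)
  }
  # at the 64-letter target depth nothing fails in soft mode
  expect_identical(sw$failed_matrices[sw$depth == 190 & sw$mode == "soft"],
                   0L)
})

test_that("failed-matrix counts do not increase with depth (soft mode)", {
  sw <- sweep64()
  soft <- sw[sw$mode == "soft", ]
  soft <- soft[order(soft$depth), ]
  expect_true(all(diff(soft$failed_matrices) <= 0))
  hard <- sw[sw$mode == "hard", ]
  hard <- hard[order(hard$depth), ]
  expect_true(all(diff(hard$failed_matrices) <= 0))
})

test_that("a miscorrected block is caught by CRC and re-decoded", {
  s <- stack64()
  sp <- rs_spec(64)
  layout <- matrix_layout(s$alphabet, sp)
  payload <- random_payload(layout$payload_bytes - 4L, seed = 55)
  archive <- encode_bytes(payload, layout)
  truth1 <- archive[[1]][1:45]
  # find a planted-error pattern on the matrix's own first block whose
  # plain hard decode lands on a wrong but valid codeword
  sd <- cached_fixture("miscorrect_seed_crc",
                       find_miscorrecting_seed(s, sp, truth = truth1))
  expect_false(is.na(sd))
  blk <- make_error_block(3, s$alphabet, s$library, sp, seed = sd,
                          truth = truth1)
  counts <- t(vapply(archive[[1]], function(i)
    rounded_expected_counts(s$alphabet$letters[i, ], 0.01, 190),
    integer(4L)))
  counts[1:45, ] <- blk$evidence$counts
  colnames(counts) <- c("A", "C", "G", "T")
  dec <- decode_counts(counts, layout, s$library, ground_truth = archive)
  expect_identical(dec$payload, payload)
  expect_identical(dec$report$matrices_failed, 0L)
  expect_gte(dec$report$decoder_errors_detected, 1L)
})
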