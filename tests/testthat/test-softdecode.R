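# toy letter-level code: 8 lowest-error letters of the resolution-2
# alphabet mapped onto RS(7,3)/GF(8), exact library at depth 12
toy_system <- function() {
  cached_fixture("toy8", {
    phi2 <- enumerate_full_alphabet(2)
    full_lib <- build_library_exact(phi2, channel_params(0.01, 12))
    alpha <- select_low_error_subset(phi2, 8, full_lib)
    lib <- build_library_exact(alpha, channel_params(0.01, 12))
    list(alphabet = alpha, library = lib, spec = rs73())
  })
}

toy_evidence <- function(truth_idx, sys) {
  counts <- t(vapply(truth_idx, function(i)
    rounded_expected_counts(sys$alphabet$letters[i, ], 0.01, 12),
    integer(4L)))
  colnames(counts) <- c("A", "C", "G", "T")
  block_evidence(counts, sys$alphabet, 0.01)
}

test_that("candidate positions are ranked by descending distance", {
  sys <- toy_system()
  truth <- rs_encode(c(1L, 5L, 2L), sys$spec) + 1L
  ev <- toy_evidence(truth, sys)
  # near-noiseless block: ties broken by ascending position
  expect_identical(rank_candidate_positions(toy_evidence(rep(1L, 7), sys),
                                            3),
                   1:3)
  # a perturbed position must rank first
  ev$distance[5] <- 0.5
  expect_identical(rank_candidate_positions(ev, 1), 5L)
  # random distances: agree with an independent sort oracle
  set.seed(14)
  ev$distance <- runif(7)
  for (d in c(1, 4, 7)) {
    expect_identical(rank_candidate_positions(ev, d),
                     order(ev$distance, decreasing = TRUE)[seq_len(d)])
  }
  expect_error(rank_candidate_positions(ev, 0), "d")
})

test_that("clean blocks decode with no soft substitutions", {
  sys <- toy_system()
  set.seed(21)
  for (i in 1:10) {
    truth <- rs_encode(sample(0:7, 3, replace = TRUE), sys$spec) + 1L
    res <- derrick_cp_decode(toy_evidence(truth, sys), sys$library,
                             sys$spec)
    expect_identical(res$status, "decoded")
    expect_identical(res$codeword, truth)
    expect_identical(nrow(res$substitutions), 0L)
  }
})

test_that("soft decoding never degrades a hard-decodable block", {
  sys <- toy_system()
  set.seed(22)
  for (i in 1:25) {
    truth <- rs_encode(sample(0:7, 3, replace = TRUE), sys$spec) + 1L
    ev <- toy_evidence(truth, sys)
    # corrupt up to t positions at the evidence level
    ne <- sample(0:2, 1)
    if (ne > 0) {
      pos <- sample(7, ne)
      ev$inferred[pos] <- ((ev$inferred[pos] + 2L) %% 8L) + 1L
      ev$distance[pos] <- ev$distance[pos] + 0.3
    }
    hard <- decode_block(ev, sys$library, sys$spec, mode = "hard")
    soft <- derrick_cp_decode(ev, sys$library, sys$spec)
    expect_identical(hard$codeword, truth)
    expect_identical(soft$codeword, truth)
    expect_identical(nrow(soft$substitutions), 0L)
  }
})

test_that("planted above-capability errors are recovered on RS(45,41)", {
  s <- stack64()
  sp <- rs_spec(64)
  for (sd in 1:6) {
    blk <- make_error_block(3, s$alphabet, s$library, sp, seed = 400 + sd)
    expect_identical(which(blk$evidence$inferred != blk$truth),
                     blk$error_positions)
    res <- decode_block(blk$evidence, s$library, sp)
    expect_identical(res$status, "decoded")
    if (res$decoder_error_suspect) {
      # the initial hard decode miscorrected (3 > t); the flag is the
      # designed behavior, and the CRC-triggered retry must recover
      res <- decode_block(blk$evidence, s$library, sp,
                          excluded = res$excluded_solutions)
    }
    expect_identical(res$codeword, blk$truth)
    expect_gte(nrow(res$substitutions), 1L)
  }
})

test_that("search completeness: all-substituted paths are reachable", {
  # 3 planted errors on the toy code (t = 1 short of them by two): with
  # permissive limits the decoder must reach the fully-substituted truth
  sys <- toy_system()
  lims <- search_limits(max_positions = 7L, max_alternatives = 2L)
  ok <- 0L
  for (sd in 1:10) {
    blk <- tryCatch(make_error_block(3, sys$alphabet, sys$library,
                                     sys$spec, seed = 500 + sd),
                    error = function(e) NULL)
    if (is.null(blk)) next
    res <- decode_block(blk$evidence, sys$library, sys$spec, lims)
    if (identical(res$codeword, blk$truth)) ok <- ok + 1L
    expect_identical(res$status, "decoded")
  }
  expect_gte(ok, 8L)
})

test_that("iteration budget is honored and exhaustion is a status", {
  s <- stack64()
  sp <- rs_spec(64)
  blk <- make_error_block(5, s$alphabet, s$library, sp, seed = 900)
  lims <- search_limits(max_iterations = 10L)
  res <- derrick_cp_decode(blk$evidence, s$library, sp, lims)
  expect_identical(res$status, "exhausted")
  expect_lte(res$iterations_used, 11L)
})

test_that("library validation flags implausible corrections", {
  s <- stack64()
  sp <- rs_spec(64)
  blk <- make_error_block(1, s$alphabet, s$library, sp, seed = 31)
  res <- decode_block(blk$evidence, s$library, sp)
  expect_identical(res$codeword, blk$truth)
  expect_true(validate_against_library(res, blk$evidence, s$library, 2))
  # a codeword whose "corrections" are arbitrary letters is rejected
  fake <- res
  pos <- blk$error_positions[1]
  wrong <- setdiff(seq_len(64),
                   c(blk$evidence$inferred[pos],
                     alternatives(s$library,
                                  blk$evidence$inferred[pos], 10)$index))
  fake$codeword[pos] <- wrong[1]
  expect_false(validate_against_library(fake, blk$evidence, s$library, 2))
  # trivially valid when decoded equals inferred everywhere
  clean <- make_error_block(0, s$alphabet, s$library, sp, seed = 32)
  res0 <- decode_block(clean$evidence, s$library, sp)
  expect_true(validate_against_library(res0, clean$evidence, s$library, 2))
})

test_that("a forced miscorrection is flagged and excluded on retry", {
  s <- stack64()
  sp <- rs_spec(64)
  sd <- cached_fixture("miscorrect_seed",
                       find_miscorrecting_seed(s, sp))
  expect_false(is.na(sd))
  blk <- make_error_block(3, s$alphabet, s$library, sp, seed = sd)
  # plain hard decoding lands on a wrong yet valid codeword
  hd <- rs_decode_hard(blk$evidence$inferred - 1L, sp)
  expect_true(hd$ok)
  expect_false(identical(hd$codeword + 1L, blk$truth))
  # soft decode accepts it but flags the block as a decoder-error suspect
  res <- decode_block(blk$evidence, s$library, sp)
  expect_true(res$decoder_error_suspect)
  expect_true(codeword_key(res$codeword - 1L) %in% res$excluded_solutions)
  # the matrix-level retry excludes the codeword; truth is then found
  res2 <- decode_block(blk$evidence, s$library, sp,
                       excluded = res$excluded_solutions)
  expect_identical(res2$codeword, blk$truth)
  expect_true(validate_against_library(res2, blk$evidence, s$library,
                                       search_limits()$validate_alternatives))
})
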