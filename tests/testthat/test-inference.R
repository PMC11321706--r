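test_that("log scores match closed forms", {
  expect_equal(log_score(c(10, 0, 0, 0), c(2, 0, 0, 0), 0), 0)
  expect_equal(log_score(c(5, 5, 0, 0), c(1, 1, 0, 0), 0), 10 * log(0.5))
  # impossible observation under a zero-probability base
  expect_identical(log_score(c(9, 1, 0, 0), c(2, 0, 0, 0), 0), -Inf)
})

test_that("exact binomial-product mode agrees with the multinomial limit", {
  # at large copy number the two scores must pick the same letter
  s6 <- sigma6_alphabet()
  set.seed(8)
  mismatches <- 0L
  for (i in 1:200) {
    truth <- sample(6, 1)
    X <- as.integer(stats::rmultinom(
      1, 15, expected_base_distribution(s6$letters[truth, ], 0.01)))
    sc_m <- vapply(seq_len(6), function(j)
      log_score(X, s6$letters[j, ], 0.01), numeric(1))
    sc_e <- vapply(seq_len(6), function(j)
      log_score(X, s6$letters[j, ], 0.01, mode = "exact",
                copy_scale_f = 1e6), numeric(1))
    if (which.max(sc_m) != which.max(sc_e)) mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("MAP inference picks the posterior-maximizing letter", {
  s6 <- sigma6_alphabet()
  # exact frequency match
  expect_identical(unname(infer_letter(c(5, 5, 0, 0), s6, 0.01)$letter),
                   c(1L, 1L, 0L, 0L))
  # skewed counts still resolve to M; scores match hand enumeration
  call <- infer_letter(c(7, 3, 0, 0), s6, 0.01)
  expect_identical(unname(call$letter), c(1L, 1L, 0L, 0L))
  expect_equal(call$candidates$log_score[1], -6.998362, tolerance = 1e-5)
  expect_equal(call$candidates$log_score[2], -17.1817, tolerance = 1e-4)
  # pure observation resolves to the pure letter
  expect_identical(unname(infer_letter(c(10, 0, 0, 0), s6, 0.01)$letter),
                   c(2L, 0L, 0L, 0L))
  expect_error(infer_letter(c(0, 0, 0, 0), s6, 0.01), "no information")
  # candidates are sorted and headed by the inferred letter
  expect_identical(call$candidates$index[1], call$index)
  expect_true(all(diff(call$candidates$log_score) <= 0))
})

test_that("reliability distance is a normalized Euclidean metric", {
  expect_equal(reliability_distance(c(5, 5, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(reliability_distance(c(6, 4, 0, 0), c(1, 1, 0, 0)),
               sqrt(0.02))
  # invariant to integer scaling of the observation
  expect_equal(reliability_distance(c(18, 12, 0, 0), c(1, 1, 0, 0)),
               reliability_distance(c(6, 4, 0, 0), c(1, 1, 0, 0)))
})

test_that("pruned search matches exhaustive scoring on large alphabets", {
  # full resolution-8 alphabet (165 letters) at depth 300
  phi8 <- enumerate_full_alphabet(8)
  set.seed(31)
  for (i in 1:400) {
    truth <- sample(nrow(phi8$letters), 1)
    X <- as.integer(stats::rmultinom(
      1, 300, expected_base_distribution(phi8$letters[truth, ], 0.01)))
    a <- infer_letter(X, phi8, 0.01, method = "pruned")$index
    b <- infer_letter(X, phi8, 0.01, method = "exhaustive")$index
    expect_identical(a, b)
  }
  # 256-letter codec subset at depth 490
  s <- stack256()$alphabet
  set.seed(32)
  for (i in 1:400) {
    truth <- sample(256, 1)
    X <- as.integer(stats::rmultinom(
      1, 490, expected_base_distribution(s$letters[truth, ], 0.01)))
    expect_identical(infer_letter(X, s, 0.01, method = "pruned")$index,
                     infer_letter(X, s, 0.01, method = "exhaustive")$index)
  }
})

test_that("batch inference agrees with the single-call path", {
  s6 <- sigma6_alphabet()
  set.seed(12)
  truth <- sample(6, 300, replace = TRUE)
  counts <- simulate_sequence(s6$letters[truth, ],
                              channel_params(0.01, 12, seed = 13))
  batch <- infer_letters(counts, s6, 0.01)
  single <- vapply(seq_len(300), function(i)
    infer_letter(counts[i, ], s6, 0.01)$index, integer(1))
  expect_identical(batch$index, single)
  expect_equal(batch$distance,
               vapply(seq_len(300), function(i)
                 reliability_distance(counts[i, ],
                                      s6$letters[batch$index[i], ]),
               numeric(1)))
})

test_that("inference accuracy is monotone non-decreasing in depth", {
  s6 <- sigma6_alphabet()
  acc <- vapply(c(5, 10, 15, 20, 30), function(N) {
    set.seed(100 + N)
    truth <- sample(6, 4000, replace = TRUE)
    counts <- simulate_sequence(s6$letters[truth, ],
                                channel_params(0.01, N, seed = 200 + N))
    mean(infer_letters(counts, s6, 0.01)$index == truth)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[5], 0.99)
})
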