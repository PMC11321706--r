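test_that("observation enumeration counts all count vectors", {
  expect_identical(nrow(enumerate_observations(1)), 4L)
  expect_identical(nrow(enumerate_observations(2)), 10L)
  expect_identical(nrow(enumerate_observations(10)), 286L)
  expect_true(all(rowSums(enumerate_observations(7)) == 7L))
})

test_that("noise-free channel yields an identity library", {
  phi1 <- enumerate_full_alphabet(1)
  lib <- build_library_exact(phi1, channel_params(0, 5))
  expect_equal(unname(lib$trans), diag(4))
  expect_equal(lib$error_rate, rep(0, 4))
  # Monte-Carlo route on pure letters, p = 0: identity rows too
  libmc <- build_library_mc(phi1, channel_params(0, 5), n_draws = 1000,
                            seed = 3)
  expect_equal(unname(libmc$trans), diag(4))
})

test_that("exact library rows are stochastic and mixed letters err more", {
  lib <- phi2_library()
  expect_true(all(abs(rowSums(lib$trans) - 1) < 1e-9))
  phi2 <- lib$alphabet
  mixed <- letter_index(phi2, c(1, 1, 0, 0))
  pure <- letter_index(phi2, c(2, 0, 0, 0))
  expect_gt(lib$error_rate[mixed], lib$error_rate[pure])
  # entropy ordering: higher composition entropy, higher error rate
  H <- apply(phi2$letters / 2, 1, function(p) {
    p <- p[p > 0]; -sum(p * log(p))
  })
  for (i in 1:10) for (j in 1:10) {
    if (H[i] > H[j] + 1e-12)
      expect_gte(lib$error_rate[i], lib$error_rate[j])
  }
})

test_that("library respects the base-symmetry of the channel", {
  # the channel is exactly base-symmetric; the deterministic tie-break
  # (canonical letter order) is not, so transition rows agree under base
  # relabeling only up to the probability mass of tied boundary
  # observations (~1e-4 at depth 10)
  lib <- phi2_library()
  phi2 <- lib$alphabet
  perm <- c(3, 1, 4, 2)  # relabel A->G, C->A, G->T, T->C
  pidx <- letter_index(phi2, phi2$letters[, perm])
  for (i in 1:10) {
    expect_equal(lib$trans[pidx[i], pidx], lib$trans[i, ],
                 tolerance = 1e-3)
    expect_lt(max(abs(lib$trans[pidx[i], pidx] - lib$trans[i, ])), 1e-3)
  }
})

test_that("Monte-Carlo library converges to the exact one", {
  phi2 <- enumerate_full_alphabet(2)
  exact <- phi2_library()
  mc <- build_library_mc(phi2, channel_params(0.01, 10), n_draws = 1e5,
                         seed = 17)
  expect_lt(max(abs(mc$trans - exact$trans)), 0.01)
  # each estimated entry within 4 Monte-Carlo standard errors
  se <- sqrt(exact$trans * (1 - exact$trans) / 1e5)
  expect_true(all(abs(mc$trans - exact$trans) <= 4 * se + 1e-4))
  # more draws, tighter estimates (seeded, so this is a fixed comparison)
  mc_small <- build_library_mc(phi2, channel_params(0.01, 10),
                               n_draws = 4000, seed = 17)
  expect_lt(max(abs(mc$trans - exact$trans)),
            max(abs(mc_small$trans - exact$trans)))
  expect_error(build_library_mc(phi2, channel_params(0.01, 10), 10),
               "n_draws")
})

test_that("exact enumeration refuses infeasible configurations", {
  expect_error(build_library_exact(enumerate_full_alphabet(10),
                                   channel_params(0.01, 490)),
               "build_library_mc")
})

test_that("alternatives rank non-identity targets by probability", {
  lib <- phi2_library()
  phi2 <- lib$alphabet
  a_idx <- letter_index(phi2, c(2, 0, 0, 0))
  m_idx <- letter_index(phi2, c(1, 1, 0, 0))
  expect_identical(nrow(alternatives(lib, a_idx, 0)), 0L)
  alt_a <- alternatives(lib, a_idx, 3)
  expect_false(a_idx %in% alt_a$index)
  expect_true(all(diff(alt_a$prob) <= 0))
  # M's most likely confusions are its composition neighbors A and C
  alt_m <- alternatives(lib, c(1, 1, 0, 0), 2)
  expect_setequal(letter_labels(phi2$letters[alt_m$index, ]),
                  c("2,0,0,0", "0,2,0,0"))
  expect_identical(alternatives(lib, m_idx, 2), alt_m)
  expect_error(alternatives(lib, 99, 2), "library")
})

test_that("selected codec subset at its target depth is low-error", {
  lib <- stack64()$library
  expect_true(all(lib$error_rate < 0.05))
  expect_true(all(abs(rowSums(lib$trans) - 1) < 1e-9))
})

test_that("library JSON serialization round-trips", {
  lib <- phi2_library()
  path <- withr::local_tempfile(fileext = ".json")
  library_to_json(lib, path)
  back <- library_from_json(path)
  expect_equal(back$trans, lib$trans)
  expect_identical(back$alphabet$letters, lib$alphabet$letters)
  expect_identical(back$depth_N, lib$depth_N)
  expect_identical(back$method, lib$method)
})
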