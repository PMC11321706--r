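# Shared fixtures, memoised across test files (library builds dominate
# runtime, so each expensive object is built once per test run).

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# exact transition library on the full resolution-2 alphabet at depth 10
phi2_library <- function() {
  cached_fixture("phi2lib", {
    build_library_exact(enumerate_full_alphabet(2), channel_params(0.01, 10))
  })
}

# the six-letter in-vitro-style alphabet {A, C, G, T, M, K} at k = 2
sigma6_alphabet <- function() {
  composite_alphabet(2, rbind(c(2, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 2, 0),
                              c(0, 0, 0, 2), c(1, 1, 0, 0), c(0, 0, 1, 1)))
}

# 64-letter codec stack (k = 6, target depth 190)
stack64 <- function() {
  cached_fixture("stack64", {
    build_alphabet_stack(6, 64, 190, p_error = 0.01, n_draws = 20000,
                         seed = 7)
  })
}

# 256-letter codec stack (k = 10, target depth 490)
stack256 <- function() {
  cached_fixture("stack256", {
    build_alphabet_stack(10, 256, 490, p_error = 0.01, n_draws = 20000,
                         seed = 21)
  })
}

# toy code for exhaustive audits: RS(7,3) over GF(8)
rs73 <- function() rs_spec(8, n_code = 7, k_info = 3)

# all 512 codewords of RS(7,3)/GF(8), one per row
rs73_codebook <- function() {
  cached_fixture("rs73book", {
    sp <- rs73()
    grid <- as.matrix(expand.grid(0:7, 0:7, 0:7))
    t(apply(grid, 1L, rs_encode, spec = sp))
  })
}

# brute-force nearest-codeword oracle: index + Hamming distance
rs73_nearest <- function(received) {
  book <- rs73_codebook()
  d <- rowSums(book != matrix(received, nrow(book), 7L, byrow = TRUE))
  i <- which.min(d)
  list(codeword = book[i, ], distance = d[i],
       n_at_min = sum(d == d[i]))
}

# small depth-sweep comparison used by several tests (soft vs hard at a
# failing and a working depth)
sweep64 <- function() {
  cached_fixture("sweep64", {
    s <- stack64()
    lims <- search_limits(max_iterations = 2000L)
    run_depth_sweep(s$alphabet, rs_spec(64), depths = c(50L, 110L, 190L),
                    p_error = 0.01, n_matrices = 4L,
                    modes = c("hard", "soft"), limits = lims,
                    n_draws = 10000L, seed = 3L,
                    libraries = list(`190` = s$library))
  })
}

# seed whose 3-error block miscorrects under plain hard decoding
# (found by search, then frozen for determinism); optionally on a fixed
# truth codeword
find_miscorrecting_seed <- function(stack, spec, seeds = 1:400,
                                    truth = NULL) {
  for (sd in seeds) {
    blk <- tryCatch(
      make_error_block(3, stack$alphabet, stack$library, spec, seed = sd,
                       truth = truth),
      error = function(e) NULL)
    if (is.null(blk)) next
    hd <- rs_decode_hard(blk$evidence$inferred - 1L, spec)
    if (hd$ok && !identical(hd$codeword + 1L, blk$truth)) return(sd)
  }
  NA_integer_
}
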