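oli <- oligo_sequences()
seq_of <- function(n) oli$sequence[oli$name == n]

test_that("packaged oligo set has the expected architecture", {
  expect_setequal(oli$name, c("docking_A", "docking_B", "template_sense",
                              "template_antisense", "linker",
                              "complement_rna"))
  expect_equal(oli$length[oli$name == "linker"], 38)
  expect_equal(oli$length[oli$name == "complement_rna"], 38)
  expect_equal(oli$length[oli$name == "docking_A"], 14)
  expect_equal(oli$length[oli$name == "docking_B"], 14)
  expect_equal(oli$material[oli$name == "linker"], "RNA")
})

test_that("overlap length matches the brute-force scan oracle", {
  cases <- list(c("linker", "docking_A"), c("linker", "docking_B"),
                c("linker", "complement_rna"),
                c("docking_A", "docking_B"),
                c("template_sense", "template_antisense"))
  for (cs in cases) {
    got <- overlap_length(seq_of(cs[1]), seq_of(cs[2]))
    expect_equal(got, oracle_overlap(seq_of(cs[1]), seq_of(cs[2])),
                 info = paste(cs, collapse = " vs "))
  }
  # the linker grabs each docking strand by one 14-nt half and the
  # complement over its full 38 nt
  expect_equal(overlap_length(seq_of("linker"), seq_of("docking_A")), 14)
  expect_equal(overlap_length(seq_of("linker"), seq_of("docking_B")), 14)
  expect_equal(overlap_length(seq_of("linker"), seq_of("complement_rna")), 38)
})

test_that("overlap handles edge cases and rejects junk", {
  expect_equal(overlap_length("AAAA", "AAAA"), 0)    # A cannot pair with A
  expect_equal(overlap_length("AAAA", "TTTT"), 4)
  expect_equal(overlap_length("ACGU", "ACGT"), oracle_overlap("ACGU", "ACGT"))
  expect_error(overlap_length("ACGX", "ACGT"), "IUPAC")
  expect_error(overlap_length("", "ACGT"), "non-empty")
})

test_that("equilibrate reproduces closed-form one-duplex solutions", {
  d0 <- duplex_table("linker", "complement", 0)
  eq0 <- equilibrate(hybrid_pool(linker = 3, complement = 2), d0)
  expect_equal(eq0$free[["linker"]], 3)
  expect_equal(eq0$free[["complement"]], 2)
  expect_equal(eq0$duplexes$conc, 0)

  cases <- expand.grid(L = c(1, 2, 80), C = c(1, 50), K = c(1, 100, 1e6))
  for (i in seq_len(nrow(cases))) {
    L <- cases$L[i]; C <- cases$C[i]; K <- cases$K[i]
    eq <- equilibrate(hybrid_pool(linker = L, complement = C),
                      duplex_table("linker", "complement", K))
    o <- oracle_one_duplex(L, C, K)
    expect_equal(eq$free[["linker"]], o[["a"]], tolerance = 1e-6)
    expect_equal(eq$free[["complement"]], o[["b"]], tolerance = 1e-6)
    expect_lt(eq$residual, 1e-9)
  }
  # golden-ratio special case L = C = 1, K = 1
  eq <- equilibrate(hybrid_pool(linker = 1, complement = 1),
                    duplex_table("linker", "complement", 1))
  expect_equal(eq$free[["linker"]], (sqrt(5) - 1) / 2, tolerance = 1e-9)
})

test_that("equilibrate matches a root-finding oracle on shared two-duplex systems", {
  set.seed(21)
  for (rep in 1:10) {
    tot <- stats::runif(3, 0.1, 100)     # linker, docking_a, complement
    Ks <- 10^stats::runif(2, -2, 4)
    eq <- equilibrate(
      hybrid_pool(linker = tot[1], docking_a = tot[2], complement = tot[3]),
      duplex_table(c("linker", "linker"), c("docking_a", "complement"),
                   K = Ks))
    o <- oracle_shared_two_duplex(tot[1], tot[2], tot[3], Ks[1], Ks[2])
    expect_equal(eq$free[["linker"]], o[["l"]], tolerance = 1e-6)
    expect_equal(eq$free[["docking_a"]], o[["b"]], tolerance = 1e-6)
    expect_equal(eq$free[["complement"]], o[["c"]], tolerance = 1e-6)
  }
})

test_that("mass is conserved per species on random pools", {
  set.seed(42)
  for (rep in 1:100) {
    pool <- hybrid_pool(linker = stats::runif(1, 0, 200),
                        complement = stats::runif(1, 0, 100),
                        docking_a = stats::runif(1, 0, 50),
                        docking_b = stats::runif(1, 0, 50),
                        fragment_a = stats::runif(1, 0, 100),
                        fragment_b = stats::runif(1, 0, 100))
    eq <- equilibrate(pool)
    expect_lt(eq$residual, 1e-9)
    expect_true(all(eq$free >= 0))
    expect_true(all(eq$duplexes$conc >= 0))
  }
})

test_that("raising the linker-complement affinity never frees more linker", {
  pool <- hybrid_pool(linker = 60, complement = 40, docking_a = 10,
                      docking_b = 10)
  Ks <- 10^seq(-2, 5, by = 1)
  free_l <- vapply(Ks, function(K) {
    dd <- default_duplexes()
    dd$K[dd$species_b == "complement"] <- K
    effective_linker(equilibrate(pool, dd))
  }, numeric(1))
  expect_true(all(diff(free_l) <= 1e-9))
})

test_that("strong binding approaches the max(0, L - C) sequestration limit", {
  d <- duplex_table("linker", "complement", 1e9)
  eq <- equilibrate(hybrid_pool(linker = 80, complement = 50), d)
  expect_equal(effective_linker(eq), 30, tolerance = 1e-6 * 80)
  eq2 <- equilibrate(hybrid_pool(linker = 1, complement = 2), d)
  expect_lt(effective_linker(eq2), 1e-6)
})

test_that("threshold transform delays onset and shortens the decay phase", {
  traj <- simulate_pulse(kinetic_params(), seq(0, 300, by = 2))
  expect_identical(threshold_transform(traj, 0), traj)
  thr <- 25
  pm0 <- pulse_metrics(traj, thr)
  delays <- offsets <- numeric(0)
  for (ct in c(10, 25, 50)) {
    eff <- threshold_transform(traj, ct)
    expect_true(all(eff$rna <= traj$rna + 1e-9))
    pm <- pulse_metrics(eff, thr)
    delays <- c(delays, pm$onset_time - pm0$onset_time)
    offsets <- c(offsets, pm$offset_time - pm$peak_time)
  }
  expect_true(all(delays > 0))
  expect_true(all(diff(delays) > 0))       # more complement, later onset
  expect_true(all(offsets < pm0$offset_time - pm0$peak_time))
})

test_that("fragment blocking saturates and is monotone in fragment load", {
  pool0 <- hybrid_pool(linker = 0, docking_a = 10, docking_b = 10)
  expect_equal(blocking_factor(pool0), 1.0)
  # equal fragments and docking at K = 1: golden-ratio free fraction
  pool1 <- hybrid_pool(docking_a = 1, docking_b = 1, fragment_a = 1,
                       fragment_b = 1)
  d1 <- duplex_table(c("fragment_a", "fragment_b"),
                     c("docking_a", "docking_b"), K = c(1, 1))
  expect_equal(blocking_factor(pool1, d1), (sqrt(5) - 1) / 2,
               tolerance = 1e-9)
  # 10x strong-binding excess wipes out the bridging capacity
  pool2 <- hybrid_pool(docking_a = 10, docking_b = 10, fragment_a = 100,
                       fragment_b = 100)
  dstrong <- duplex_table(c("fragment_a", "fragment_b"),
                          c("docking_a", "docking_b"), K = c(1e6, 1e6))
  expect_lt(blocking_factor(pool2, dstrong), 1e-3)
  fr <- seq(0, 50, by = 10)
  bf <- vapply(fr, function(f)
    blocking_factor(hybrid_pool(docking_a = 20, docking_b = 20,
                                fragment_a = f, fragment_b = f)),
    numeric(1))
  expect_true(all(diff(bf) <= 1e-12))
  expect_error(blocking_factor(hybrid_pool()), "docking")
})
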