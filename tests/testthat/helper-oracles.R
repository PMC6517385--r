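# Independent oracles used by the tests; deliberately implemented with
# different algorithms than the package code they check.

# Longest perfect antiparallel complementary stretch by brute force:
# slide b (reversed) along a at every offset and count the longest run
# of complementary pairs.
oracle_overlap <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  x <- strsplit(toupper(a), "")[[1]]
  y <- rev(strsplit(toupper(b), "")[[1]])   # antiparallel
  x[x == "U"] <- "T"
  best <- 0L
  for (off in (-length(y) + 1):(length(x) - 1)) {
    run <- 0L
    for (j in seq_along(y)) {
      i <- j + off
      pair <- !is.na(comp[y[j]]) && i >= 1 && i <= length(x) &&
        x[i] == chartr("ACGTU", "TGCAA", y[j])
      run <- if (pair) run + 1L else 0L
      best <- max(best, run)
    }
  }
  best
}

# One-duplex equilibrium by the quadratic closed form:
# free A solves K x^2 + (1 + K(B - A)) x - A = 0.
oracle_one_duplex <- function(A_tot, B_tot, K) {
  if (K == 0) return(c(a = A_tot, b = B_tot, ab = 0))
  qa <- K; qb <- 1 + K * (B_tot - A_tot); qc <- -A_tot
  a <- (-qb + sqrt(qb^2 - 4 * qa * qc)) / (2 * qa)
  ab <- K * a * (B_tot - (A_tot - a))
  c(a = a, b = B_tot - (A_tot - a), ab = A_tot - a)
}

# Two duplexes sharing one species: root-find on the shared free
# concentration (monotone residual, bisection via uniroot).
oracle_shared_two_duplex <- function(L_tot, B_tot, C_tot, K1, K2) {
  res <- function(fl) {
    fb <- B_tot / (1 + K1 * fl)
    fc <- C_tot / (1 + K2 * fl)
    fl + K1 * fl * fb + K2 * fl * fc - L_tot
  }
  fl <- stats::uniroot(res, c(0, L_tot), tol = 1e-14)$root
  c(l = fl, b = B_tot / (1 + K1 * fl), c = C_tot / (1 + K2 * fl))
}

# quick pulse trajectory on a grid from arbitrary lumped rates
params_from_lumped <- function(A, lam, mu, ntp0 = 1) {
  kinetic_params(k1 = A / ntp0, k2 = mu, k3 = lam, t7 = 1, temp = 1,
                 rnaseh = 1, ntp0 = ntp0)
}
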