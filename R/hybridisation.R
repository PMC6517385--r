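# Mass-action equilibria of the competing DNA/RNA hybridisation reactions.
#
# The 38-nt RNA linker can hybridise with (i) a fully complementary RNA
# strand added as an "aggregation threshold", (ii) the two 14-nt DNA
# docking strands grafted on the colloids, and (iii) nothing else.  The
# degradation by-products (half-linker fragments) compete with full-length
# linkers for the docking strands and thereby lower the bridging capacity
# of colloids that have already been through an aggregation/disintegration
# cycle.  All reactions are bimolecular A + B <-> AB with association
# constant K (1/nM), solved under per-species mass conservation.

.species_names <- c("linker", "complement", "docking_a", "docking_b",
                    "fragment_a", "fragment_b")

#' Packaged oligonucleotide sequences
#'
#' Reads the oligo set of the experimental system (docking strands A/B,
#' sense/antisense template, the RNA linker and its full complement) from
#' the FASTA file shipped with the package.
#'
#' @return A data frame with columns `name`, `sequence`, `material`
#'   (DNA/RNA) and `length`.
#' @examples
#' oligo_sequences()
#' @export
oligo_sequences <- function() {
  path <- system.file("extdata", "oligos.fasta", package = "colloidpulse",
                      mustWork = TRUE)
  seqs <- Biostrings::readBStringSet(path)
  hdr <- strsplit(names(seqs), " ", fixed = TRUE)
  data.frame(
    name = vapply(hdr, `[`, "", 1L),
    sequence = as.character(seqs),
    material = sub("^material=", "", vapply(hdr, `[`, "", 2L)),
    length = Biostrings::width(seqs)
  )
}

# normalise an oligo string: upper case, RNA U -> T; errors on non-IUPAC
.norm_seq <- function(s) {
  s <- toupper(s)
  if (grepl("[^ACGTURYSWKMBDHVN]", s))
    stop("sequence contains non-IUPAC characters")
  chartr("U", "T", s)
}

#' Longest perfect hybridisation overlap between two strands
#'
#' Length (nt) of the longest contiguous stretch over which the two
#' strands can form a perfect antiparallel Watson-Crick duplex (RNA U
#' pairs like T).  Equivalently, the longest common substring of the first
#' sequence and the reverse complement of the second.  Only exact A-T/U
#' and C-G pairs count; ambiguity codes never match.
#'
#' @param a,b Nucleotide strings, or single rows of [oligo_sequences()].
#' @return Integer overlap length (0 when no complementary stretch exists).
#' @examples
#' oli <- oligo_sequences()
#' overlap_length(oli$sequence[oli$name == "linker"],
#'                oli$sequence[oli$name == "docking_A"])
#' @export
overlap_length <- function(a, b) {
  if (is.data.frame(a)) a <- a$sequence
  if (is.data.frame(b)) b <- b$sequence
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  x <- strsplit(.norm_seq(a), "")[[1]]
  y <- strsplit(.norm_seq(b), "")[[1]]
  # reverse complement of b (antiparallel pairing), then longest common
  # substring by dynamic programming; sequences are tens of nt long
  yrc <- rev(chartr("ACGT", "TGCA", y))
  best <- 0L
  prev <- integer(length(yrc))
  for (i in seq_along(x)) {
    cur <- integer(length(yrc))
    hit <- x[i] == yrc & x[i] %in% c("A", "C", "G", "T")
    cur[hit] <- 1L
    j <- which(hit & seq_along(yrc) > 1L)
    if (length(j)) cur[j] <- prev[j - 1L] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

#' Duplex specification table
#'
#' @param species_a,species_b Species names (see [hybrid_pool()]).
#' @param K Association constants (1/nM).
#' @param overlap Complementary region lengths (nt), informational.
#' @return A data frame of class `duplex_table`.
#' @export
duplex_table <- function(species_a, species_b, K, overlap = NA_integer_) {
  if (any(K < 0)) stop("association constants must be >= 0")
  structure(data.frame(species_a = species_a, species_b = species_b,
                       K = K, overlap = overlap),
            class = c("duplex_table", "data.frame"))
}

#' Default set of competing duplexes
#'
#' The affinity of each duplex is set from its overlap length by the
#' two-parameter rule `K(n) = K0 * exp(gamma * n)`, an exponential
#' free-energy-per-base-pair model.  The defaults (`K0 = 1e-3` 1/nM,
#' `gamma = 0.6` per nt) make the 38-nt linker/complement duplex many
#' orders of magnitude stronger than the 14-nt docking duplexes, which is
#' the regime the threshold mechanism relies on; they are configuration
#' parameters, not thermodynamic measurements.
#'
#' @param K0 Pre-factor (1/nM).
#' @param gamma Affinity gain per complementary nucleotide.
#' @return A [duplex_table()] with the linker-complement (38 nt),
#'   linker-docking (14 nt each) and fragment-docking (14 nt each) pairs.
#' @export
default_duplexes <- function(K0 = 1e-3, gamma = 0.6) {
  ov <- c(38L, 14L, 14L, 14L, 14L)
  duplex_table(
    species_a = c("linker", "linker", "linker", "fragment_a", "fragment_b"),
    species_b = c("complement", "docking_a", "docking_b",
                  "docking_a", "docking_b"),
    K = K0 * exp(gamma * ov),
    overlap = ov
  )
}

#' Pool of total nucleic-acid concentrations
#'
#' @param linker Full-length RNA linker total (nM).
#' @param complement Complementary RNA total (nM).
#' @param docking_a,docking_b Docking-strand totals (nM, effective
#'   solution concentration of the grafted strands).
#' @param fragment_a,fragment_b Degradation-fragment totals (nM), pooled
#'   per docking strand they block.
#' @return Named numeric vector of class `hybrid_pool`.
#' @export
hybrid_pool <- function(linker = 0, complement = 0, docking_a = 0,
                        docking_b = 0, fragment_a = 0, fragment_b = 0) {
  x <- c(linker = linker, complement = complement, docking_a = docking_a,
         docking_b = docking_b, fragment_a = fragment_a,
         fragment_b = fragment_b)
  if (any(!is.finite(x)) || any(x < 0))
    stop("totals must be finite and >= 0")
  structure(x, class = "hybrid_pool")
}

#' Equilibrate the competing hybridisation reactions
#'
#' Solves the coupled bimolecular equilibria `[AB] = K * [A]free * [B]free`
#' subject to mass conservation `free + sum(duplexes) = total` for every
#' species, by damped fixed-point iteration on the free concentrations
#' (`free_s = total_s / (1 + sum K * free_partner)`, geometric damping in
#' log space with adaptive step).  The mass-action equilibrium of a
#' network of bimolecular associations with positive constants is unique,
#' so any convergent scheme finds it.
#'
#' @param pool A [hybrid_pool()] (or named non-negative vector of totals).
#' @param duplexes A [duplex_table()]; defaults to [default_duplexes()].
#' @param tol Absolute convergence tolerance on free concentrations (nM).
#' @param max_iter Iteration cap; non-convergence is an error reporting
#'   the conservation residual.
#' @param init Optional named vector of starting free concentrations
#'   (warm start, e.g. from the previous point of a trajectory).
#' @return An object of class `equilibrium_partition`: list with `free`
#'   (named vector, nM), `duplexes` (the table with a `conc` column, nM),
#'   `residual` (max relative conservation violation) and `iterations`.
#' @examples
#' eq <- equilibrate(hybrid_pool(linker = 100, complement = 50))
#' effective_linker(eq)
#' @export
equilibrate <- function(pool, duplexes = default_duplexes(),
                        tol = 1e-12, max_iter = 1e5, init = NULL) {
  totals <- unclass(pool)
  if (is.null(names(totals)) || any(!is.finite(totals)) || any(totals < 0))
    stop("'pool' must be a named vector of finite non-negative totals")
  sp <- names(totals)
  bad <- setdiff(c(duplexes$species_a, duplexes$species_b), sp)
  if (length(bad))
    stop("duplex references unknown species: ", paste(bad, collapse = ", "))
  ia <- match(duplexes$species_a, sp)
  ib <- match(duplexes$species_b, sp)
  K <- duplexes$K

  active <- totals > 0
  free <- totals
  if (!is.null(init) && all(sp %in% names(init)))
    free <- pmin(pmax(init[sp], 1e-15), totals)
  free[!active] <- 0
  alpha <- 0.5
  resid_of <- function(f) {
    bound <- numeric(length(sp))
    d <- K * f[ia] * f[ib]
    for (k in seq_along(d)) {
      bound[ia[k]] <- bound[ia[k]] + d[k]
      bound[ib[k]] <- bound[ib[k]] + d[k]
    }
    max(abs(f + bound - totals) / pmax(totals, .Machine$double.eps))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- rep(1, length(sp))
    load_a <- K * free[ib]
    load_b <- K * free[ia]
    for (k in seq_along(K)) {
      denom[ia[k]] <- denom[ia[k]] + load_a[k]
      denom[ib[k]] <- denom[ib[k]] + load_b[k]
    }
    target <- totals / denom
    new_free <- free
    pos <- active & free > 0
    new_free[pos] <- free[pos] * (target[pos] / free[pos])^alpha
    new_free[active & free == 0] <- target[active & free == 0]
    delta <- max(abs(new_free - free))
    free <- new_free
    if (delta < tol) break
    if (it >= max_iter)
      stop(sprintf(
        "equilibrate did not converge in %d iterations (residual %.3g)",
        it, resid_of(free)))
  }
  dconc <- K * free[ia] * free[ib]
  duplexes$conc <- dconc
  structure(list(free = free, duplexes = duplexes,
                 residual = resid_of(free), iterations = it),
            class = "equilibrium_partition")
}

#' @export
print.equilibrium_partition <- function(x, ...) {
  cat("Hybridisation equilibrium (", x$iterations, " iterations, ",
      "conservation residual ", format(x$residual, digits = 3), ")\n",
      sep = "")
  cat("Free (nM):\n")
  print(round(x$free, 6))
  cat("Duplexes (nM):\n")
  print(data.frame(x$duplexes$species_a, x$duplexes$species_b,
                   conc = round(x$duplexes$conc, 6)))
  invisible(x)
}

#' Free full-length linker at equilibrium
#'
#' The only species able to bridge the two colloid types is the unbound
#' full-length linker; everything sequestered by the complementary RNA or
#' parked on a single docking strand is unavailable.
#'
#' @param partition An `equilibrium_partition` from [equilibrate()].
#' @return Free linker concentration (nM).
#' @export
effective_linker <- function(partition) {
  stopifnot(inherits(partition, "equilibrium_partition"))
  unname(partition$free[["linker"]])
}

#' Apply the complementary-RNA aggregation threshold to a pulse
#'
#' Maps each point of an RNA trajectory to the free linker concentration
#' at hybridisation equilibrium with `complement_tot` of fully
#' complementary RNA present (quasi-static approximation: hybridisation is
#' fast relative to the enzymatic rates).  With a strongly bound 38-nt
#' duplex this approaches `max(0, rna - complement_tot)` pointwise, which
#' is why the added complement acts as an aggregation threshold: it delays
#' the onset of aggregation and accelerates the apparent disintegration.
#'
#' @param traj An [rna_trajectory()].
#' @param complement_tot Total complementary RNA (nM).
#' @param duplexes [duplex_table()] to use; the default restricts the
#'   system to the linker-complement duplex.
#' @return An [rna_trajectory()] whose `rna` column holds the effective
#'   (free) linker concentration; always pointwise `<=` the input.
#' @export
threshold_transform <- function(traj, complement_tot,
                                duplexes = NULL) {
  if (complement_tot < 0) stop("'complement_tot' must be >= 0")
  if (is.null(duplexes)) {
    dd <- default_duplexes()
    duplexes <- dd[dd$species_a == "linker" & dd$species_b == "complement", ]
  }
  if (complement_tot == 0) return(traj)
  eff <- numeric(nrow(traj))
  warm <- NULL
  for (i in seq_len(nrow(traj))) {
    r <- traj$rna[i]
    if (r == 0) { eff[i] <- 0; next }
    eq <- equilibrate(hybrid_pool(linker = r, complement = complement_tot),
                      duplexes, init = warm)
    warm <- eq$free
    eff[i] <- effective_linker(eq)
  }
  rna_trajectory(traj$times, eff, traj$ntp)
}

#' Bridging-capacity multiplier under fragment blocking
#'
#' Degradation fragments occupy docking strands and block them from
#' binding full-length linkers.  The bridging capacity of a colloid pair
#' is limited by whichever docking species is more heavily occupied, so
#' the multiplier returned is one minus the fragment-occupied fraction of
#' the limiting (most blocked) docking species.
#'
#' @param pool A [hybrid_pool()] with positive docking totals.
#' @param duplexes A [duplex_table()]; defaults to [default_duplexes()].
#' @return Fraction in `[0, 1]`.
#' @export
blocking_factor <- function(pool, duplexes = default_duplexes()) {
  totals <- unclass(pool)
  dock <- c("docking_a", "docking_b")
  present <- dock[dock %in% names(totals) & totals[dock] > 0]
  if (!length(present)) stop("docking totals are zero")
  eq <- equilibrate(pool, duplexes)
  d <- eq$duplexes
  frag <- grepl("^fragment", d$species_a) | grepl("^fragment", d$species_b)
  occ <- vapply(present, function(s) {
    rows <- frag & (d$species_a == s | d$species_b == s)
    sum(d$conc[rows]) / totals[[s]]
  }, numeric(1))
  1 - max(occ)
}
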