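# Independent oracles and small fixtures shared across tests.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")

rand_aa <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Naive ends-free affine-gap dynamic program (score only), written from the
# recurrence; independent of the alignment library used by the package.
dp_overlap_score <- function(a, b, sm = blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0  # free leading gaps
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- sm[A[i - 1], B[j - 1]] +
      max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  max(M[n + 1, ], X[n + 1, ], Y[n + 1, ], M[, m + 1], X[, m + 1], Y[, m + 1])
}

# Runge-Kutta integration of the K -> M -> O -> ground chain; the numerical
# cross-check for the closed-form populations.
ode_concentrations <- function(model, times) {
  f <- model$excited_fraction
  deriv <- function(t, y, parms) {
    with(as.list(c(y, parms)), list(c(
      K = -k1 * K, M = k1 * K - k2 * M, O = k2 * M - k3 * O, G = k3 * O)))
  }
  out <- deSolve::ode(y = c(K = f, M = 0, O = 0, G = 0), times = c(0, times),
                      func = deriv,
                      parms = c(k1 = model$k1, k2 = model$k2, k3 = model$k3),
                      method = "ode45", atol = 1e-12, rtol = 1e-12)
  out[-1, c("K", "M", "O", "G"), drop = FALSE]
}

# Hamming p-distance for equal-length, gap-free sequences (the generator is
# substitution-only, so this is exact ground truth).
hamming_p <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  mean(av != bv)
}

# A motif_call built by hand (for rule-table tests without alignment).
make_motif_call <- function(triplet, schiff = TRUE, counterion = "D",
                            release = "EE") {
  structure(list(motif_triplet = triplet, schiff_lysine_present = schiff,
                 counterion_residue = counterion, release_pair = release,
                 query_positions = setNames(rep(NA_integer_, 7),
                   c("acceptor", "hbond_partner", "donor", "counterion",
                     "release1", "release2", "schiff_lysine")),
                 gaps = character(0)),
            class = "motif_call")
}

default_spec <- function(seed = 101L) scaffold_spec(seed = seed)
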