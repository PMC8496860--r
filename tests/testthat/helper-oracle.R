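## Independent, literal transcription of the model equations, kept
## deliberately separate in style and structure from the package
## implementation: every term is written out exactly as printed, using
## scalar arithmetic on an explicit parameter list. Used as the oracle
## for right-hand-side equivalence tests.
oracle_rhs <- function(state, p, glucex, galex) {
  G1 <- state[["G1"]]; G2 <- state[["G2"]]; G3 <- state[["G3"]]
  G3s <- state[["G3s"]]; G80 <- state[["G80"]]; G4 <- state[["G4"]]
  C83 <- state[["C83"]]; C84 <- state[["C84"]]; HXT <- state[["HXT"]]
  Rtot <- state[["Rtot"]]; gluc <- state[["gluc_in"]]; gal <- state[["gal_in"]]

  Rs <- gluc^p[["nRs"]] / (gluc^p[["nRs"]] + p[["KRs"]]^p[["nRs"]]) * Rtot

  dG1 <- p[["a1"]] +
    p[["ag1"]] * G4^p[["n1"]] / (G4^p[["n1"]] + p[["KG1"]]^p[["n1"]]) *
      p[["KR1"]]^p[["nR1"]] / (p[["KR1"]]^p[["nR1"]] + Rs^p[["nR1"]]) -
    p[["d"]] * G1
  dG2 <- p[["a2"]] +
    p[["ag2"]] * G4^p[["n2"]] / (G4^p[["n2"]] + p[["KG2"]]^p[["n2"]]) -
    p[["d"]] * G2
  dG3 <- p[["a3"]] +
    p[["ag3"]] * G4^p[["n3"]] / (G4^p[["n3"]] + p[["KG3"]]^p[["n3"]]) *
      p[["KR3"]]^p[["nR3"]] / (p[["KR3"]]^p[["nR3"]] + Rs^p[["nR3"]]) -
    p[["kf3"]] * gal * G3 + p[["kr3"]] * G3s - p[["d"]] * G3
  dG3s <- p[["kf3"]] * gal * G3 - p[["kr3"]] * G3s -
    p[["kf83"]] * G3s * G80 + p[["kr83"]] * C83 - p[["d"]] * G3s
  dG80 <- p[["a80"]] +
    p[["ag80"]] * G4^p[["n80"]] / (G4^p[["n80"]] + p[["KG80"]]^p[["n80"]]) -
    p[["kf83"]] * G3s * G80 + p[["kr83"]] * C83 -
    p[["kf84"]] * G4 * G80 + p[["kr84"]] * C84 - p[["d"]] * G80
  dG4 <- p[["a4"]] +
    p[["ag4"]] * p[["KR4"]]^p[["nR4"]] / (p[["KR4"]]^p[["nR4"]] + Rs^p[["nR4"]]) -
    p[["kf84"]] * G4 * G80 + p[["kr84"]] * C84 - p[["d"]] * G4
  dC83 <- p[["kf83"]] * G3s * G80 - p[["kr83"]] * C83 - p[["d"]] * C83
  dC84 <- p[["kf84"]] * G4 * G80 - p[["kr84"]] * C84 - p[["d"]] * C84
  dHXT <- p[["a0HXT"]] +
    p[["aHXT"]] * p[["KHXT"]]^p[["nHXT"]] /
      (p[["KHXT"]]^p[["nHXT"]] + G4^p[["nHXT"]]) -
    p[["d"]] * HXT
  dRtot <- p[["aR"]] - p[["d"]] * Rtot
  dgluc <- p[["kG2"]] * G2 * glucex /
      (1 / p[["rG2"]] * galex + glucex + p[["KGgluc"]]) +
    (p[["rcat"]] * p[["kG2"]]) * HXT * glucex /
      (1 / p[["rHXT"]] * galex + glucex + p[["KHXTgluc"]]) -
    p[["dsugar"]] * gluc
  dgal <- p[["kG2"]] * G2 * galex /
      (p[["rG2"]] * glucex + galex + p[["rG2"]] * p[["KGgluc"]]) -
    p[["kf3"]] * gal * G3 + p[["kr3"]] * G3s +
    (p[["rcat"]] * p[["kG2"]]) * HXT * galex /
      (p[["rHXT"]] * glucex + galex + p[["rHXT"]] * p[["KHXTgluc"]]) -
    p[["dsugar"]] * gal

  c(G1 = dG1, G2 = dG2, G3 = dG3, G3s = dG3s, G80 = dG80, G4 = dG4,
    C83 = dC83, C84 = dC84, HXT = dHXT, Rtot = dRtot,
    gluc_in = dgluc, gal_in = dgal)
}

## lean fixed-step classic Runge-Kutta integrator over the oracle RHS;
## the derivative function is written flat for speed
oracle_rk4 <- function(state, p, glucex, galex, h = 0.05, t_end = 4000,
                       check_every = 2000, rel_tol = 1e-8) {
  pl <- as.list(as.numeric(p))
  names(pl) <- names(p)
  y <- as.numeric(state)
  nm <- names(state)
  f <- function(y) {
    s <- as.list(y)
    names(s) <- nm
    unname(oracle_rhs(s, pl, glucex, galex))
  }
  prev <- y
  steps <- ceiling(t_end / h)
  for (i in seq_len(steps)) {
    k1 <- f(y)
    k2 <- f(pmax(y + h / 2 * k1, 0))
    k3 <- f(pmax(y + h / 2 * k2, 0))
    k4 <- f(pmax(y + h * k3, 0))
    y <- pmax(y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    if (i %% check_every == 0) {
      if (max(abs(y - prev) / pmax(abs(y), 1e-9)) < rel_tol) break
      prev <- y
    }
  }
  names(y) <- nm
  y
}

## draw a random positive state / parameter pair for equivalence tests
random_state_params <- function() {
  st <- stats::runif(12, 0, 10)
  names(st) <- c("G1", "G2", "G3", "G3s", "G80", "G4", "C83", "C84",
                 "HXT", "Rtot", "gluc_in", "gal_in")
  base <- reference_parameters()
  vals <- as.numeric(base) * 10^stats::runif(45, -0.5, 0.5)
  names(vals) <- names(base)
  ## Hill coefficients stay at modest integer-ish values for conditioning
  vals[c("n1", "n2", "n3", "n80", "nHXT", "nR1", "nR3", "nR4", "nRs")] <-
    sample(1:4, 9, replace = TRUE)
  list(state = st, params = gal_params(vals),
       glucose = stats::runif(1, 0, 1), galactose = stats::runif(1, 0, 4))
}

## small grids keep calibration-scale tests at desk scale
tiny_grid <- function() {
  sugar_grid(glucose_levels = c(0.0625, 0),
             galactose_levels = c(0.5, 0.03125, 0))
}

small_grid <- function() {
  sugar_grid(glucose_levels = c(0.25, 0.0625, 0.015625, 0),
             galactose_levels = c(2, 0.5, 0.125, 0.03125, 0.0078125, 0))
}

## mean silhouette width for a 2-group labelling of 2-d points
silhouette_mean <- function(xy, labels) {
  d <- as.matrix(stats::dist(xy))
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- mean(d[i, !own])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

## synthetic boundaries object for delta-metric arithmetic tests
fake_boundaries <- function(gal_on, gal_full, always_off = FALSE,
                            ladder = 4 / 2^(10:0)) {
  structure(list(gal_on = gal_on, gal_full = gal_full,
                 always_off = always_off,
                 always_bimodal = is.na(gal_full) && !always_off,
                 ladder = ladder),
            class = "bimodal_boundaries")
}
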