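# Builds the packaged synthetic force-field parameter files:
#   inst/extdata/forcefield_his21_synthetic.yaml  (two His states, 21 types)
#   inst/extdata/forcefield_mpipi_synthetic.yaml  (averaged His, 20 types)
#   inst/extdata/qm_reference_synthetic.csv       (calibration series)
#
# The tables are a synthetic stand-in for a published pair-strength table
# that is not redistributable here. Construction:
#   * per-residue diameters: standard residue van-der-Waals diameters;
#   * base contact strength eps_ij = EPS_SCALE * (lambda_i + lambda_j)/2
#     from a normalized hydropathy scale;
#   * pi-pi enhancements among aromatics and cation-pi enhancements for
#     Arg/Lys (and protonated His) with aromatics;
#   * His0-His0 and His0-Arg strengths from a least-squares linear
#     rescaling of a synthetic reference binding-energy series onto the
#     pi-pi and cation-pi strengths of the non-His pairs (the packaged
#     qm_reference_synthetic.csv);
#   * EPS_SCALE fixed once so that a generic 50-residue disordered chain
#     reproduces the empirical Flory size 2.54 * N^0.52 (see
#     data-raw/calibrate_scale.R).
#
# Energies are in reduced units (thermal energy at 300 K = 0.45).

suppressMessages(library(yaml))

EPS_SCALE <- 0.20   # set by data-raw/calibrate_scale.R, then frozen

lambda <- c(
  A = 0.45, R = 0.56, N = 0.38, D = 0.29, C = 0.60, Q = 0.39, E = 0.21,
  G = 0.44, I = 0.68, L = 0.72, K = 0.19, M = 0.62, F = 0.95, P = 0.55,
  S = 0.38, T = 0.40, W = 1.00, Y = 0.92, V = 0.59,
  "H0" = 0.55, "H+" = 0.40, H = 0.53
)
diameter <- c(
  A = 5.04, R = 6.56, N = 5.68, D = 5.58, C = 5.48, Q = 6.02, E = 5.92,
  G = 4.50, I = 6.18, L = 6.18, K = 6.36, M = 6.18, F = 6.36, P = 5.56,
  S = 5.18, T = 5.62, W = 6.78, Y = 6.46, V = 5.86,
  "H0" = 6.08, "H+" = 6.08, H = 6.08
)
res_name <- c(
  A = "alanine", R = "arginine", N = "asparagine", D = "aspartate",
  C = "cysteine", Q = "glutamine", E = "glutamate", G = "glycine",
  I = "isoleucine", L = "leucine", K = "lysine", M = "methionine",
  F = "phenylalanine", P = "proline", S = "serine", T = "threonine",
  W = "tryptophan", Y = "tyrosine", V = "valine",
  "H0" = "histidine (neutral)", "H+" = "histidine (protonated)",
  H = "histidine (averaged)"
)
charge <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
            I = 0, L = 0, K = 0 + 1, M = 0, F = 0, P = 0, S = 0, T = 0,
            W = 0, Y = 0, V = 0, "H0" = 0, "H+" = 1, H = 0.375)

# aromatic weights for the pi enhancements
arom_w <- c(F = 1.00, Y = 0.92, W = 1.12)
PIPI0 <- 0.30    # pi-pi enhancement prefactor (reduced units)
CATR0 <- 0.32    # Arg cation-pi prefactor
CATK0 <- 0.12    # Lys cation-pi prefactor (weaker, field consensus)
CATHP0 <- 0.36   # His+ cation-pi prefactor (exceeds Arg's)
W_H0 <- 0.92     # His0 pi weight for contacts with Phe/Tyr/Trp

base_eps <- function(a, b) EPS_SCALE * (lambda[[a]] + lambda[[b]]) / 2

pair_eps <- function(codes) {
  n <- length(codes)
  eps <- matrix(0, n, n, dimnames = list(codes, codes))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- codes[i]; b <- codes[j]
    e <- base_eps(a, b)
    if (a %in% names(arom_w) && b %in% names(arom_w)) {
      e <- e + PIPI0 * arom_w[[a]] * arom_w[[b]]
    }
    cat_pair <- function(cation, pref) {
      (a == cation && b %in% names(arom_w)) ||
        (b == cation && a %in% names(arom_w))
    }
    arom_of <- function(p, q) if (p %in% names(arom_w)) arom_w[[p]] else arom_w[[q]]
    if (cat_pair("R")) e <- e + CATR0 * arom_of(a, b)
    if (cat_pair("K")) e <- e + CATK0 * arom_of(a, b)
    if (cat_pair("H+")) e <- e + CATHP0 * arom_of(a, b)
    # His0 behaves as a pi system toward the standard aromatics (and is a
    # weak cation-pi acceptor for Lys); His0-His0 / His0-Arg are overwritten
    # by the calibration below.
    if ((a == "H0" && b %in% names(arom_w)) || (b == "H0" && a %in% names(arom_w))) {
      e <- e + PIPI0 * W_H0 * arom_of(a, b)
    }
    if ((a == "H0" && b == "K") || (a == "K" && b == "H0")) {
      e <- e + CATK0 * W_H0
    }
    # averaged His (Mpipi-style) keeps pi contacts with aromatics but has
    # no His-His or His-Arg enhancement (those are the averaged-out terms)
    if ((a == "H" && b %in% names(arom_w)) || (b == "H" && a %in% names(arom_w))) {
      e <- e + PIPI0 * W_H0 * arom_of(a, b)
    }
    eps[i, j] <- e
  }
  eps
}

codes21 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "I", "L", "K", "M",
             "F", "P", "S", "T", "W", "Y", "V", "H0", "H+")
codes20 <- c(setdiff(codes21, c("H0", "H+")), "H")

eps21 <- pair_eps(codes21)
eps20 <- pair_eps(codes20)

## ---- synthetic reference binding-energy series -------------------------
# Mean binding energies (kcal/mol, negative = attractive) for the pi-pi and
# cation-pi reference series, constructed to be near-affine in the model's
# existing pair strengths, with the two His0 query pairs placed at energies
# comparable to Phe-Phe (pi-pi) and Arg-Phe (cation-pi) respectively.
pipi_pairs <- list(c("F", "F"), c("F", "Y"), c("F", "W"),
                   c("Y", "Y"), c("Y", "W"), c("W", "W"))
cat_pairs <- list(c("R", "F"), c("R", "Y"), c("R", "W"))

jit_pipi <- c(0.05, -0.04, 0.03, -0.05, 0.02, -0.01)
jit_cat <- c(0.03, -0.04, 0.02)

eps_of <- function(p) eps21[p[1], p[2]]
qm_pipi <- -(1.0 + 3.5 * vapply(pipi_pairs, eps_of, 1)) + jit_pipi
qm_cat <- -(0.8 + 3.0 * vapply(cat_pairs, eps_of, 1)) + jit_cat
qm_h0h0 <- qm_pipi[1] - 0.05   # comparable to Phe-Phe
qm_h0r <- qm_cat[1] - 0.03     # comparable to Arg-Phe

qm_table <- rbind(
  data.frame(series = "pipi",
             pair = vapply(pipi_pairs, paste, "", collapse = "-"),
             qm_energy = qm_pipi,
             target_epsilon = vapply(pipi_pairs, eps_of, 1)),
  data.frame(series = "cation_pi",
             pair = vapply(cat_pairs, paste, "", collapse = "-"),
             qm_energy = qm_cat,
             target_epsilon = vapply(cat_pairs, eps_of, 1)),
  data.frame(series = c("pipi_query", "cation_pi_query"),
             pair = c("H0-H0", "H0-R"),
             qm_energy = c(qm_h0h0, qm_h0r),
             target_epsilon = NA)
)

fit_pipi <- lm(target_epsilon ~ qm_energy,
               data = subset(qm_table, series == "pipi"))
fit_cat <- lm(target_epsilon ~ qm_energy,
              data = subset(qm_table, series == "cation_pi"))
eps_h0h0 <- unname(predict(fit_pipi, data.frame(qm_energy = qm_h0h0)))
eps_h0r <- unname(predict(fit_cat, data.frame(qm_energy = qm_h0r)))
cat(sprintf("calibrated: H0-H0 = %.4f (R2 %.3f), H0-R = %.4f (R2 %.3f)\n",
            eps_h0h0, summary(fit_pipi)$r.squared,
            eps_h0r, summary(fit_cat)$r.squared))

eps21["H0", "H0"] <- eps_h0h0
eps21["H0", "R"] <- eps21["R", "H0"] <- eps_h0r

## ---- write files -------------------------------------------------------
write_ff <- function(codes, eps, name, path) {
  entries <- list()
  for (i in seq_along(codes)) for (j in i:length(codes)) {
    entries[[length(entries) + 1]] <-
      list(codes[i], codes[j], round(unname(eps[i, j]), 6))
  }
  out <- list(
    name = name,
    provenance = "synthetic",
    residues = lapply(codes, function(cc) list(
      code = cc, name = res_name[[cc]], charge = charge[[cc]],
      diameter = diameter[[cc]])),
    epsilon = entries,
    sigma_overrides = list(),
    electrostatics = list(coulomb_constant = 332, dielectric = 80,
                          salt_coefficient = 1, reference_temperature = 300,
                          ionic_strength = 0.15),
    bonded = list(k_bond = 20, d0 = 3.8, k_angle = 2.0, theta0 = 2.12,
                  k_dihedral = 1.0, phi0 = -1.3),
    cutoffs = list(contact_factor = 3, electrostatic = 35)
  )
  yaml::write_yaml(out, path, precision = 17)
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_ff(codes21, eps21, "his21-synthetic", "inst/extdata/forcefield_his21_synthetic.yaml")
write_ff(codes20, eps20, "mpipi-synthetic", "inst/extdata/forcefield_mpipi_synthetic.yaml")
write.csv(qm_table, "inst/extdata/qm_reference_synthetic.csv", row.names = FALSE)
cat("wrote parameter files\n")
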