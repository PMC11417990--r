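#' Build a bead-chain topology from a typed sequence
#'
#' One spherical bead per residue, centred on the C-alpha position. An
#' N-residue chain carries N-1 harmonic bonds and N-2 harmonic angles;
#' dihedral terms are added only for consecutive four-bead windows that
#' contain a proline. Nonbonded terms (contacts and electrostatics) apply
#' to residue pairs with sequence separation `|i - j| > 3`.
#'
#' Bonded-term constants come from the force field's `bonded` block:
#' `k_bond` (energy/A^2, potential `k (d - d0)^2`), `d0` (A, 3.8 by
#' default for the virtual C-alpha bond), `k_angle` (energy/rad^2,
#' `k (theta - theta0)^2`), `theta0` (rad), and the proline dihedral
#' constants `k_dihedral`, `phi0` (potential `K (1 - cos(phi - phi0))`).
#'
#' @param typed An `idp_sequence` from [assign_protonation()].
#' @param forcefield A `cg_forcefield` whose residue set covers the
#'   sequence.
#' @return A `cg_topology`: codes, 1-based type indices into the force
#'   field's residue table, per-bead charges, bond/angle/dihedral term
#'   tables, bead mass (1, reduced) and the nonbonded exclusion rule.
#' @examples
#' ff <- default_forcefield("high_pH")
#' top <- build_chain(assign_protonation(hst5_sequence(), "high_pH"), ff)
#' nrow(top$bonds)   # 23
#' @export
build_chain <- function(typed, forcefield) {
  stopifnot(inherits(typed, "idp_sequence"), inherits(forcefield, "cg_forcefield"))
  codes <- typed$code
  n <- length(codes)
  if (n < 2) rlang::abort("chain needs at least 2 residues")
  type_idx <- match(codes, forcefield$residues$code)
  if (anyNA(type_idx)) {
    bad <- which(is.na(type_idx))[1]
    rlang::abort(paste0("residue '", codes[bad], "' at position ", bad,
                        " is not in force field '", forcefield$name, "'"))
  }
  b <- forcefield$bonded
  bonds <- tibble::tibble(i = seq_len(n - 1), j = 2:n,
                          k_bond = b$k_bond, d0 = b$d0)
  angles <- if (n >= 3) {
    tibble::tibble(i = seq_len(n - 2), j = 2:(n - 1), k = 3:n,
                   k_angle = b$k_angle, theta0 = b$theta0)
  } else {
    tibble::tibble(i = integer(0), j = integer(0), k = integer(0),
                   k_angle = numeric(0), theta0 = numeric(0))
  }
  quads <- if (n >= 4) seq_len(n - 3) else integer(0)
  has_pro <- vapply(quads, function(s) any(codes[s:(s + 3)] == "P"), logical(1))
  quads <- quads[has_pro]
  dihedrals <- tibble::tibble(i = quads, j = quads + 1, k = quads + 2,
                              l = quads + 3,
                              k_dihedral = rep(b$k_dihedral, length(quads)),
                              phi0 = rep(b$phi0, length(quads)))
  structure(list(
    codes = codes,
    n = n,
    type_idx = type_idx,
    charges = forcefield$residues$charge[type_idx],
    bonds = bonds,
    angles = angles,
    dihedrals = dihedrals,
    mass = 1,
    min_seq_sep = 3,
    forcefield_name = forcefield$name
  ), class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("<cg_topology> ", x$n, " beads (", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", nrow(x$dihedrals), " dihedrals)\n", sep = "")
  cat("  net charge: ", sum(x$charges), " e; nonbonded pairs: |i-j| > ",
      x$min_seq_sep, "\n", sep = "")
  invisible(x)
}

#' Initial chain conformation
#'
#' `"extended"` places beads on a straight line at the equilibrium bond
#' length; `"random_walk"` grows a random self-avoiding-ish walk with all
#' bond lengths equal to `d0`, resampling any step that comes closer than
#' 0.8 d0 to an existing bead. Deterministic for a fixed seed.
#'
#' @param topology A `cg_topology`.
#' @param seed Integer RNG seed.
#' @param method `"random_walk"` or `"extended"`.
#' @return An N x 3 coordinate matrix (Angstrom).
#' @export
initial_conformation <- function(topology, seed = 1,
                                 method = c("random_walk", "extended")) {
  method <- match.arg(method)
  n <- topology$n
  d0 <- topology$bonds$d0[1]
  if (method == "extended") {
    return(cbind(x = (seq_len(n) - 1) * d0, y = rep(0, n), z = rep(0, n)))
  }
  withr_seed(seed, {
    xyz <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    for (i in 2:n) {
      for (attempt in 1:200) {
        u <- stats::rnorm(3)
        step <- d0 * u / sqrt(sum(u^2))
        cand <- xyz[i - 1, ] + step
        prev <- xyz[seq_len(i - 2), , drop = FALSE]
        if (i == 2 || nrow(prev) == 0 ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) > 0.8 * d0) {
          xyz[i, ] <- cand
          break
        }
        if (attempt == 200) xyz[i, ] <- cand
      }
    }
    xyz
  })
}
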