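#' Lennard-Jones 10-12 pair potential
#'
#' Short-range contact potential `U(r) = eps * (5 (sigma/r)^12 - 6
#' (sigma/r)^10)`. The minimum, of depth `-eps`, sits exactly at
#' `sigma` (the optimal pair distance), and `U` decays to zero at large `r`.
#'
#' @param r Pair distance (Angstrom), positive. Vectorized.
#' @param epsilon Contact strength (reduced energy units), `>= 0`.
#' @param sigma Optimal pair distance (Angstrom), `> 0`.
#' @return Pair energy in reduced units.
#' @examples
#' lj1012(6, 0.5, 6)    # -0.5 at the minimum
#' @export
lj1012 <- function(r, epsilon, sigma) {
  if (any(r <= 0)) rlang::abort("lj1012 is singular at r <= 0")
  stopifnot(all(epsilon >= 0), all(sigma > 0))
  s2 <- (sigma / r)^2
  epsilon * (5 * s2^6 - 6 * s2^5)
}

#' Debye-Hueckel screened electrostatic pair potential
#'
#' `U(r) = B(kappa) * K_coulomb * q1 * q2 * exp(-kappa r) / (eps_r * r)`,
#' evaluated in kcal/mol and converted to reduced energy units with the
#' settings' conversion factor. The sign follows `q1 * q2` and the
#' magnitude decreases monotonically with both `r` and `kappa`.
#'
#' @param q1,q2 Charges in elementary-charge units.
#' @param r Pair distance (Angstrom), positive. Vectorized.
#' @param settings Electrostatics settings list (as in
#'   `forcefield$electrostatics`): `coulomb_constant`, `dielectric`,
#'   `salt_coefficient`, `kappa`, `kcal_to_energy`.
#' @param convert If `FALSE`, return kcal/mol instead of reduced units.
#' @return Pair energy.
#' @export
debye_huckel <- function(q1, q2, r, settings, convert = TRUE) {
  if (any(r <= 0)) rlang::abort("debye_huckel is singular at r <= 0")
  u <- settings$salt_coefficient * settings$coulomb_constant * q1 * q2 *
    exp(-settings$kappa * r) / (settings$dielectric * r)
  if (convert) u * settings$kcal_to_energy else u
}

elec_prefactor <- function(settings) {
  settings$salt_coefficient * settings$coulomb_constant /
    settings$dielectric * settings$kcal_to_energy
}

cpp_args <- function(coords, topology, forcefield, cutoffs = TRUE) {
  el <- forcefield$electrostatics
  cc <- forcefield$cutoffs
  list(
    coords = coords,
    type0 = topology$type_idx - 1L,
    charges = topology$charges,
    eps = unname(forcefield$epsilon),
    sig = unname(forcefield$sigma),
    bonds = {
      m <- as.matrix(topology$bonds)
      if (nrow(m)) m[, 1:2] <- m[, 1:2] - 1
      m
    },
    angles = {
      m <- as.matrix(topology$angles)
      if (nrow(m)) m[, 1:3] <- m[, 1:3] - 1
      m
    },
    dihedrals = {
      m <- as.matrix(topology$dihedrals)
      if (nrow(m)) m[, 1:4] <- m[, 1:4] - 1
      m
    },
    min_seq_sep = topology$min_seq_sep,
    contact_cutoff_factor = if (cutoffs) cc$contact_factor else -1,
    elec_cutoff = if (cutoffs) cc$electrostatic else -1,
    kappa = el$kappa,
    elec_pref = elec_prefactor(el)
  )
}

#' Potential energy breakdown of a conformation
#'
#' Evaluates every term of the chain potential: harmonic bonds and angles,
#' proline dihedrals, LJ 10-12 contacts over pairs with `|i - j| > 3`, and
#' Debye-Hueckel electrostatics over the same pair set. `total` is the sum
#' of the five components.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param topology A `cg_topology`.
#' @param forcefield A `cg_forcefield`.
#' @param cutoffs Apply the force field's contact (3 sigma_ij) and
#'   electrostatic cutoffs; set `FALSE` for exact no-cutoff evaluation.
#' @return A one-row tibble: `bonded`, `angular`, `dihedral`, `contacts`,
#'   `electrostatic`, `total` (reduced energy units).
#' @export
chain_energy <- function(coords, topology, forcefield, cutoffs = TRUE) {
  check_frame(coords, topology)
  a <- cpp_args(coords, topology, forcefield, cutoffs)
  en <- cpp_energy(a$coords, a$type0, a$charges, a$eps, a$sig, a$bonds,
                   a$angles, a$dihedrals, a$min_seq_sep,
                   a$contact_cutoff_factor, a$elec_cutoff, a$kappa, a$elec_pref)
  tibble::tibble(bonded = en[["bonded"]], angular = en[["angular"]],
                 dihedral = en[["dihedral"]], contacts = en[["contacts"]],
                 electrostatic = en[["electrostatic"]], total = sum(en))
}

#' Analytic forces on every bead
#'
#' Negative gradient of [chain_energy()]; matches central finite
#' differences of the total energy and sums to zero over the chain.
#'
#' @inheritParams chain_energy
#' @return N x 3 force matrix (reduced energy / Angstrom).
#' @export
chain_forces <- function(coords, topology, forcefield, cutoffs = TRUE) {
  check_frame(coords, topology)
  a <- cpp_args(coords, topology, forcefield, cutoffs)
  cpp_forces(a$coords, a$type0, a$charges, a$eps, a$sig, a$bonds,
             a$angles, a$dihedrals, a$min_seq_sep,
             a$contact_cutoff_factor, a$elec_cutoff, a$kappa, a$elec_pref)
}

check_frame <- function(coords, topology) {
  if (!is.matrix(coords) || ncol(coords) != 3 || nrow(coords) != topology$n) {
    rlang::abort(paste0("coordinate frame must be a ", topology$n,
                        " x 3 matrix matching the topology"))
  }
  if (!all(is.finite(coords))) rlang::abort("non-finite coordinates")
  invisible(coords)
}

#' Reference (brute-force) energy evaluation
#'
#' Plain-R double-loop re-implementation of every energy term with no
#' cutoffs and no vectorization tricks, kept deliberately independent of
#' the compiled path. Intended as a cross-check oracle; use
#' [chain_energy()] for real work.
#'
#' @inheritParams chain_energy
#' @return A one-row tibble like [chain_energy()]'s.
#' @export
reference_energy <- function(coords, topology, forcefield) {
  check_frame(coords, topology)
  n <- topology$n
  dist3 <- function(a, b) sqrt(sum((coords[a, ] - coords[b, ])^2))

  e_bond <- 0
  for (b in seq_len(nrow(topology$bonds))) {
    r <- dist3(topology$bonds$i[b], topology$bonds$j[b])
    e_bond <- e_bond + topology$bonds$k_bond[b] * (r - topology$bonds$d0[b])^2
  }
  e_ang <- 0
  for (a in seq_len(nrow(topology$angles))) {
    v1 <- coords[topology$angles$i[a], ] - coords[topology$angles$j[a], ]
    v2 <- coords[topology$angles$k[a], ] - coords[topology$angles$j[a], ]
    cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    th <- acos(max(-1, min(1, cs)))
    e_ang <- e_ang + topology$angles$k_angle[a] * (th - topology$angles$theta0[a])^2
  }
  e_dih <- 0
  for (d in seq_len(nrow(topology$dihedrals))) {
    dd <- topology$dihedrals[d, ]
    b1 <- coords[dd$j, ] - coords[dd$i, ]
    b2 <- coords[dd$k, ] - coords[dd$j, ]
    b3 <- coords[dd$l, ] - coords[dd$k, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
            n1[1] * n2[2] - n1[2] * n2[1])
    phi <- atan2(sum(m1 * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
    e_dih <- e_dih + dd$k_dihedral * (1 - cos(phi - dd$phi0))
  }
  e_lj <- 0
  e_el <- 0
  el <- forcefield$electrostatics
  for (i in seq_len(n - 1)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      if (j - i <= topology$min_seq_sep) next
      r <- dist3(i, j)
      ci <- topology$codes[i]
      cj <- topology$codes[j]
      e_lj <- e_lj + lj1012(r, forcefield$epsilon[ci, cj],
                            forcefield$sigma[ci, cj])
      qi <- topology$charges[i]
      qj <- topology$charges[j]
      if (qi != 0 && qj != 0) {
        e_el <- e_el + debye_huckel(qi, qj, r, el)
      }
    }
  }
  tibble::tibble(bonded = e_bond, angular = e_ang, dihedral = e_dih,
                 contacts = e_lj, electrostatic = e_el,
                 total = e_bond + e_ang + e_dih + e_lj + e_el)
}
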