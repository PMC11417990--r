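#' The extended residue alphabet
#'
#' Twenty standard amino acids plus two histidine protonation states. In the
#' two-state ("his21") parameter set the plain code `H` is not a valid bead
#' type: histidine must be resolved to neutral `H0` or protonated `H+` (see
#' [assign_protonation()]). The averaged-His ("mpipi") set instead uses a
#' single `H` type carrying a +0.375 e charge.
#'
#' @param set `"his21"` (two His states, 21 types) or `"mpipi"`
#'   (averaged His, 20 types).
#' @return A tibble with columns `code`, `name`, `charge` (elementary
#'   charges).
#' @export
residue_alphabet <- function(set = c("his21", "mpipi")) {
  set <- match.arg(set)
  std <- tibble::tibble(
    code = c("A", "R", "N", "D", "C", "Q", "E", "G", "I", "L",
             "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    name = c("alanine", "arginine", "asparagine", "aspartate", "cysteine",
             "glutamine", "glutamate", "glycine", "isoleucine", "leucine",
             "lysine", "methionine", "phenylalanine", "proline", "serine",
             "threonine", "tryptophan", "tyrosine", "valine"),
    charge = c(0, 1, 0, -1, 0, 0, -1, 0, 0, 0,
               1, 0, 0, 0, 0, 0, 0, 0, 0)
  )
  his <- if (set == "his21") {
    tibble::tibble(code = c("H0", "H+"),
                   name = c("histidine (neutral)", "histidine (protonated)"),
                   charge = c(0, 1))
  } else {
    tibble::tibble(code = "H", name = "histidine (averaged)", charge = 0.375)
  }
  dplyr::bind_rows(std, his)
}

#' Read a force-field parameter file
#'
#' Parameter files are YAML with a residue block (code, name, charge,
#' diameter in Angstrom), a long-format `epsilon` block of pair contact
#' strengths (reduced energy units), optional per-pair `sigma_overrides`
#' (Angstrom), electrostatics settings, bonded-term constants and cutoffs.
#' Pair distances `sigma_ij` default to the arithmetic mean of the two
#' residue diameters.
#'
#' @param path Path to a YAML parameter file.
#' @return A `cg_forcefield` object: residue table, symmetric `epsilon` and
#'   `sigma` matrices, electrostatics settings, bonded constants, cutoffs,
#'   and a manifest (file path, md5 checksum, provenance).
#' @export
read_forcefield <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("parameter file not found: ", path))
  raw <- yaml::read_yaml(path)
  res <- dplyr::bind_rows(lapply(raw$residues, tibble::as_tibble))
  codes <- res$code
  n <- length(codes)
  if (any(duplicated(codes))) {
    rlang::abort(paste0("duplicated residue code: ",
                        paste(unique(codes[duplicated(codes)]), collapse = ", ")))
  }
  bad <- res$code[res$diameter <= 0]
  if (length(bad)) {
    rlang::abort(paste0("non-positive diameter for residue: ",
                        paste(bad, collapse = ", ")))
  }

  eps <- matrix(NA_real_, n, n, dimnames = list(codes, codes))
  for (entry in raw$epsilon) {
    a <- as.character(entry[[1]]); b <- as.character(entry[[2]])
    v <- as.numeric(entry[[3]])
    if (!(a %in% codes) || !(b %in% codes)) {
      rlang::abort(paste0("epsilon entry references unknown residue pair: ", a, "-", b))
    }
    prev <- eps[a, b]
    if (!is.na(prev) && prev != v) {
      rlang::abort(paste0("asymmetric epsilon entries for pair ", a, "-", b,
                          " (", prev, " vs ", v, ")"))
    }
    eps[a, b] <- v
    eps[b, a] <- v
  }
  if (anyNA(eps)) {
    idx <- which(is.na(eps), arr.ind = TRUE)[1, ]
    rlang::abort(paste0("missing epsilon entry for pair ",
                        codes[idx[1]], "-", codes[idx[2]]))
  }

  sig <- outer(res$diameter, res$diameter, function(a, b) (a + b) / 2)
  dimnames(sig) <- list(codes, codes)
  for (entry in raw$sigma_overrides) {
    a <- as.character(entry[[1]]); b <- as.character(entry[[2]])
    v <- as.numeric(entry[[3]])
    if (!(a %in% codes) || !(b %in% codes)) {
      rlang::abort(paste0("sigma override references unknown pair: ", a, "-", b))
    }
    if (v <= 0) rlang::abort(paste0("non-positive sigma for pair ", a, "-", b))
    sig[a, b] <- v
    sig[b, a] <- v
  }

  el <- raw$electrostatics
  electro <- list(
    coulomb_constant = el$coulomb_constant %||% 332,
    dielectric = el$dielectric %||% 80,
    salt_coefficient = el$salt_coefficient %||% 1,
    reference_temperature = el$reference_temperature %||% 300,
    ionic_strength = el$ionic_strength %||% 0.15
  )
  electro$kappa <- debye_kappa(electro$ionic_strength, electro$dielectric,
                               electro$reference_temperature)
  electro$kcal_to_energy <- kcal_to_reduced(electro$reference_temperature)

  ff <- structure(list(
    name = raw$name %||% "unnamed",
    provenance = raw$provenance %||% "unknown",
    residues = res,
    epsilon = eps,
    sigma = sig,
    electrostatics = electro,
    bonded = raw$bonded,
    cutoffs = raw$cutoffs %||% list(contact_factor = 3, electrostatic = 35),
    manifest = list(file = normalizePath(path),
                    checksum = unname(tools::md5sum(path)))
  ), class = "cg_forcefield")
  validate_forcefield(ff)
  ff
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat("<cg_forcefield> ", x$name, " (", x$provenance, ")\n", sep = "")
  cat("  residue types: ", nrow(x$residues), "\n", sep = "")
  cat("  ionic strength: ", x$electrostatics$ionic_strength, " M (kappa = ",
      signif(x$electrostatics$kappa, 4), " 1/A)\n", sep = "")
  invisible(x)
}

validate_forcefield <- function(ff) {
  res <- ff$residues
  stopifnot(is.matrix(ff$epsilon), is.matrix(ff$sigma))
  if (!isTRUE(all.equal(ff$epsilon, t(ff$epsilon)))) {
    rlang::abort("epsilon table is not symmetric")
  }
  if (!isTRUE(all.equal(ff$sigma, t(ff$sigma)))) {
    rlang::abort("sigma table is not symmetric")
  }
  if (any(ff$sigma <= 0)) rlang::abort("sigma table has non-positive entries")
  if (any(res$diameter <= 0)) rlang::abort("non-positive residue diameter")
  his <- intersect(c("H0", "H+", "H"), res$code)
  for (h in his) {
    if (anyNA(ff$epsilon[h, ])) {
      rlang::abort(paste0("incomplete epsilon row for ", h))
    }
  }
  invisible(ff)
}

#' Write a force-field parameter file
#'
#' Inverse of [read_forcefield()]: numeric content round-trips exactly (the
#' YAML writer uses full double precision).
#'
#' @param ff A `cg_forcefield` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  codes <- ff$residues$code
  ut <- which(upper.tri(ff$epsilon, diag = TRUE), arr.ind = TRUE)
  eps_entries <- lapply(seq_len(nrow(ut)), function(k) {
    i <- ut[k, 1]; j <- ut[k, 2]
    list(codes[i], codes[j], ff$epsilon[i, j])
  })
  default_sig <- outer(ff$residues$diameter, ff$residues$diameter,
                       function(a, b) (a + b) / 2)
  ov <- which(upper.tri(ff$sigma, diag = TRUE) & ff$sigma != default_sig,
              arr.ind = TRUE)
  sig_entries <- lapply(seq_len(nrow(ov)), function(k) {
    i <- ov[k, 1]; j <- ov[k, 2]
    list(codes[i], codes[j], ff$sigma[i, j])
  })
  out <- list(
    name = ff$name,
    provenance = ff$provenance,
    residues = lapply(seq_len(nrow(ff$residues)), function(i) {
      as.list(ff$residues[i, c("code", "name", "charge", "diameter")])
    }),
    epsilon = eps_entries,
    sigma_overrides = sig_entries,
    electrostatics = ff$electrostatics[c("coulomb_constant", "dielectric",
                                         "salt_coefficient",
                                         "reference_temperature",
                                         "ionic_strength")],
    bonded = ff$bonded,
    cutoffs = ff$cutoffs
  )
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Load a packaged parameter set for a given pH mode
#'
#' Modes map onto parameter sets and His handling as follows:
#' * `high_pH` — two-state set, plain `H` resolved to neutral `H0`;
#' * `low_pH` — two-state set, plain `H` resolved to protonated `H+`;
#' * `mpipi` — averaged-His set (single `H` type, charge +0.375 e);
#' * `control_high` / `control_low` — as `high_pH` / `low_pH` but with the
#'   His0-His0 and His0-Arg contact strengths set to zero, isolating the
#'   electrostatic contribution of the His charge state.
#'
#' The packaged tables are a synthetic parameter set (see the package
#' vignette): constructed from a hydropathy scale plus pi-pi and cation-pi
#' enhancements, with His contact strengths produced by
#' [calibrate_pair_strength()] from a packaged synthetic reference series.
#'
#' @param mode One of `"high_pH"`, `"low_pH"`, `"mpipi"`, `"control_high"`,
#'   `"control_low"`.
#' @param salt_mM Monovalent salt concentration in mM (sets the Debye
#'   screening length).
#' @return A `cg_forcefield`.
#' @export
default_forcefield <- function(mode = c("high_pH", "low_pH", "mpipi",
                                        "control_high", "control_low"),
                               salt_mM = 150) {
  mode <- match.arg(mode)
  file <- if (mode == "mpipi") "forcefield_mpipi_synthetic.yaml" else
    "forcefield_his21_synthetic.yaml"
  path <- system.file("extdata", file, package = "idpsim", mustWork = TRUE)
  ff <- read_forcefield(path)
  if (mode %in% c("control_high", "control_low")) {
    ff <- zero_his0_terms(ff)
  }
  set_ionic_strength(ff, salt_mM / 1000)
}

#' Disable the His0-specific contact terms (control model)
#'
#' Returns a copy of the force field with the His0-His0 and His0-Arg contact
#' strengths set to zero, leaving every other entry untouched. This is the
#' ablation used to separate the electrostatic effect of the His charge
#' state from the short-range pi-pi / cation-pi terms.
#'
#' @param ff A two-state `cg_forcefield` (must contain an `H0` type).
#' @return A modified `cg_forcefield` with `-control` appended to its name.
#' @export
zero_his0_terms <- function(ff) {
  if (!"H0" %in% ff$residues$code) {
    rlang::abort("force field has no H0 type; control ablation applies to the two-state set")
  }
  ff$epsilon["H0", "H0"] <- 0
  ff$epsilon["H0", "R"] <- 0
  ff$epsilon["R", "H0"] <- 0
  ff$name <- paste0(ff$name, "-control")
  ff
}

#' Set the ionic strength of a force field
#'
#' Recomputes the Debye screening parameter `kappa` for the new salt
#' concentration.
#'
#' @param ff A `cg_forcefield`.
#' @param molar Ionic strength in mol/L.
#' @return The modified `cg_forcefield`.
#' @export
set_ionic_strength <- function(ff, molar) {
  stopifnot(molar >= 0)
  ff$electrostatics$ionic_strength <- molar
  ff$electrostatics$kappa <- debye_kappa(molar, ff$electrostatics$dielectric,
                                         ff$electrostatics$reference_temperature)
  ff
}

`%||%` <- function(a, b) if (is.null(a)) b else a
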