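#' Langevin dynamics of a coarse-grained chain
#'
#' Integrates the chain with a velocity-Verlet Langevin (BAOAB) scheme in
#' reduced units: bead mass 1, thermal energy `temperature` (0.45 by
#' default, corresponding approximately to room temperature in this
#' model's energy units), time step `dt` (nominally mapped to 50 fs per
#' step). Initial velocities are drawn from the Maxwell-Boltzmann
#' distribution at the set temperature. A fixed seed reproduces the
#' trajectory bit for bit.
#'
#' @param topology A `cg_topology`.
#' @param forcefield A `cg_forcefield`.
#' @param n_steps Number of MD steps.
#' @param dt Reduced time step.
#' @param temperature Thermal energy in reduced units (`k_B T`).
#' @param friction Langevin friction, reduced inverse time. Low values
#'   speed conformational sampling; equilibrium averages do not depend on
#'   it. `friction = 0` disables the thermostat (plain velocity Verlet).
#' @param output_every Save a frame every this many steps.
#' @param seed Integer seed (initial conformation, velocities, noise).
#' @param init Initial coordinates: `"random_walk"`, `"extended"`, or an
#'   N x 3 matrix (e.g. a previous run's final `coords`, for
#'   checkpoint-style continuation).
#' @param init_velocities Optional N x 3 velocity matrix (e.g. a previous
#'   run's final `velocities`); drawn from Maxwell-Boltzmann when `NULL`.
#' @param replicate Replicate id stored in the trajectory metadata.
#' @return A `cg_trajectory`: `frames` (N x 3 x n_frames array, Angstrom),
#'   `steps`, per-frame `kinetic` energy, final `coords`/`velocities`, and
#'   a `settings` record echoing every parameter.
#' @examples
#' ff <- default_forcefield("high_pH", salt_mM = 120)
#' top <- build_chain(assign_protonation(hst5_sequence(), "high_pH"), ff)
#' tr <- simulate_chain(top, ff, n_steps = 2000, output_every = 200, seed = 7)
#' dim(tr$frames)
#' @export
simulate_chain <- function(topology, forcefield, n_steps = 2e8, dt = 0.01,
                           temperature = 0.45, friction = 0.05,
                           output_every = 1000, seed = 1,
                           init = "extended", init_velocities = NULL,
                           replicate = 1L) {
  stopifnot(inherits(topology, "cg_topology"), inherits(forcefield, "cg_forcefield"))
  if (dt <= 0) rlang::abort("dt must be positive")
  if (n_steps < output_every) rlang::abort("n_steps must be >= output_every")
  coords <- if (is.matrix(init)) {
    check_frame(init, topology)
  } else {
    initial_conformation(topology, seed = seed, method = init)
  }
  vel <- if (!is.null(init_velocities)) {
    stopifnot(is.matrix(init_velocities),
              all(dim(init_velocities) == c(topology$n, 3)))
    init_velocities
  } else {
    v <- withr_seed(seed + 500000L, {
      matrix(stats::rnorm(3 * topology$n,
                          sd = sqrt(max(temperature, 0) / topology$mass)),
             topology$n, 3)
    })
    if (temperature <= 0) v[] <- 0
    v
  }
  a <- cpp_args(coords, topology, forcefield, cutoffs = TRUE)
  res <- cpp_run_langevin(a$coords, vel, a$type0, a$charges, a$eps, a$sig,
                          a$bonds, a$angles, a$dihedrals, a$min_seq_sep,
                          a$contact_cutoff_factor, a$elec_cutoff, a$kappa,
                          a$elec_pref, n_steps, dt, friction, temperature,
                          seed, output_every)
  structure(list(
    frames = res$frames,
    steps = res$steps,
    kinetic = res$kinetic,
    coords = res$coords,
    velocities = res$velocities,
    codes = topology$codes,
    settings = list(n_steps = n_steps, dt = dt, temperature = temperature,
                    friction = friction, output_every = output_every,
                    seed = seed, replicate = replicate,
                    forcefield = forcefield$name,
                    ionic_strength = forcefield$electrostatics$ionic_strength)
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  s <- x$settings
  cat("<cg_trajectory> ", length(x$codes), " beads, ", dim(x$frames)[3],
      " frames (", format(s$n_steps, big.mark = ","), " steps, dt = ", s$dt,
      ", T = ", s$temperature, ", seed = ", s$seed, ")\n", sep = "")
  invisible(x)
}

#' Independent simulation replicates
#'
#' Runs `n_replicates` simulations that differ only in their random seed
#' (`base_seed + r` for replicate `r`), hence in initial conformation,
#' initial velocities and thermal noise.
#'
#' @inheritParams simulate_chain
#' @param n_replicates Number of replicates (5 by default; 10 is typical
#'   for long chains).
#' @param base_seed Base integer seed.
#' @param ... Passed on to [simulate_chain()].
#' @return A `cg_ensemble`: a list of `cg_trajectory` objects.
#' @export
run_replicates <- function(topology, forcefield, n_replicates = 5,
                           base_seed = 1, ...) {
  stopifnot(n_replicates >= 1)
  out <- lapply(seq_len(n_replicates), function(r) {
    simulate_chain(topology, forcefield, seed = base_seed + r,
                   replicate = r, ...)
  })
  structure(out, class = "cg_ensemble")
}

#' @export
print.cg_ensemble <- function(x, ...) {
  cat("<cg_ensemble> ", length(x), " replicates of ", length(x[[1]]$codes),
      " beads\n", sep = "")
  invisible(x)
}

as_ensemble <- function(x) {
  if (inherits(x, "cg_ensemble")) return(x)
  if (inherits(x, "cg_trajectory")) return(structure(list(x), class = "cg_ensemble"))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "cg_trajectory"))) {
    return(structure(x, class = "cg_ensemble"))
  }
  rlang::abort("expected a cg_trajectory or a list of them")
}
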