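#' Radius of gyration of a conformation
#'
#' Root-mean-square distance of the beads from their centroid, with equal
#' bead masses.
#'
#' @param frame N x 3 coordinate matrix (Angstrom).
#' @return Rg in Angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(10, 0, 0)))  # 5
#' @export
radius_of_gyration <- function(frame) {
  stopifnot(is.matrix(frame), ncol(frame) == 3, nrow(frame) >= 1)
  centred <- sweep(frame, 2, colMeans(frame))
  sqrt(mean(rowSums(centred^2)))
}

keep_frames <- function(traj, equilibration_steps) {
  which(traj$steps > equilibration_steps)
}

#' Per-frame Rg series of a trajectory or ensemble
#'
#' @param x A `cg_trajectory`, `cg_ensemble`, or list of trajectories.
#' @param equilibration_steps Frames at step indices `<=` this are
#'   discarded as equilibration.
#' @return Tibble with columns `replicate`, `step`, `rg` (Angstrom).
#' @export
rg_series <- function(x, equilibration_steps = 0) {
  ens <- as_ensemble(x)
  purrr::map_dfr(ens, function(tr) {
    kf <- keep_frames(tr, equilibration_steps)
    if (!length(kf)) return(tibble::tibble(replicate = integer(0),
                                           step = numeric(0), rg = numeric(0)))
    rg <- vapply(kf, function(f) radius_of_gyration(tr$frames[, , f]),
                 numeric(1))
    tibble::tibble(replicate = tr$settings$replicate, step = tr$steps[kf],
                   rg = rg)
  })
}

#' Ensemble Rg summary
#'
#' The mean Rg is the arithmetic average over all post-equilibration frames
#' pooled across replicates; the error is the standard deviation of the
#' per-replicate mean Rg values. `replicate_means = TRUE` instead averages
#' the per-replicate means (identical when replicates have equal frame
#' counts).
#'
#' @inheritParams rg_series
#' @param replicate_means Average replicate means instead of pooling
#'   frames.
#' @return One-row tibble: `mean_rg`, `rg_sd` (across replicates, `NA` for
#'   a single replicate), `n_replicates`, `n_frames`, `flory_rg` for the
#'   chain length. The per-replicate means are attached as the
#'   `"per_replicate"` attribute.
#' @export
summarize_rg <- function(x, equilibration_steps = 0, replicate_means = FALSE) {
  ens <- as_ensemble(x)
  series <- rg_series(ens, equilibration_steps)
  if (!nrow(series)) {
    rlang::abort("no frames left after removing the equilibration window")
  }
  per_rep <- dplyr::summarise(dplyr::group_by(series, .data$replicate),
                              mean_rg = mean(.data$rg),
                              n_frames = dplyr::n(), .groups = "drop")
  mean_rg <- if (replicate_means) mean(per_rep$mean_rg) else mean(series$rg)
  out <- tibble::tibble(
    mean_rg = mean_rg,
    rg_sd = if (nrow(per_rep) > 1) stats::sd(per_rep$mean_rg) else NA_real_,
    n_replicates = nrow(per_rep),
    n_frames = nrow(series),
    flory_rg = flory_rg(length(ens[[1]]$codes))
  )
  attr(out, "per_replicate") <- per_rep
  out
}

#' Relative Rg change between low- and high-pH ensembles
#'
#' `delta_rg = 100 * (rg_low_pH - rg_high_pH) / rg_high_pH` (percent);
#' positive values mean expansion upon acidification.
#'
#' @param rg_low_pH,rg_high_pH Mean Rg values (Angstrom).
#' @return Percent change.
#' @examples
#' delta_rg(15, 10)  # +50
#' @export
delta_rg <- function(rg_low_pH, rg_high_pH) {
  if (any(rg_high_pH == 0)) rlang::abort("high-pH Rg must be non-zero")
  100 * (rg_low_pH - rg_high_pH) / rg_high_pH
}

#' Flory scaling reference Rg
#'
#' Empirical size expected for a typical N-residue disordered protein,
#' `2.54 * N^0.52` Angstrom.
#'
#' @param n_residues Chain length.
#' @return Reference Rg in Angstrom.
#' @examples
#' flory_rg(24)   # ~13.3
#' @export
flory_rg <- function(n_residues) {
  stopifnot(n_residues >= 1)
  2.54 * n_residues^0.52
}

#' Flory-normalized Rg distribution
#'
#' Histogram of `Rg / flory_rg(N)`; a peak below 1 indicates chains more
#' compact than the typical disordered protein of that length.
#'
#' @param rg Vector of per-frame Rg values (Angstrom).
#' @param n_residues Chain length used for the reference.
#' @param breaks Passed to [graphics::hist()]; Freedman-Diaconis by
#'   default.
#' @return Tibble with `ratio_mid`, `count`, `density`.
#' @export
normalized_rg_distribution <- function(rg, n_residues, breaks = "FD") {
  ratio <- rg / flory_rg(n_residues)
  h <- graphics::hist(ratio, breaks = breaks, plot = FALSE)
  tibble::tibble(ratio_mid = h$mids, count = h$counts, density = h$density)
}

#' Residue class annotation
#'
#' Classifies residues the way contact analyses group them: aromatic
#' (Phe, Tyr, Trp, His0), cationic (Lys, Arg, His+), anionic (Asp, Glu),
#' everything else `other`; histidine is additionally tracked separately
#' via `is_his` (any of `H`, `H0`, `H+`).
#'
#' @param codes Character vector of residue codes.
#' @return Tibble with `position`, `code`, `class`, `is_his`.
#' @export
residue_classes <- function(codes) {
  cls <- dplyr::case_when(
    codes %in% c("F", "Y", "W", "H0") ~ "aromatic",
    codes %in% c("K", "R", "H+") ~ "cationic",
    codes %in% c("D", "E") ~ "anionic",
    TRUE ~ "other"
  )
  tibble::tibble(position = seq_along(codes), code = codes, class = cls,
                 is_his = codes %in% c("H", "H0", "H+"))
}

#' Ensemble contact map
#'
#' Probability that residues i and j are within `cutoff` of each other,
#' computed over post-equilibration frames pooled across replicates. Only
#' pairs with `|i - j| > min_seq_sep` are considered; the near-diagonal
#' band is masked (`NA`). The map is symmetric with entries in \[0, 1\].
#'
#' @inheritParams rg_series
#' @param cutoff Contact distance threshold (Angstrom, default 10).
#' @param min_seq_sep Mask pairs with sequence separation `<=` this.
#' @return A `contact_map`: probability matrix `p` plus metadata. Use
#'   [tidy()] for a long tibble and [autoplot()] to draw it.
#' @export
contact_map <- function(x, cutoff = 10, equilibration_steps = 0,
                        min_seq_sep = 3) {
  ens <- as_ensemble(x)
  n <- length(ens[[1]]$codes)
  counts <- matrix(0, n, n)
  n_frames <- 0
  for (tr in ens) {
    if (length(tr$codes) != n) rlang::abort("replicates have inconsistent chain lengths")
    kf <- keep_frames(tr, equilibration_steps)
    if (!length(kf)) next
    sub <- tr$frames[, , kf, drop = FALSE]
    counts <- counts + cpp_contact_counts(sub, n, cutoff, min_seq_sep)
    n_frames <- n_frames + length(kf)
  }
  if (n_frames == 0) rlang::abort("no frames left after equilibration removal")
  p <- counts / n_frames
  mask <- abs(row(p) - col(p)) <= min_seq_sep
  p[mask] <- NA_real_
  structure(list(p = p, cutoff = cutoff, min_seq_sep = min_seq_sep,
                 codes = ens[[1]]$codes, n_frames = n_frames),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", length(x$codes), " residues, cutoff ", x$cutoff,
      " A, ", x$n_frames, " frames, mask |i-j| <= ", x$min_seq_sep, "\n",
      sep = "")
  invisible(x)
}

#' @rdname contact_map
#' @param ... Unused.
#' @export
tidy.contact_map <- function(x, ...) {
  p <- x$p
  idx <- which(upper.tri(p) & !is.na(p), arr.ind = TRUE)
  cls <- residue_classes(x$codes)
  tibble::tibble(
    i = idx[, 1], j = idx[, 2],
    code_i = x$codes[idx[, 1]], code_j = x$codes[idx[, 2]],
    class_i = cls$class[idx[, 1]], class_j = cls$class[idx[, 2]],
    p = p[idx]
  )
}

#' Difference between two contact maps
#'
#' Elementwise `map_a - map_b` on unmasked entries; antisymmetric under
#' argument swap.
#'
#' @param map_a,map_b `contact_map`s of identical dimension and mask.
#' @return A `contact_map` whose `p` holds signed probability differences.
#' @export
contact_map_difference <- function(map_a, map_b) {
  check_compatible_maps(map_a, map_b)
  out <- map_a
  out$p <- map_a$p - map_b$p
  out$difference <- TRUE
  out
}

#' Paired contact probabilities from two maps
#'
#' Returns the paired (P_ij^a, P_ij^b) values of the unmasked upper
#' triangle, optionally restricted to residue classes (both partners must
#' belong to one of the requested classes; `"his"` selects any histidine).
#'
#' @inheritParams contact_map_difference
#' @param classes Optional character vector drawn from `"aromatic"`,
#'   `"cationic"`, `"anionic"`, `"his"`.
#' @return Tibble `i`, `j`, `code_i`, `code_j`, `p_a`, `p_b`.
#' @export
contact_correlation <- function(map_a, map_b, classes = NULL) {
  check_compatible_maps(map_a, map_b)
  idx <- which(upper.tri(map_a$p) & !is.na(map_a$p), arr.ind = TRUE)
  out <- tibble::tibble(
    i = idx[, 1], j = idx[, 2],
    code_i = map_a$codes[idx[, 1]], code_j = map_a$codes[idx[, 2]],
    p_a = map_a$p[idx], p_b = map_b$p[idx]
  )
  if (!is.null(classes)) {
    cls <- residue_classes(map_a$codes)
    in_cls <- function(pos) {
      cls$class[pos] %in% setdiff(classes, "his") |
        ("his" %in% classes & cls$is_his[pos])
    }
    out <- out[in_cls(out$i) & in_cls(out$j), ]
  }
  out
}

check_compatible_maps <- function(a, b) {
  stopifnot(inherits(a, "contact_map"), inherits(b, "contact_map"))
  if (!identical(dim(a$p), dim(b$p))) rlang::abort("contact maps differ in dimension")
  if (a$min_seq_sep != b$min_seq_sep) rlang::abort("contact maps differ in masking")
  invisible(TRUE)
}

resolve_selector <- function(sel, codes) {
  cls <- residue_classes(codes)
  hit <- rep(FALSE, length(codes))
  for (s in sel) {
    hit <- hit | switch(s,
      his = cls$is_his,
      aromatic = cls$class == "aromatic",
      cationic = cls$class == "cationic",
      anionic = cls$class == "anionic",
      codes == s)
  }
  which(hit)
}

#' Class-resolved mean short-range pair energies
#'
#' For each labeled residue-pair class, sums the LJ 10-12 contact energy
#' over all nonbonded pairs in the class per frame, then reports the mean
#' and standard deviation across post-equilibration frames. Classes with
#' no matching pair in the sequence are absent from the output (not zero).
#'
#' @inheritParams rg_series
#' @param topology The chain's `cg_topology`.
#' @param forcefield The `cg_forcefield` used for the run.
#' @param pairs Named list; each element is a length-2 list/vector of
#'   selectors, where a selector is a residue code or one of `"his"`,
#'   `"aromatic"`, `"cationic"`, `"anionic"`. Defaults to the His-His,
#'   His-Arg and His-Phe/Tyr classes.
#' @return Tibble `pair_class`, `mean_energy`, `sd_energy`, `n_pairs`,
#'   `n_frames`.
#' @export
mean_pair_energy <- function(x, topology, forcefield,
                             pairs = list(
                               "His-His" = list("his", "his"),
                               "His-Arg" = list("his", "R"),
                               "His-Phe/Tyr" = list("his", c("F", "Y"))),
                             equilibration_steps = 0) {
  ens <- as_ensemble(x)
  codes <- topology$codes
  n <- topology$n
  empty <- tibble::tibble(pair_class = character(0), mean_energy = numeric(0),
                          sd_energy = numeric(0), n_pairs = integer(0),
                          n_frames = integer(0))
  out <- purrr::map_dfr(names(pairs), function(label) {
    sel_a <- resolve_selector(pairs[[label]][[1]], codes)
    sel_b <- resolve_selector(pairs[[label]][[2]], codes)
    grid <- expand.grid(i = sel_a, j = sel_b)
    grid <- grid[abs(grid$i - grid$j) > topology$min_seq_sep, ]
    key <- paste(pmin(grid$i, grid$j), pmax(grid$i, grid$j))
    grid <- grid[!duplicated(key), ]
    if (!nrow(grid)) return(NULL)
    eps <- forcefield$epsilon[cbind(codes[grid$i], codes[grid$j])]
    sig <- forcefield$sigma[cbind(codes[grid$i], codes[grid$j])]
    series <- unlist(lapply(ens, function(tr) {
      kf <- keep_frames(tr, equilibration_steps)
      if (!length(kf)) return(numeric(0))
      sub <- tr$frames[, , kf, drop = FALSE]
      cpp_pair_energy_series(sub, n, as.integer(grid$i), as.integer(grid$j),
                             eps, sig)
    }))
    tibble::tibble(pair_class = label, mean_energy = mean(series),
                   sd_energy = stats::sd(series), n_pairs = nrow(grid),
                   n_frames = length(series))
  })
  if (!nrow(out)) empty else out
}
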