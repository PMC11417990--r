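#' Write a trajectory to an XYZ file
#'
#' Plain multi-frame XYZ (element column = residue code) readable by
#' common viewers. A JSON sidecar with the run settings is written next to
#' it when `sidecar = TRUE`.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output `.xyz` path.
#' @param sidecar Also write `<path>.json` with the run metadata.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "cg_trajectory"))
  n <- length(traj$codes)
  nf <- dim(traj$frames)[3]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(as.character(n), paste0("step ", traj$steps[f])), con)
    xyz <- traj$frames[, , f]
    writeLines(sprintf("%s %.4f %.4f %.4f", traj$codes,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  if (sidecar) {
    jsonlite::write_json(traj$settings, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file written by [write_xyz()]
#'
#' @param path `.xyz` file path.
#' @return A list with `codes` and `frames` (N x 3 x n_frames).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  stride <- n + 2
  nf <- length(lines) %/% stride
  frames <- array(NA_real_, c(n, 3, nf))
  codes <- character(n)
  for (f in seq_len(nf)) {
    block <- lines[((f - 1) * stride + 3):((f - 1) * stride + 2 + n)]
    parts <- strsplit(block, "[[:space:]]+")
    codes <- vapply(parts, `[[`, character(1), 1)
    frames[, , f] <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  }
  list(codes = codes, frames = frames)
}
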