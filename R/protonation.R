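#' Tokenize a one-letter protein sequence
#'
#' Accepts the 20 standard one-letter codes plus the explicit histidine
#' tokens `h0` (neutral) and `h+` (protonated), which survive any pH mode.
#' Whitespace is ignored.
#'
#' @param sequence A single character string.
#' @return Character vector of tokens (`"A"`..., `"H"`, `"H0"`, `"H+"`).
#' @keywords internal
tokenize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(gsub("[[:space:]]", "", sequence), "")[[1]]
  tokens <- character(0)
  i <- 1
  pos <- 0
  valid <- c(residue_alphabet("his21")$code, "H")
  while (i <= length(chars)) {
    pos <- pos + 1
    if (identical(chars[i], "h")) {
      nxt <- if (i < length(chars)) chars[i + 1] else ""
      if (!nxt %in% c("0", "+")) {
        rlang::abort(paste0("unknown residue token at position ", pos,
                            ": 'h' must be followed by '0' or '+'"))
      }
      tokens <- c(tokens, if (nxt == "0") "H0" else "H+")
      i <- i + 2
    } else {
      if (!chars[i] %in% valid) {
        rlang::abort(paste0("unknown residue code '", chars[i],
                            "' at position ", pos))
      }
      tokens <- c(tokens, chars[i])
      i <- i + 1
    }
  }
  tokens
}

#' Resolve histidine protonation for a sequence
#'
#' Maps every plain `H` in the input according to the pH mode: `high_pH`
#' and `control_high` type it as neutral `H0`; `low_pH` and `control_low`
#' as protonated `H+` (+1 e); `mpipi` keeps the single averaged `H` type
#' (+0.375 e). Explicit `h0` / `h+` tokens in the input (or entries in
#' `overrides`) are immune to the mode, which permits mixed-protonation
#' chains. Non-His residues are never altered.
#'
#' @param sequence One-letter sequence string (may contain `h0` / `h+`).
#' @param mode One of `"high_pH"`, `"low_pH"`, `"mpipi"`, `"control_high"`,
#'   `"control_low"`.
#' @param overrides Optional data frame with columns `position` and `code`
#'   (`"H0"` or `"H+"`), applied after mode resolution; positions must hold
#'   a histidine.
#' @return An `idp_sequence`: a tibble with columns `position`, `input`,
#'   `code`, `charge`, carrying the mode as an attribute.
#' @examples
#' assign_protonation("HAH", "high_pH")
#' net_charge(assign_protonation(hst5_sequence(), "low_pH"))  # +12
#' @export
assign_protonation <- function(sequence,
                               mode = c("high_pH", "low_pH", "mpipi",
                                        "control_high", "control_low"),
                               overrides = NULL) {
  mode <- match.arg(mode)
  tokens <- tokenize_sequence(sequence)
  his_target <- switch(mode,
    high_pH = "H0", control_high = "H0",
    low_pH = "H+", control_low = "H+",
    mpipi = "H")
  codes <- ifelse(tokens == "H", his_target, tokens)
  if (mode == "mpipi" && any(codes %in% c("H0", "H+"))) {
    rlang::abort("explicit h0/h+ tokens conflict with the averaged-His (mpipi) mode")
  }
  if (!is.null(overrides)) {
    stopifnot(all(c("position", "code") %in% names(overrides)))
    for (k in seq_len(nrow(overrides))) {
      p <- overrides$position[k]
      if (p < 1 || p > length(codes) || !codes[p] %in% c("H0", "H+", "H")) {
        rlang::abort(paste0("override position ", p, " does not hold a histidine"))
      }
      codes[p] <- overrides$code[k]
    }
  }
  set <- if (mode == "mpipi") "mpipi" else "his21"
  alpha <- residue_alphabet(set)
  charge <- alpha$charge[match(codes, alpha$code)]
  out <- tibble::tibble(position = seq_along(codes), input = tokens,
                        code = codes, charge = charge)
  structure(out, class = c("idp_sequence", class(out)), mode = mode)
}

#' Net charge of a typed sequence
#'
#' @param typed An `idp_sequence` from [assign_protonation()].
#' @return Net charge in elementary-charge units.
#' @export
net_charge <- function(typed) {
  stopifnot(inherits(typed, "idp_sequence"))
  sum(typed$charge)
}

#' Neutral-histidine fraction from the Henderson-Hasselbalch relation
#'
#' Fraction of histidines in the neutral (deprotonated) state at a given
#' pH, `1 / (1 + 10^(pKa - pH))`. With the free-residue pKa of 6.3, about
#' 93% of His residues are neutral at physiological pH 7.4.
#'
#' @param pH Solution pH.
#' @param pKa Histidine side-chain pKa (default 6.3, isolated residue).
#' @return Fraction in \[0, 1\]; vectorized over `pH`.
#' @examples
#' his_neutral_fraction(7.4)  # ~0.926
#' @export
his_neutral_fraction <- function(pH, pKa = 6.3) {
  stopifnot(is.finite(pH), is.finite(pKa))
  1 / (1 + 10^(pKa - pH))
}

#' Read sequences from a FASTA file
#'
#' Reads single- or multi-record FASTA via Biostrings. Sequences are
#' returned as plain strings so that the explicit `h0` / `h+` histidine
#' tokens (which are outside the standard amino-acid alphabet) pass through
#' to the package's own tokenizer.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  nm <- names(sequences) %||% paste0("seq", seq_along(sequences))
  x <- Biostrings::BStringSet(stats::setNames(unname(sequences), nm))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
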