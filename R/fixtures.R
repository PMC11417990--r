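#' Histatin 5 benchmark sequences
#'
#' Histatin 5 (Hst5) is a 24-residue His-rich salivary peptide (7 His, 4
#' Lys, 3 Arg, 1 Asp, 1 Glu) widely used to benchmark pH-dependent IDP
#' models. `hst5_tandem()` returns its tandem duplication, a single
#' 48-residue chain of two head-to-tail Hst5 copies whose dimensions are
#' strongly pH sensitive.
#'
#' @return A one-letter sequence string.
#' @examples
#' hst5_sequence()
#' nchar(hst5_tandem())  # 48
#' @export
hst5_sequence <- function() "DSHAKRHHGYKRKFHEKHHSHRGY"

#' @rdname hst5_sequence
#' @export
hst5_tandem <- function() paste0(hst5_sequence(), hst5_sequence())

#' Histatin 5 His-content variants
#'
#' Generates Hst5-like 24-mers in which some of the 7 wild-type histidines
#' are replaced by glutamine (Q, neutral and of similar size), keeping the
#' backbone otherwise identical. The experimentally studied variant series
#' varies His content this way; the exact published placements are not
#' reproduced here, so placement is exposed as a parameter instead.
#'
#' @param n_his Number of histidines to retain (0-7).
#' @param placement Which His positions to substitute: `"cterm"` keeps the
#'   N-terminal-most `n_his` histidines (substituting from the C-terminal
#'   end), `"nterm"` the C-terminal-most, `"spread"` keeps an evenly spread
#'   subset, `"random"` a seeded random subset.
#' @param seed RNG seed used when `placement = "random"`.
#' @return A 24-residue sequence string. Net charge at high pH is +5 e
#'   regardless of `n_his` (Q is neutral).
#' @examples
#' hst5_variant(7)                 # wild type
#' hst5_variant(0)                 # all His -> Q
#' @export
hst5_variant <- function(n_his, placement = c("cterm", "nterm", "spread", "random"),
                         seed = 1) {
  placement <- match.arg(placement)
  if (n_his < 0 || n_his > 7) rlang::abort("n_his must be between 0 and 7")
  chars <- strsplit(hst5_sequence(), "")[[1]]
  his_pos <- which(chars == "H")
  n_sub <- 7 - n_his
  keep <- switch(placement,
    cterm = head(his_pos, n_his),
    nterm = tail(his_pos, n_his),
    spread = if (n_his == 0) integer(0) else
      his_pos[unique(round(seq(1, 7, length.out = n_his)))],
    random = {
      r <- withr_seed(seed, sample(his_pos, n_his))
      sort(r)
    })
  chars[setdiff(his_pos, keep)] <- "Q"
  paste(chars, collapse = "")
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' List packaged fixture sequences
#'
#' @return Tibble with columns `name`, `sequence`, `length`, `n_his`.
#' @export
fixture_sequences <- function() {
  seqs <- c(hst5_wt = hst5_sequence(), hst5_x2 = hst5_tandem())
  tibble::tibble(
    name = names(seqs),
    sequence = unname(seqs),
    length = nchar(unname(seqs)),
    n_his = vapply(strsplit(unname(seqs), ""), function(x) sum(x == "H"), integer(1))
  )
}
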