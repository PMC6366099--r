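#' Parse a ceramide species label
#'
#' Labels follow `CER[X(a)Y(b)]` where `X` is the fatty-acid class —
#' `N` (non-hydroxy) or `A` (alpha-hydroxy) — with `a` carbons, and `Y`
#' is the sphingoid base — `S` (sphingosine) or `DS` (dihydrosphingosine)
#' — with `b` carbons. The structural class code is the concatenation of
#' fatty-acid class and base: NS, NDS, AS or ADS.
#'
#' @param label species label, e.g. `"CER[N(18)DS(24)]"`.
#' @param lenient if `TRUE`, non-ceramide labels (eicosanoids,
#'   endocannabinoids) are passed through untyped (`NA` fields) instead of
#'   raising an error.
#' @return list with fields `raw_label`, `base`, `fa_class`, `fa_carbons`,
#'   `base_carbons`, `class_code`.
#' @export
parseCeramideName <- function(label, lenient = FALSE) {
  stopifnot(is.character(label), length(label) == 1)
  rx <- "^CER\\[(N|A)\\(([0-9]+)\\)(DS|S)\\(([0-9]+)\\)\\]$"
  m <- regmatches(label, regexec(rx, label))[[1]]
  if (length(m) == 0) {
    if (lenient)
      return(list(raw_label = label, base = NA_character_,
                  fa_class = NA_character_, fa_carbons = NA_integer_,
                  base_carbons = NA_integer_, class_code = NA_character_))
    stop("not a ceramide label: '", label,
         "' (expected CER[<N|A>(<carbons>)<S|DS>(<carbons>)])")
  }
  faCarbons <- as.integer(m[3])
  baseCarbons <- as.integer(m[5])
  if (faCarbons < 1 || baseCarbons < 1)
    stop("carbon counts must be positive in '", label, "'")
  list(raw_label = label, base = m[4], fa_class = m[2],
       fa_carbons = faCarbons, base_carbons = baseCarbons,
       class_code = paste0(m[2], m[4]))
}

#' Format a parsed ceramide back to its label
#'
#' Inverse of [parseCeramideName()]; `format(parse(x)) == x` for every
#' valid label.
#'
#' @param parsed list as returned by [parseCeramideName()].
#' @return character label.
#' @export
formatCeramideName <- function(parsed) {
  if (is.na(parsed$class_code)) return(parsed$raw_label)
  sprintf("CER[%s(%d)%s(%d)]", parsed$fa_class, parsed$fa_carbons,
          parsed$base, parsed$base_carbons)
}
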