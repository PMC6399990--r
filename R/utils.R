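# internal helpers shared across modules

#' @noRd
msg <- function(..., quiet = getOption("apoeprs.quiet", FALSE)) {
  if (!isTRUE(quiet)) message("[apoeprs] ", ...)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot() with readable messages
#' @noRd
check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

# deterministic float formatting for writers: 6 significant digits,
# plain notation for the magnitudes we emit
#' @noRd
fmt_num <- function(x) {
  out <- formatC(signif(x, 6), format = "fg", flag = "#", digits = 6)
  out <- sub("\\.$", "", trimws(out))
  out[!is.finite(x)] <- "NA"
  out
}

# expected alleleB dosage from a probability array (samples x snps x 3)
#' @noRd
expected_dosage <- function(probs) {
  probs[, , 2L, drop = FALSE][, , 1L] + 2 * probs[, , 3L, drop = FALSE][, , 1L]
}

# strand-ambiguous (palindromic) allele pair?
#' @noRd
is_ambiguous_pair <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}
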