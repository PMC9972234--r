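# small shared helpers

#' Round half away from zero
#'
#' Reporting rounds percentages half-up (91.8 -> 92, 50.5 -> 51), unlike
#' base R's round-half-even.
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic 32-bit seed stream derived from a user seed
mix_seed <- function(seed, i) {
  as.integer((as.double(seed %% 65536L) * 62497 + i * 151) %% 2147483647)
}

# structured result of one fitted model / test
model_result <- function(kind, term, beta, ci_lo = NA_real_, ci_hi = NA_real_,
                         p = NA_real_, flags = character(0)) {
  out <- data.frame(term = term, beta = beta, ci_lo = ci_lo, ci_hi = ci_hi,
                    p = p, stringsAsFactors = FALSE)
  structure(list(kind = kind, coef = out, flags = flags),
            class = "chronact_model")
}

#' @export
print.chronact_model <- function(x, ...) {
  cat(sprintf("<%s model>%s\n", x$kind,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  print(x$coef, row.names = FALSE, digits = 4)
  invisible(x)
}
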