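#' Derive a child random seed from a master seed and labels
#'
#' All randomness in the package flows from a single master seed through this
#' rule: the labels identifying a random draw (for example
#' `("scan", "sub003", "test", "rest1")`) are concatenated with `/` and hashed
#' with a 31-multiplier polynomial rolling hash modulo 2^31 - 1; the child
#' seed is `(master + hash) mod (2^31 - 1)`. Because the child stream depends
#' only on the labels, adding or removing subjects never perturbs the draws
#' of the remaining ones.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)),
                  collapse = "/")
  h <- 0
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((as.numeric(master) + h) %% 2147483647)
}

# Fisher r-to-z with clamping so |r| = 1 (possible for degenerate inputs)
# stays finite; tolerance keeps atanh below ~14.
fisher_z <- function(r) atanh(pmax(pmin(r, 1 - 1e-12), -1 + 1e-12))

# z-score a vector; constant or length-1 input maps to zeros rather than NaN.
zscore <- function(x) {
  s <- stats::sd(x)
  if (length(x) < 2L || !is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

parcel_ids <- function(p) sprintf("p%03d", seq_len(p))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fc <- function(...) stop(sprintf(...), call. = FALSE)
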