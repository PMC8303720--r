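#' @noRd
cry_error <- function(msg, class) {
  stop(structure(class = c(class, "cryscreen_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Reverse complement of a DNA string
#'
#' Plain character interface used by the read scanner; ambiguous bases
#' other than N are passed through [chartr()] untouched.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Format an allele frequency at fixed precision
#'
#' Reports mix two display conventions at four decimals: arithmetic
#' rounding and plain truncation. Operations in this package always
#' return full precision; this formatter applies one explicit convention
#' for display or comparison against published values.
#'
#' @param f numeric vector of frequencies.
#' @param digits number of decimal places (default 4).
#' @param mode `"round"` or `"truncate"`.
#' @return numeric vector at the requested precision.
#' @examples
#' format_frequency(27 / 82, mode = "truncate") # 0.3292
#' format_frequency(22 / 82, mode = "round")    # 0.2683
#' @export
format_frequency <- function(f, digits = 4, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  scale <- 10^digits
  switch(mode,
         round = round(f * scale) / scale,
         truncate = trunc(f * scale + sqrt(.Machine$double.eps)) / scale)
}

# Deterministic child seed (< 2^31) derived from a master seed and a tag.
#' @noRd
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Run code under a temporary RNG state.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
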