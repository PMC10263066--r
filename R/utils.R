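#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Stable integer derivation so that each stage / sample of a seeded run has
#' its own reproducible stream.  Results stay below 2^31.
#'
#' @param seed master integer seed.
#' @param index non-negative integer stream index.
#' @return integer seed.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + 7919 * index) %% 2147483629)
}

# z-scale columns with the sample-sd (n-1) convention; constant columns map
# to 0 (warning), missing values are excluded from the moments and retained.
zscale_columns <- function(m, warn_constant = TRUE) {
  ctr <- apply(m, 2, mean, na.rm = TRUE)
  scl <- apply(m, 2, stats::sd, na.rm = TRUE)
  const <- !is.na(scl) & (scl == 0 | !is.finite(scl))
  if (any(const) && warn_constant) {
    warning("constant feature column(s) set to z = 0: ",
            paste(colnames(m)[const], collapse = ", "))
  }
  scl[const | is.na(scl)] <- 1
  z <- sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
  z[, const] <- 0
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}
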