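#' Derive per-stage random seeds from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed through this single splitting rule, so a whole experiment is
#' reproducible from one integer while stages remain independently
#' re-runnable.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds to draw.
#' @param labels Optional character vector of length `n`; if given, the
#'   result is named.
#' @return An integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @examples
#' split_seeds(42, 3, c("panel", "expand", "arch"))
#' @export
split_seeds <- function(master, n, labels = NULL) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  s <- sample.int(2147483646L, n)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    names(s) <- labels
  }
  s
}
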