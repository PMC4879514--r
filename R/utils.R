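#' @importFrom rlang .data abort warn %||%
#' @importFrom stats anova as.dist chisq.test cor cor.test density dist lm
#'   median optimize p.adjust quantile residuals rnorm rbinom rpois runif
#'   sd setNames var wilcox.test cmdscale model.matrix qnbinom pnorm qbeta
#'   qgamma qlnorm complete.cases coef
#' @importFrom utils head combn
NULL

# derive a reproducible 32-bit sub-seed from a master seed and stream indices
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 48271 + as.double(i)) %% 2147483647
  as.integer(s)
}

`%not in%` <- function(x, table) !(x %in% table)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}
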