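#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rpois rbinom rgamma rexp dpois density acf
#'   quantile var sd cor median model.matrix rchisq qnorm lm coef vcov predict
#'   cor.test glm quasipoisson setNames complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

# Signal a classed error so callers/tests can condition on failure type.
cqg_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "colonyQG_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

cqg_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "colonyQG_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation: one master seed fans out to named
# sub-streams (kept below 2^31 - 1).
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x)
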