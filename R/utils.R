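#' Logit transform of a proportion
#'
#' `logit()` maps a proportion strictly inside (0, 1) to the real line via
#' `log(p / (1 - p))`. WMH load is logit-transformed before modelling to
#' normalize its heavy right skew and stabilize the variance. Values at or
#' outside the boundary raise an error rather than being clamped: a load of
#' exactly 0 or 1 indicates an upstream data fault, not a value to impute.
#'
#' @param p Numeric vector of proportions, each strictly in (0, 1).
#' @return Numeric vector, `log(p / (1 - p))`.
#' @examples
#' logit(0.5)      # 0
#' logit(0.0052)   # about -5.25
#' @export
logit <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  bad <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(bad)) {
    abort(sprintf(
      "logit() requires 0 < p < 1; %d value(s) outside the open interval (first: %g).",
      sum(bad), p[which(bad)[1]]
    ))
  }
  log(p / (1 - p))
}

# Deterministic per-stage sub-seed so adding a generator stage never
# perturbs draws of earlier stages. Small string hash folded into the
# user seed, kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 + h) %% 2147483629)
}

# shared argument checks ------------------------------------------------

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must be probabilities in [0, 1].", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and nonnegative.", name))
  }
  invisible(x)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    abort(sprintf("`%s` must be finite.", name))
  }
  invisible(x)
}
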