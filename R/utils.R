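# internal helpers shared across modules

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

#' Geometric mean
#'
#' @param x numeric vector of positive values.
#' @param na.rm drop missing values before averaging.
#' @return the geometric mean, or `NA` if any value is missing and
#'   `na.rm = FALSE`.
#' @keywords internal
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (anyNA(x)) return(NA_real_)
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

stop_parse <- function(path, row, msg) {
  stop(sprintf("parse error in '%s' (row %s): %s", path, row, msg),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lognormal multiplicative noise with mean exactly 1 and the requested
# coefficient of variation
rlnorm_mean1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# sd of log(e1/e2) for two independent mean-1 lognormal factors with given cv;
# this is the logit-scale measurement noise a two-peak lane inherits
lane_logit_noise_sd <- function(cv) {
  if (cv <= 0) return(0)
  sqrt(2 * log1p(cv^2))
}
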