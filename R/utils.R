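# internal helpers shared across modules

# population standard deviation (divisor n, not n-1)
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

pop_var <- function(x) {
  x <- x[is.finite(x)]
  mean((x - mean(x))^2)
}

# multiplicative log-normal noise factors with mean 1 and coefficient of
# variation `cv`; cv = 0 returns exact 1s so the noise-free path is exact
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

runif_log <- function(n, lo, hi) {
  if (lo == hi) return(rep(lo, n))
  exp(stats::runif(n, log(lo), log(hi)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
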