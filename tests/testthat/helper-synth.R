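# shared synthetic fixtures, built in code at test time

test_grid <- function() 200:300

test_library <- function() default_library(test_grid())

# random full-coverage composition design
random_design <- function(n, seed) {
  set.seed(seed)
  data.frame(sample_id = paste0("x", seq_len(n)),
             no3_uM = stats::runif(n, 0, 80),
             no2_uM = stats::runif(n, 0, 20),
             salinity_psu = stats::runif(n, 0, 34))
}

# triplicated single-component standards for library estimation
standards_design <- function() {
  base <- data.frame(
    no3_uM = c(10, 25, 50, 0, 0, 0, 0, 0, 0),
    no2_uM = c(0, 0, 0, 5, 10, 20, 0, 0, 0),
    salinity_psu = c(0, 0, 0, 0, 0, 0, 10, 20, 34))
  out <- base[rep(seq_len(nrow(base)), 3L), ]
  out$sample_id <- paste0("std", seq_len(nrow(out)))
  out
}

# brute-force leave-one-out PRESS: refit per fold AND per factor count
press_loo_oracle <- function(X, Y, h_max) {
  n <- nrow(X)
  vapply(seq_len(h_max), function(h) {
    sum(vapply(seq_len(n), function(i) {
      m <- fit_pls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], h)
      sum((Y[i, ] - predict(m, X[i, , drop = FALSE]))^2)
    }, numeric(1L)))
  }, numeric(1L))
}

# ordinary least squares on centered data
ols_oracle_predict <- function(X, Y, Xnew) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  B <- solve(crossprod(Xc), crossprod(Xc, Yc))
  sweep(sweep(Xnew, 2L, xm) %*% B, 2L, ym, "+")
}
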