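# Independent oracle for the JZS Bayes factor: the g-prior integral form
# (inverse-gamma(1/2, scale^2/2) mixing on g, i.e. the Cauchy written as a
# scale mixture of normals), evaluated on a transformed finite domain with
# fine fixed-grid trapezoid quadrature. Entirely different parameterization
# and quadrature than the implementation's noncentral-t marginal.
jzs_bf_oracle <- function(t, n, scale = 0.707) {
  df <- n - 1
  log_m0 <- -((df + 1) / 2) * log1p(t^2 / df)
  f <- function(g) {
    a <- 1 + n * g
    exp(-0.5 * log(a) - ((df + 1) / 2) * log1p(t^2 / (a * df)) +
          stats::dgamma(1 / g, shape = 0.5, rate = scale^2 / 2, log = TRUE) -
          2 * log(g))
  }
  # substitute g = u / (1 - u), jacobian 1/(1-u)^2, u in (0,1)
  u <- seq(1e-9, 1 - 1e-9, length.out = 200001)
  g <- u / (1 - u)
  vals <- f(g) / (1 - u)^2
  log_m1 <- log(sum((vals[-1] + vals[-length(vals)]) / 2 * diff(u)))
  exp(log_m1 - log_m0)
}
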