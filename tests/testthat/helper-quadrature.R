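# Total mass of the conditional response density for one (theta, item) pair.
# Beta densities with shapes < 1 have integrable singularities at 0 and 1, so
# plain quadrature cannot reach 1e-6; substituting u = y^a near 0 and
# v = (1-y)^b near 1 flattens the integrand on both halves.
density_mass <- function(theta, item, n_quad = 301) {
  sp <- shape_params(theta, item)
  a <- sp$accept; b <- sp$refuse
  f <- function(y) exp(beta_irm_log_density(y, theta, item))
  left <- pracma::gaussLegendre(n_quad, 0, 0.5^a)
  right <- pracma::gaussLegendre(n_quad, 0, 0.5^b)
  sum(left$w * f(left$x^(1 / a)) * (1 / a) * left$x^(1 / a - 1)) +
    sum(right$w * f(1 - right$x^(1 / b)) * (1 / b) * right$x^(1 / b - 1))
}
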