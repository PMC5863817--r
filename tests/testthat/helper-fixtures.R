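# shared fixtures: small geometries and noise-free simulation settings

test_geometry <- function(...) eye_geometry(...)

noiseless_params <- function(deviation = 14, seed = 1, ...) {
  sim_params(true_deviation_deg = deviation,
             phoria_noise_sd_deg = 0, trace_noise_sd_deg = 0,
             blink_rate_hz = 0, seed = seed, ...)
}

# independent ANOVA-based oracle for ICC(2,1): mean squares straight from
# stats::aov on the long-format data
icc_a1_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   col = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + col, data = df))[[1]]
  msr <- tab[1, "Mean Sq"]; msc <- tab[2, "Mean Sq"]; mse <- tab[3, "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# covariance-formula oracle for the product-moment correlation
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
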