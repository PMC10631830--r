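# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (shoelace, lm, t.test wrappers, ANOVA shortcut).

# fan triangulation area of a convex polygon
fan_area <- function(x, y) {
  total <- 0
  for (i in 2:(length(x) - 1)) {
    total <- total + 0.5 * abs(
      (x[i] - x[1]) * (y[i + 1] - y[1]) - (x[i + 1] - x[1]) * (y[i] - y[1])
    )
  }
  total
}

# trapezoidal contour integral of P dV around the closed loop
trapz_pdv <- function(v, p) {
  vn <- c(v[-1], v[1])
  pn <- c(p[-1], p[1])
  abs(sum((p + pn) / 2 * (vn - v)))
}

# convex polygon: points of an ellipse at sorted random angles
random_convex_polygon <- function(n, seed) {
  set.seed(seed)
  th <- sort(stats::runif(n, 0, 2 * pi))
  a <- stats::runif(1, 30, 80)
  b <- stats::runif(1, 30, 80)
  list(v = 150 + a * cos(th), p = 100 + b * sin(th))
}

# smooth positive closed loop with mild harmonics (generally non-convex)
random_smooth_loop <- function(n, seed) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  v <- 150 + 50 * cos(th) + 6 * stats::runif(1) * cos(2 * th + stats::runif(1, 0, pi))
  p <- 70 + 55 * sin(th) + 5 * stats::runif(1) * sin(2 * th + stats::runif(1, 0, pi))
  list(v = v, p = pmax(p, 0.5))
}

# squared Pearson correlation by the sum formula
pearson_r2_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# percent Bland-Altman by explicit elementwise arithmetic
ba_oracle <- function(a, b) {
  d <- numeric(length(a))
  for (i in seq_along(a)) d[i] <- 100 * (a[i] - b[i]) / ((a[i] + b[i]) / 2)
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  c(bias = m, lo = m - 1.96 * s, hi = m + 1.96 * s)
}

# paired t from the difference-mean/SD formula
t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  tt <- mean(d) / (stats::sd(d) / sqrt(n))
  c(t = tt, p = 2 * stats::pt(-abs(tt), n - 1))
}

# ICC(2,1) from stats::aov mean squares
icc_aov_oracle <- function(a, b) {
  n <- length(a)
  df <- data.frame(
    value = c(a, b),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(c("a", "b"), each = n))
  )
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# sampled sinusoidal volume curve V(t) = edv - amp * sin(pi t / T)
sin_volume_curve <- function(edv = 150, amp = 50, hr = 70, n = 25) {
  period <- 60 / hr
  t <- seq(0, period, length.out = n + 1)[1:n]
  volume_curve(
    tibble::tibble(time_s = t, volume_ml = edv - amp * sin(pi * t / period)),
    heart_rate = hr
  )
}
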