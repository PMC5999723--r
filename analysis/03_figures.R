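#!/usr/bin/env Rscript
# Stage 3: figures from the analysis tables — grip-peak inverted-U with
# quartic fits and extrema, lag-vs-ln(k) with the hinge fit, inertial lag,
# and acceleration sign at force onset.

library(gripswitch)

out <- "results"
dir.create(file.path(out, "figures"), showWarnings = FALSE)
features <- read.csv(file.path(out, "features.csv"))

agg <- function(d, var) {
  a <- aggregate(d[[var]], list(lnk = round(d$lnk, 9)), mean, na.rm = TRUE)
  a[order(a$lnk), ]
}

pdf(file.path(out, "figures", "switching.pdf"), width = 9, height = 7)
par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))

cols <- c(ascending = "firebrick", descending = "steelblue")
plot(NA, xlim = c(3.4, 8), ylim = c(3.5, 6.5), xlab = "ln(stiffness)",
     ylab = "grip-force peak (N)", main = "Grip peak vs ln k")
for (cond in names(cols)) {
  d <- agg(features[features$condition == cond, ], "gf_peak")
  fit <- fit_extremum(d$lnk, d$x)
  points(d$lnk, d$x, col = cols[cond], pch = 16, cex = 0.6)
  g <- seq(min(d$lnk), max(d$lnk), length.out = 200)
  lines(g, drop(outer(g, 0:4, `^`) %*% fit$coeffs), col = cols[cond], lty = 2)
  abline(v = fit$x_star, col = cols[cond])
}
legend("topright", names(cols), col = cols, lty = 1, bty = "n")

d <- agg(features, "lag_impact_ms")
plot(d$lnk, d$x, pch = 16, cex = 0.6, xlab = "ln(stiffness)",
     ylab = "grip peak - impact lag (ms)", main = "Lag vs ln k (hinge fit)")
pw <- piecewise_fit(d$lnk, d$x, xb = 4.98)
g <- seq(min(d$lnk), max(d$lnk), length.out = 200)
lines(g, pw$intercept + pw$s_lo * pmin(g - pw$xb, 0) +
        pw$s_hi * pmax(g - pw$xb, 0), col = "firebrick")
abline(v = pw$xb, lty = 3)

d <- agg(features[is.finite(features$lag_inertial_ms), ], "lag_inertial_ms")
plot(d$lnk, d$x, pch = 16, cex = 0.6, ylim = c(-15, 15),
     xlab = "ln(stiffness)", ylab = "inertial grip lag (ms)",
     main = "First grip peak vs first acceleration peak")
abline(h = 0, lty = 3)

d <- agg(features, "acc_at_field_onset")
plot(d$lnk, d$x, pch = 16, cex = 0.6, xlab = "ln(stiffness)",
     ylab = "acceleration at force onset (m/s^2)",
     main = "Acceleration sign at force onset")
abline(h = 0, lty = 3)
abline(v = acc_sign_threshold(features$lnk, features$acc_at_field_onset),
       col = "firebrick")
dev.off()

message("wrote ", file.path(out, "figures", "switching.pdf"))
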