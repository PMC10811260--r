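# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Classical balanced one-way ANOVA variance component estimators:
# V_R = MS_within, V_G = (MS_between - MS_within) / n_reps.
anova_oneway_vc <- function(y, group) {
  group <- factor(group)
  a <- nlevels(group)
  n <- length(y) / a
  stopifnot(all(table(group) == n))
  means <- tapply(y, group, mean)
  ssw <- sum((y - means[group])^2)
  msw <- ssw / (a * (n - 1))
  msb <- n * sum((means - mean(y))^2) / (a - 1)
  list(V_G = (msb - msw) / n, V_R = msw, msb = msb, msw = msw, n = n, a = a)
}

# Restricted log-likelihood of the balanced one-way random model, written
# from the eigenstructure of V = V_R I + V_G Z Z' (up to an additive
# constant): -2 l = (N-a) log V_R + (a-1) log(V_R + n V_G)
#                 + SSW/V_R + SSB/(V_R + n V_G).
reml_loglik_oneway <- function(vg, vr, y, group) {
  group <- factor(group)
  a <- nlevels(group)
  n <- length(y) / a
  means <- tapply(y, group, mean)
  ssw <- sum((y - means[group])^2)
  ssb <- n * sum((means - mean(y))^2)
  lam <- vr + n * vg
  -0.5 * ((length(y) - a) * log(vr) + (a - 1) * log(lam) +
            ssw / vr + ssb / lam)
}

# Dense grid search over the restricted likelihood surface, refined twice.
reml_grid_oneway <- function(y, group, vg_range = c(0.01, 20),
                             vr_range = c(0.01, 20)) {
  best <- c(vg = NA, vr = NA, ll = -Inf)
  for (pass in 1:3) {
    vgs <- seq(vg_range[1], vg_range[2], length.out = 60)
    vrs <- seq(vr_range[1], vr_range[2], length.out = 60)
    for (vg in vgs) for (vr in vrs) {
      ll <- reml_loglik_oneway(vg, vr, y, group)
      if (ll > best["ll"]) best <- c(vg = vg, vr = vr, ll = ll)
    }
    dg <- diff(vg_range) / 59; dr <- diff(vr_range) / 59
    vg_range <- c(max(best["vg"] - 2 * dg, 1e-6), best["vg"] + 2 * dg)
    vr_range <- c(max(best["vr"] - 2 * dr, 1e-6), best["vr"] + 2 * dr)
  }
  best
}

# Pearson correlation from the raw sum formulas.
pearson_hand <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# A minimal valid design used by several tests.
small_design <- function(panel_size = 30, seed = 1,
                         geometry = list(blocks = 3, columns = 2, rows = 10),
                         control_reps = 2) {
  pan <- make_panel(panel_size, control_id = "CTRL", seed = seed)
  build_design(pan, geometry, reps = 2, control_id = "CTRL",
               control_reps = control_reps, seed = seed)
}

# Parameters for a single-trait (CH) simulation with configurable structure.
ch_only_params <- function(V_G = 4, V_R = 1, V_spatial = 0, doys = 160,
                           delta = function(doy) rep(0, length(doy)),
                           gxe_sd = 0, year = 1) {
  sim_params(
    variance_components = list(CH = list(V_G = V_G, V_block = V_spatial,
                                         V_column = V_spatial,
                                         V_row = V_spatial, V_R = V_R)),
    trait_baselines = list(CH = function(doy) rep(25, length(doy))),
    doys = list(CH = doys),
    drought_effect = delta, gxe_sd = gxe_sd,
    early_fraction = 0, flowering_ch_boost = 0, fault_rate = 0, year = year)
}
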