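test_that("four-layer stack is assembled with the configured surfaces", {
  cfg <- flower_config()
  st <- build_flower_stack(cfg, K_p_star = 1.4, S_p_star = 0.5)
  expect_length(st, 4)
  expect_equal(st[[1]]$r_top, 0.03)
  expect_equal(st[[1]]$t_down, 0.97)
  expect_equal(st[[4]]$r_top, 0.03)
  # with S_u* = 0 the unpigmented layer is optically absent
  st0 <- build_flower_stack(flower_config(S_u_star = 0), 1.4, 0.5)
  expect_plate_equal(combine_stack(st0),
                     combine_stack(st0[c(1, 2, 4)]), tol = 1e-15)
  # bare pigmented plate when surfaces vanish too
  st00 <- build_flower_stack(flower_config(r_surface = 0, S_u_star = 0),
                             1.4, 0.5)
  expect_plate_equal(combine_stack(st00), km_plate_rt(1.4, 0.5), tol = 1e-15)
  expect_error(flower_config(r_surface = 1), "\\[0, 1\\)")
  expect_error(flower_config(S_u_star = -0.1), ">= 0")
})

test_that("fit recovers the generating pigment spectra exactly on noiseless data", {
  grid <- default_grid()
  K <- make_pigment_kstar(grid = grid)
  S <- make_scatter_sstar(0.5, grid, trough_coupling = 0.3, K_star = K)
  cfg <- flower_config(S_u_star = 0.1)
  m <- simulate_measurement(build_flower_stack(cfg, K$value, S$value),
                            wavelength = grid)
  fit <- fit_petal(m$R_ad, m$T_ad, cfg)
  expect_true(all(fit$valid))
  expect_lt(max(abs(fit$K_p_star - K$value)), 1e-6)
  expect_lt(max(abs(fit$S_p_star - S$value)), 1e-6)
  expect_equal(fit$D, absorbance_from_kstar(fit$K_p_star))
})

test_that("degenerate configuration reduces the fit to direct layer inversion", {
  grid <- seq(400, 700, by = 5)
  K <- make_pigment_kstar(grid = grid)
  cfg0 <- flower_config(r_surface = 0, S_u_star = 0)
  m <- simulate_measurement(build_flower_stack(cfg0, K$value, 0.5),
                            wavelength = grid)
  fit <- fit_petal(m$R_ad, m$T_ad, cfg0)
  direct <- km_invert_rt(m$R_ad$value, m$T_ad$value)
  expect_equal(fit$K_p_star, direct$K_star, tolerance = 1e-10)
  expect_equal(fit$S_p_star, direct$S_star, tolerance = 1e-10)
})

test_that("K_p* is robust to the assumed S_u* while S_p* shifts visibly", {
  grid <- default_grid(by = 2)
  K <- make_pigment_kstar(grid = grid)
  truth_cfg <- flower_config(S_u_star = 0.1)
  m <- simulate_measurement(build_flower_stack(truth_cfg, K$value, 0.5),
                            wavelength = grid)
  fits <- lapply(c(0, 0.1, 0.2), function(su)
    fit_petal(m$R_ad, m$T_ad, flower_config(S_u_star = su)))
  vis <- grid >= 400
  k <- vapply(fits, function(f) f$K_p_star[vis][grid[vis] == 544], 0)
  s <- vapply(fits, function(f) mean(f$S_p_star[grid >= 650], na.rm = TRUE),
              0)
  # absorption parameter barely moves with the assumed S_u* ...
  expect_lt(max(abs(k - k[2])) / k[2], 0.1)
  # ... while the scattering parameter absorbs the difference: its relative
  # spread across the assumed S_u* values is several-fold larger
  expect_gt((max(s) - min(s)) / mean(s), 3 * (max(k) - min(k)) / mean(k))
})

test_that("prediction closes on the input spectra and is side-symmetric in T", {
  grid <- default_grid(by = 2)
  K <- make_pigment_kstar(grid = grid)
  cfg <- flower_config()
  m <- simulate_measurement(build_flower_stack(cfg, K$value, 0.5),
                            wavelength = grid)
  fit <- fit_petal(m$R_ad, m$T_ad, cfg)
  pred <- predict(fit)
  expect_lt(max(abs(pred$R_ad$value - m$R_ad$value)), 1e-10)
  expect_lt(max(abs(pred$T_ad$value - m$T_ad$value)), 1e-10)
  expect_identical(pred$T_ad$value, pred$T_ab$value)
  res <- residuals(fit)
  expect_lt(max(abs(res$reflectance)), 1e-10)
  # with pigment on top only, the abaxial side reflects more at the peak
  expect_gt(stats::approx(grid, pred$R_ab$value, 545)$y,
            stats::approx(grid, pred$R_ad$value, 545)$y)
})

test_that("with S_u* = 0 the predicted abaxial reflectance equals the adaxial input", {
  grid <- default_grid(by = 2)
  K <- make_pigment_kstar(grid = grid)
  # data from a genuinely layered petal, interpreted as homogeneous
  m <- simulate_measurement(
    build_flower_stack(flower_config(S_u_star = 0.1), K$value, 0.5),
    wavelength = grid)
  fit0 <- fit_petal(m$R_ad, m$T_ad, flower_config(S_u_star = 0))
  pred <- predict(fit0)
  v <- fit0$valid
  expect_lt(max(abs(pred$R_ab$value[v] - m$R_ad$value[v])), 1e-9)
})

test_that("fitting averaged replicates and noisy spectra degrades gracefully", {
  grid <- default_grid(by = 2)
  K <- make_pigment_kstar(grid = grid)
  cfg <- flower_config()
  stack <- build_flower_stack(cfg, K$value, 0.5)
  reps <- lapply(1:4, function(i)
    simulate_measurement(stack, noise_sd = 0.01, seed = 100 + i,
                         wavelength = grid))
  fit <- fit_petal(lapply(reps, `[[`, "R_ad"), lapply(reps, `[[`, "T_ad"),
                   cfg)
  k545 <- fit$K_p_star[grid == 544]
  expect_true(is.finite(k545))
  truth <- K$value[grid == 544]
  expect_lt(abs(k545 - truth) / truth, 0.15)
})

test_that("simulate method regenerates measurement-like replicates from a fit", {
  grid <- seq(420, 680, by = 5)
  K <- make_pigment_kstar(grid = grid)
  cfg <- flower_config()
  m <- simulate_measurement(build_flower_stack(cfg, K$value, 0.5),
                            wavelength = grid)
  fit <- fit_petal(m$R_ad, m$T_ad, cfg)
  sims <- simulate(fit, nsim = 2, seed = 5, noise_sd = 0.005)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$R_ad$value, sims[[2]]$R_ad$value))
  expect_lt(max(abs(sims[[1]]$R_ad$value - m$R_ad$value)), 0.03)
})

test_that("pigment-distribution scenarios conserve totals and rank saturation", {
  grid <- default_grid()
  K <- make_pigment_kstar(grid = grid)
  sc <- scenario_spectra(K, S_p_star = 0.5, S_u_star = 0.1)

  # same pigment and scattering totals by construction of the three stacks
  tot <- function(layers, n) {
    inner <- layers[-c(1, length(layers))]
    sums <- sapply(inner, function(p) {
      inv <- km_invert_rt(p)   # constant layers enter once per wavelength
      c(K = sum(rep_len(inv$K_star, n)), S = sum(rep_len(inv$S_star, n)))
    })
    rowSums(as.matrix(sums))
  }
  n <- length(grid)
  t_a <- tot(build_scenario("asymmetric", K$value, 0.5, 0.1), n)
  t_h <- tot(build_scenario("homogeneous", K$value, 0.5, 0.1), n)
  t_s <- tot(build_scenario("symmetric", K$value, 0.5, 0.1), n)
  expect_equal(t_a, t_h, tolerance = 1e-6)
  expect_equal(t_a, t_s, tolerance = 1e-6)

  # transmittance is side-invariant for every scenario
  for (d in names(sc)) {
    st <- build_scenario(d, K$value, 0.5, 0.1)
    cmb <- combine_stack(st)
    expect_equal(cmb$t_down, cmb$t_up, tolerance = 1e-14)
  }

  # asymmetric pigmentation gives the most saturated pigmented-side colour
  sat <- vapply(sc, function(x) saturation_metric(x$R_ad, 545), 0)
  expect_gt(sat[["asymmetric"]], sat[["homogeneous"]])
  expect_gt(sat[["asymmetric"]], sat[["symmetric"]])
  # homogeneous and symmetric petals differ far less than either differs
  # from the asymmetric one at the absorption peak
  at545 <- vapply(sc, function(x)
    stats::approx(x$R_ad$wavelength, x$R_ad$value, 545)$y, 0)
  expect_lt(abs(at545[["homogeneous"]] - at545[["symmetric"]]),
            0.5 * abs(at545[["asymmetric"]] - at545[["homogeneous"]]))
  # homogeneous and symmetric petals reflect identically from both sides
  for (d in c("homogeneous", "symmetric"))
    expect_equal(sc[[d]]$R_ad$value, sc[[d]]$R_ab$value, tolerance = 1e-12)

  # no pigment: the three scenarios coincide
  sc0 <- scenario_spectra(rep(0, length(grid)), grid, S_p_star = 0.5,
                          S_u_star = 0.1)
  expect_equal(sc0$asymmetric$R_ad$value, sc0$homogeneous$R_ad$value,
               tolerance = 1e-12)
  expect_equal(sc0$asymmetric$R_ad$value, sc0$symmetric$R_ad$value,
               tolerance = 1e-12)
  expect_error(build_scenario("striped", K$value), "arg")
})

test_that("saturation metric measures relative trough depth", {
  flat <- spectrum_km(c(300, 500, 700), c(0.4, 0.4, 0.4), "reflectance")
  expect_equal(saturation_metric(flat, 500), 0)
  half <- spectrum_km(c(400, 545, 700), c(0.8, 0.4, 0.8), "reflectance")
  expect_equal(saturation_metric(half, 545), 0.5)
  expect_error(saturation_metric(flat, 200), "range")
})

test_that("an all-invalid fit raises a degeneracy error with step counts", {
  wl <- c(400, 500, 600)
  # R + T > 1 at every wavelength: no physical middle layer exists
  R <- spectrum_km(wl, c(0.55, 0.55, 0.55), "reflectance")
  T <- spectrum_km(wl, c(0.55, 0.55, 0.55), "transmittance")
  expect_error(fit_petal(R, T, flower_config(S_u_star = 0.1)),
               class = "petalkm_degenerate_fit")
})
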