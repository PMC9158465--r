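test_that("named strains apply exactly their tabulated overrides", {
  base <- default_kp
  cnb1 <- strain_parameters(strain_config("cnb1"), base)
  expect_equal(cnb1$CaN_t, 0)
  expect_equal(cnb1$v_Pmc1, 41079)
  expect_equal(cnb1$k_MS, base$k_MS)
  cch1 <- strain_parameters(strain_config("cch1"), base)
  expect_equal(cch1$k_Cch1, 0)
  expect_equal(cch1$v_Pmc1, 41079)
  flc2 <- strain_parameters(strain_config("flc2"), base)
  expect_equal(flc2$k_MS, 238519)
  expect_equal(flc2$v_Pmc1, base$v_Pmc1)
  # unchanged fields stay at wild-type values
  expect_equal(cnb1$v_Vcx1, base$v_Vcx1)
  expect_error(strain_config("nonsense"), "unknown strain")
  expect_error(strain_config("custom"), "requires explicit overrides")
  expect_error(strain_parameters(
    strain_config("custom", overrides = list(bogus = 1))), "unknown")
})

test_that("resting baseline agrees with a brute-force bisection oracle", {
  kp <- default_kp
  bp <- default_bp
  proto <- default_proto
  oracle_root <- function(camb0) {
    dv <- default_derived
    f <- function(ca) {
      y <- c(dv$V_os0, ca, camb0, quasi_steady_canb(camb0, kp))
      oracle_rhs(0, y, kp, bp, dv, proto)[2]
    }
    lo <- 0; hi <- 29500
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    mid
  }
  for (camb0 in c(0, 0.5, 1, 5)) {
    expect_equal(resting_baseline(kp, camb0, bp, proto),
                 oracle_root(camb0), tolerance = 1e-6)
  }
  # efflux-only limit
  kp0 <- kinetic_params(k_MS = 0, k_Cch1 = 0, v_IN = 0)
  expect_equal(resting_baseline(kp0, 0, bp, proto), 0)
  # more bound calmodulin -> stronger leak inhibition -> lower baseline
  bases <- vapply(c(0, 0.5, 1, 2, 5), resting_baseline, 0,
                  params = kp, biophys = bp, protocol = proto)
  expect_true(all(diff(bases) < 0))
})

test_that("calmodulin calibration inverts the resting baseline", {
  kp <- default_kp
  # fixed point: the uninhibited baseline calibrates to camb0 = 0
  b0 <- resting_baseline(kp, 0)
  expect_equal(calibrate_resting_calmodulin(kp, b0), 0, tolerance = 1e-6)
  for (target in c(180, 215, 250)) {
    camb0 <- calibrate_resting_calmodulin(kp, target)
    expect_equal(resting_baseline(kp, camb0), target, tolerance = 1e-6)
  }
  # wild-type baseline needs about a nanomolar of bound calmodulin
  expect_equal(calibrate_resting_calmodulin(kp, 215), 0.973,
               tolerance = 0.01)
  # inert mechanosensitive leak makes the parameter non-identifiable
  kp_off <- patch_params(kp, list(k_MS = 0))
  expect_error(calibrate_resting_calmodulin(kp_off, 215),
               "non-identifiable")
  # unreachable targets: error by default, clamp on request
  expect_error(calibrate_resting_calmodulin(kp, 29450), "above")
  expect_equal(calibrate_resting_calmodulin(kp, 29450, clamp = TRUE), 0)
  expect_error(calibrate_resting_calmodulin(kp, 100), "below")
  expect_equal(calibrate_resting_calmodulin(kp, 100, clamp = TRUE),
               kp$CaM_t)
})

test_that("no-shock simulation preserves the calibrated plateau", {
  proto <- stimulus_protocol(d = 1)
  tr <- simulate_strain(strain_config("wild-type"), protocol = proto,
                        settings = fast_settings())
  # quasi-static calmodulin drifts slightly; the plateau stays within 2%
  expect_true(all(abs(tr$ca_cyt_nM - 215) / 215 < 0.02))
})

test_that("wild-type shock produces a single transient that decays", {
  tr <- simulate_strain(settings = fast_settings(dt = 0.2))
  m <- trace_metrics(tr)
  expect_gt(m$peak, m$baseline)
  expect_lt(m$time_to_peak, 120)
  # decays back toward baseline by the end of the window
  end <- tr$ca_cyt_nM[nrow(tr)]
  expect_lt(end, m$baseline + 0.25 * (m$peak - m$baseline))
  # swelling stays within a few percent of the resting volume
  rel <- (default_bp$V_b + tr$V_os_L) / default_bp$V_total0 - 1
  expect_true(all(rel >= 0 - 1e-12 & rel < 0.10))
})

test_that("conservation bounds hold along integrated trajectories", {
  for (s in list(strain_config("wild-type"),
                 strain_config("cnb1", target_baseline = 300),
                 strain_config("flc2"))) {
    tr <- simulate_strain(s, settings = fast_settings())
    kp <- attr(tr, "params")
    expect_true(all(tr$ca_cyt_nM >= 0))
    expect_true(all(tr$camb_nM >= -1e-9 & tr$camb_nM <= kp$CaM_t + 1e-9))
    expect_true(all(tr$canb_nM >= -1e-9 & tr$canb_nM <= kp$CaN_t + 1e-9))
  }
})

test_that("simulation is deterministic and robust to solver settings", {
  a <- simulate_strain(settings = fast_settings())
  b <- simulate_strain(settings = fast_settings())
  expect_identical(a$ca_cyt_nM, b$ca_cyt_nM)
  # compiled and plain-R right-hand sides integrate to the same trace
  r <- simulate_strain(settings = solver_settings(dt = 1,
                                                  compiled = FALSE))
  cc <- simulate_strain(settings = solver_settings(dt = 1))
  expect_equal(cc$ca_cyt_nM, r$ca_cyt_nM, tolerance = 1e-5)
  # tightening tolerances tenfold barely moves the reported metrics
  loose <- trace_metrics(simulate_strain(settings = solver_settings()))
  tight <- trace_metrics(simulate_strain(
    settings = solver_settings(rtol = 1e-9,
                               atol = c(1e-21, 1e-5, 1e-9, 1e-9))))
  expect_equal(tight$baseline, loose$baseline, tolerance = 1e-3)
  expect_equal(tight$peak, loose$peak, tolerance = 1e-3)
  # halving the output grid does not change the solution between nodes
  fine <- simulate_strain(settings = solver_settings(dt = 0.05))
  coarse <- simulate_strain(settings = solver_settings(dt = 0.1))
  shared <- match(coarse$time_s, fine$time_s)
  expect_equal(fine$ca_cyt_nM[shared], coarse$ca_cyt_nM,
               tolerance = 1e-4)
})

test_that("trace metrics summarise baseline, peak and latency", {
  t <- seq(0, 160, by = 1)
  flat <- data.frame(time_s = t, ca_cyt_nM = rep(100, length(t)))
  m <- trace_metrics(flat, stimulus_protocol())
  expect_equal(m$baseline, 100)
  expect_equal(m$peak, 100)
  expect_equal(m$time_to_peak, 0)
  # triangle: rise to 500 at t_off + 20, then fall
  tri <- data.frame(time_s = t, ca_cyt_nM = approx(
    c(0, 30, 50, 160), c(100, 100, 500, 100), xout = t)$y)
  m2 <- trace_metrics(tri, stimulus_protocol())
  expect_equal(m2$baseline, 100)
  expect_equal(m2$peak, 500)
  expect_equal(m2$time_to_peak, 20)
  expect_error(trace_metrics(data.frame(time_s = 100, ca_cyt_nM = 1),
                             stimulus_protocol()), "pre-stimulus")
})

test_that("knockout continuity: baseline approaches the MS-off limit", {
  kp <- default_kp
  camb_star <- function(kp, ca) {
    kp$CaM_t * ca^3 / (ca^3 + kp$km_minus / kp$km_plus)
  }
  off <- patch_params(kp, list(k_MS = 0))
  b_off <- resting_baseline(off, camb_star(off, 160))
  ks <- kp$k_MS * 10^(-(1:4))
  bases <- vapply(ks, function(k) {
    kpk <- patch_params(kp, list(k_MS = k))
    resting_baseline(kpk, camb_star(kpk, 160))
  }, 0)
  expect_true(all(diff(abs(bases - b_off)) < 0))
  expect_equal(bases[4], b_off, tolerance = 1e-3)
})

test_that("mixing-time scan tabulates metrics and reports the argmax", {
  grid <- c(5, 10, 15, 20)
  sc <- mixing_time_scan(grid, settings = fast_settings(dt = 0.2))
  expect_equal(sc$t_m, grid)
  expect_true(all(diff(sc$time_to_peak) > 0))
  expect_true(attr(sc, "t_m_opt") %in% grid)
  one <- mixing_time_scan(7, settings = fast_settings(dt = 0.2))
  expect_equal(attr(one, "t_m_opt"), 7)
  expect_error(mixing_time_scan(numeric(0)))
})

test_that("flux decomposition reproduces the calcium derivative", {
  tr <- simulate_strain(settings = solver_settings(dt = 0.1))
  fx <- flux_decomposition(tr)
  dt <- 0.1
  i <- 2:(nrow(tr) - 1)
  fd <- (tr$ca_cyt_nM[i + 1] - tr$ca_cyt_nM[i - 1]) / (2 * dt)
  keep <- abs(tr$time_s[i] - attr(tr, "protocol")$t_off) > 2 * dt
  err <- max(abs(fd[keep] - fx$net_flux[i][keep])) / max(abs(fx$net_flux))
  expect_lt(err, 0.01)
  # uninhibited fluxes bound their inhibited counterparts
  expect_true(all(fx$j_ms <= fx$j_ms0 + 1e-9 |
                    (fx$j_ms0 < 0 & fx$j_ms >= fx$j_ms0)))
  expect_true(all(fx$j_vcx1 <= fx$j_vcx10 + 1e-12))
})

test_that("traces round-trip through CSV with their metadata sidecar", {
  dir <- withr::local_tempdir()
  tr <- simulate_strain(settings = fast_settings(dt = 1))
  path <- file.path(dir, "wt.csv")
  write_trace(tr, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".meta.yaml")))
  back <- utils::read.csv(path)
  expect_equal(back$ca_cyt_nM, tr$ca_cyt_nM)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  expect_equal(meta$strain, "wild-type")
  expect_equal(meta$protocol$d, 5)
})
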