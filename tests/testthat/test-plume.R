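test_that("packet plume obeys release, advection and culling accounting", {
  cfg <- plume_config()
  pl <- simulate_plume(cfg, seed = 51)
  # expected live packets: release_rate x transit time through the arena
  live <- diff(pl$offsets)
  lifetime <- (cfg$cull_x - cfg$source[1]) / cfg$v_d
  expect_equal(mean(live), cfg$release_rate * lifetime, tolerance = 0.25)
  # concentrations are non-negative and mass-conserving: peak x sigma^2
  # is constant over a packet's life
  expect_true(all(pl$peak > 0))
  expect_equal(unique(round(pl$peak * pl$sig2, 6)),
               round(cfg$c0 * cfg$sigma0^2, 6))
  # empty plume
  pl0 <- simulate_plume(plume_config(release_rate = 0), seed = 1)
  expect_equal(length(pl0$x), 0)
  expect_equal(unname(plume_encounter_frequency(pl0, n_probe = 50,
                                                seed = 2)["frequency_hz"]), 0)
})

test_that("telegraph crosswind dispersion has exponential holding times", {
  # track sign changes of packet y-increments; culling is disabled so
  # long-lived packets provide uncensored interior holding intervals
  cfg <- plume_config(t_total = 40, release_rate = 5, growth = 2, c0 = 50,
                      dt = 1 / 240, cull_x = 1e6, cull_y = 1e6,
                      peak_floor = 1e-9, warmup = 0)
  pl <- simulate_plume(cfg, seed = 52)
  d <- data.frame(step = rep(seq_len(pl$n_steps), diff(pl$offsets)),
                  x = pl$x, y = pl$y)
  d$id <- round((d$step - 1) * cfg$dt - (d$x - cfg$source[1]) / cfg$v_d, 5)
  holds <- unlist(lapply(split(d, d$id), function(p) {
    if (nrow(p) < 200) return(NULL)
    p <- p[order(p$step), ]
    r <- rle(sign(diff(p$y)))$lengths * cfg$dt
    r[-c(1, length(r))]
  }))
  expect_gt(length(holds), 2000)
  # mean holding time 1/lambda_c with exponential spread (CV ~ 1)
  expect_equal(mean(holds), 0.5, tolerance = 0.05)
  expect_equal(sd(holds) / mean(holds), 1, tolerance = 0.15)
})

test_that("bilateral sensing is symmetric and side-sensitive", {
  pk <- data.frame(x = 0, y = 0, sig2 = 25, peak = 2)
  # packet dead ahead on the midline: left equals right by symmetry
  cc <- sensor_concentrations(0, -5, 90, pk)
  expect_equal(unname(cc["C_L"]), unname(cc["C_R"]), tolerance = 1e-9)
  # packet displaced to the agent's left
  pk2 <- data.frame(x = -2, y = 0, sig2 = 4, peak = 2)
  cc2 <- sensor_concentrations(0, -3, 90, pk2)  # heading +y, left is -x
  expect_gt(cc2["C_L"], cc2["C_R"])
  # no packets
  cc0 <- sensor_concentrations(0, 0, 0, pk[0, ])
  expect_equal(unname(cc0), c(0, 0))
  # sample grid respects the configured density and ellipse
  pts <- sensor_points()
  expect_true(all((pts$a / 0.75)^2 + (pts$b / 0.25)^2 <= 1))
  expect_equal(sort(unique(pts$side)), c(-1L, 1L))
})

test_that("HRC correlator signs odor motion direction", {
  expect_equal(hrc_motion(1, 1, 1, 1), 0)
  # pattern moving left -> right: right channel is a delayed copy of left
  cl_prev <- 2; cl <- 1; cr_prev <- 1.2; cr <- 2
  expect_gt(hrc_motion(cl_prev, cr_prev, cl, cr), 0)
  # swapping channels flips the sign exactly
  expect_equal(hrc_motion(cr_prev, cl_prev, cr, cl),
               -hrc_motion(cl_prev, cr_prev, cl, cr))
})

test_that("R and C++ sensor concentrations agree", {
  set.seed(53)
  pl <- simulate_plume(plume_config(), seed = 53)
  step <- 2500
  pk <- plume_packets_at(pl, step)
  skip_if(nrow(pk) == 0)
  x <- pk$x[1] + 2; y <- pk$y[1] - 1; th <- 135
  ref <- sensor_concentrations(x, y, th, pk)
  pts <- sensor_points()
  cc <- flynav:::cpp_sensor_conc(
    pl[c("offsets", "x", "y", "sig2", "peak", "rcut")], step - 1L,
    x, y, th, pts$a, pts$b, as.integer(pts$side))
  # the C++ path prunes far packets below ~1e-4 a.u.; agree to that scale
  expect_equal(unname(cc), unname(ref), tolerance = 1e-3)
})

test_that("encounter frequency rises with release rate", {
  f1 <- plume_encounter_frequency(plume_config(release_rate = 0.75),
                                  n_probe = 800, seed = 54)
  f2 <- plume_encounter_frequency(plume_config(release_rate = 3),
                                  n_probe = 800, seed = 54)
  f3 <- plume_encounter_frequency(plume_config(release_rate = 7),
                                  n_probe = 800, seed = 54)
  expect_lt(f1["frequency_hz"], f2["frequency_hz"])
  expect_lt(f2["frequency_hz"], f3["frequency_hz"])
  # calibrated default: low-frequency plume sits near 0.2 Hz
  expect_equal(unname(f1["frequency_hz"]), 0.2, tolerance = 0.2)
})

test_that("navigation control logic behaves at the edges", {
  # no odor: success does not depend on the plume seed (there is none) and
  # the bootstrap stderr matches the binomial scale
  r1 <- navigate(plume = NULL, n_agents = 800, seed = 55)
  r2 <- navigate(plume = NULL, n_agents = 800, seed = 55)
  expect_identical(r1$success, r2$success)
  expect_true(all(r1$n_onsets == 0))
  sr <- success_rate(r1, n_boot = 400)
  p <- sr[["fraction"]]
  if (p > 0) {
    expect_equal(sr[["stderr"]], sqrt(p * (1 - p) / 800), tolerance = 0.5)
  }
  # success region fractions stay in [0, 1]
  expect_true(all(r1$success %in% c(0L, 1L)))
})

test_that("bootstrap success statistics and z-test are coherent", {
  set.seed(56)
  a <- rbinom(3000, 1, 0.2)
  b <- rbinom(3000, 1, 0.25)
  sr <- success_rate(a, n_boot = 500)
  expect_equal(sr[["fraction"]], mean(a))
  expect_equal(sr[["stderr"]], sqrt(mean(a) * (1 - mean(a)) / 3000),
               tolerance = 0.25)
  rt <- success_ratio(a, b, n_boot = 500)
  expect_equal(rt[["ratio"]], mean(a) / mean(b), tolerance = 1e-9)
  z <- success_z_test(a, b)
  expect_lt(z[["p_value"]], 0.05)
  za <- success_z_test(a, a)
  expect_equal(za[["p_value"]], 1)
  # all-success edge
  expect_equal(unname(success_rate(rep(1, 50), n_boot = 50)),
               c(1, 0))
})

test_that("plume agents respond to odor and ablation hooks engage", {
  pl <- simulate_plume(plume_config(), seed = 57)
  full <- navigate(pl, n_agents = 250, motion = TRUE, seed = 58,
                   collect_nbar = TRUE)
  expect_gt(mean(full$n_onsets), 0.5)
  expect_length(full$nbar, as.integer(75 * 60))
  expect_true(all(full$nbar >= 0 & full$nbar <= 1))
  abl <- navigate(pl, n_agents = 250, motion = TRUE, ablation = "both",
                  nbar = full$nbar, seed = 59)
  expect_equal(abl$ablation, "both")
  # motion off is a valid policy path
  nm <- navigate(pl, n_agents = 100, motion = FALSE, seed = 60)
  expect_true(all(nm$success %in% c(0L, 1L)))
})
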