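# generator/analyzer roundtrips and sampling statistics of the synthetic
# geometry module

roundtrip_schedule <- function() {
  geometry_schedule(
    bd = data.frame(rc = c(-4, 0), value = c(85, 105)),
    fl = data.frame(rc = c(-4, 0), value = c(8, 0)),
    tau = data.frame(rc = c(-4, 0), value = c(-20, 60)),
    d_n_p5p = data.frame(rc = c(-4, 0), value = c(4.3, 4.0)),
    d_c_o3p = data.frame(rc = c(-4, 0), value = c(4.96, 1.75)),
    d_n_o3p = data.frame(rc = c(-4, -2.5, 0), value = c(5.8, 4.2, 3.2))
  )
}

test_that("zero-noise roundtrip recovers every scheduled observable exactly", {
  sched <- roundtrip_schedule()
  rcs <- seq(-4, 0, by = 0.25)
  fr <- generate_geometry_frames(sched, rcs, seed = 1)
  obs <- geometry_observables(fr)
  targets <- lapply(sched$observables, function(bp) approx(bp$rc, bp$value, rcs, rule = 2)$y)
  expect_equal(obs$bd, targets$bd, tolerance = 1e-7)
  expect_equal(obs$fl, targets$fl, tolerance = 1e-7)
  expect_equal(obs$tau, targets$tau, tolerance = 1e-7)
  expect_equal(obs$d_n_p5p, targets$d_n_p5p, tolerance = 1e-9)
  expect_equal(obs$d_c_o3p, targets$d_c_o3p, tolerance = 1e-9)
  expect_equal(obs$d_n_o3p, targets$d_n_o3p, tolerance = 1e-9)
  # derived H3'-O3' distance makes the computed RC the nominal one
  expect_equal(obs$rc_computed, rcs, tolerance = 1e-9)
})

test_that("specific scheduled distances are recovered (TS-like and post-TS frames)", {
  d_sched <- geometry_schedule_preset("D-Ala", noise = c(bd = 0))
  fr <- generate_geometry_frames(d_sched, c(-0.55, -0.3), seed = 2)
  obs <- geometry_observables(fr)
  expect_equal(obs$d_n_p5p[1], 5.1, tolerance = 1e-9)   # held until the barrier
  expect_equal(obs$d_n_p5p[2], 6.3, tolerance = 1e-9)   # jump after passing it
  l_sched <- geometry_schedule_preset("L-Ala", noise = c(bd = 0))
  frl <- generate_geometry_frames(l_sched, -0.5, seed = 2)
  expect_equal(geometry_observables(frl)$d_n_p5p, 4.0, tolerance = 1e-9)
})

test_that("scheduled noise reproduces its Gaussian statistics", {
  sched <- geometry_schedule(
    bd = data.frame(rc = c(-4, 0), value = c(100, 100)),
    fl = data.frame(rc = c(-4, 0), value = c(0, 0)),
    tau = data.frame(rc = c(-4, 0), value = c(30, 30)),
    d_n_p5p = data.frame(rc = c(-4, 0), value = c(4.3, 4.3)),
    d_c_o3p = data.frame(rc = c(-4, 0), value = c(3, 3)),
    noise = c(bd = 2)
  )
  fr <- generate_geometry_frames(sched, rep(-2, 4000), seed = 3)
  bd <- geometry_observables(fr)$bd
  sem <- 2 / sqrt(4000)
  expect_lt(abs(mean(bd) - 100), 3 * sem)
  expect_equal(sd(bd), 2, tolerance = 0.1)
})

test_that("infeasible target sets raise a construction error", {
  sched <- geometry_schedule(
    bd = data.frame(rc = c(-4, 0), value = c(105, 105)),
    fl = data.frame(rc = c(-4, 0), value = c(0, 0)),
    tau = data.frame(rc = c(-4, 0), value = c(0, 0)),
    d_n_p5p = data.frame(rc = c(-4, 0), value = c(4, 4)),
    d_c_o3p = data.frame(rc = c(-4, 0), value = c(5, 5)),
    d_n_o3p = data.frame(rc = c(-4, 0), value = c(0.5, 0.5))  # unreachable
  )
  expect_error(generate_geometry_frames(sched, -2, seed = 1),
               class = "chiralpmf_construction_error")
})

test_that("schedule validation rejects out-of-range targets", {
  bad_bd <- data.frame(rc = c(-4, 0), value = c(-5, 200))
  ok <- data.frame(rc = c(-4, 0), value = c(4, 4))
  expect_error(
    geometry_schedule(bd = bad_bd,
                      fl = data.frame(rc = c(-4, 0), value = c(0, 0)),
                      tau = data.frame(rc = c(-4, 0), value = c(0, 0)),
                      d_n_p5p = ok, d_c_o3p = ok),
    class = "chiralpmf_value_error")
  expect_error(
    geometry_schedule(bd = data.frame(rc = c(-4, 0), value = c(100, 100)),
                      fl = data.frame(rc = c(-4, 0), value = c(0, 0)),
                      tau = data.frame(rc = c(-4, 0), value = c(0, 0)),
                      d_n_p5p = ok,
                      d_c_o3p = data.frame(rc = c(-4, 0), value = c(-1, 3))),
    class = "chiralpmf_value_error")
})

test_that("the preset L and D pathways diverge the way the two stereochemistries do", {
  rcs <- seq(-4, 0, by = 0.05)
  frL <- generate_geometry_frames(geometry_schedule_preset("L-Ala"), rcs, seed = 4)
  frD <- generate_geometry_frames(geometry_schedule_preset("D-Ala"), rcs, seed = 4)
  w <- build_window_schedule(umbrella_segments())
  obsL <- geometry_observables(frL)
  obsD <- geometry_observables(frD)
  tauL <- window_statistics(obsL, "tau", w, circular = TRUE)
  tauD <- window_statistics(obsD, "tau", w, circular = TRUE)
  # D flips cis -> trans near -2.2; L rotates gradually and stays below 90
  expect_lt(max(abs(tauL$mean)), 90)
  expect_gt(abs(tauD$mean[which.min(abs(tauD$window_center + 0.5))]), 150)
  expect_lt(abs(tauD$mean[which.min(abs(tauD$window_center + 3.5))]), 30)
  # the amino group ends ~1 A closer to the 5'-phosphate for L at the barrier
  npL <- window_statistics(obsL, "d_n_p5p", w)
  npD <- window_statistics(obsD, "d_n_p5p", w)
  iL <- which.min(abs(npL$window_center + 0.5))
  iD <- which.min(abs(npD$window_center + 0.55))
  expect_gt(npD$mean[iD] - npL$mean[iL], 0.6)
})
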