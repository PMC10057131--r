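test_that("approach angles on hand-built geometries", {
  base <- tibble::tibble(
    frame = 1L,
    atom = atom_labels(),
    x = c(-1, -2, 0, 1, -0.5, -0.5, -1.5, -3),
    y = c(0, 0, 0, 0, 1.2, -1.2, 1.8, 2.5),
    z = c(0, 0, 0, 0, 0, 0, 0.5, 1)
  )
  expect_equal(bd_angle(base), 180)  # O3' opposite Ocarb through Ccarb
  above <- dplyr::mutate(base, x = replace(x, atom == "O3p", 0),
                         z = replace(z, atom == "O3p", 2))
  expect_equal(bd_angle(above), 90)
  expect_error(bd_angle(dplyr::mutate(base, x = replace(x, atom == "O3p", 0),
                                      y = replace(y, atom == "O3p", 0),
                                      z = replace(z, atom == "O3p", 0))),
               class = "chiralpmf_value_error")
})

test_that("Flippin-Lodge angle has the documented zero and boundary geometry", {
  # carbonyl plane = xy; Ob on the -y side; O3' in the axis-normal plane -> 0
  fr <- tibble::tibble(
    frame = 1L,
    atom = atom_labels(),
    x = c(0.5, 0.5, 0, 1.23, -0.76, -0.78, -1.5, -3),
    y = c(0, 0, 0, 0, 1.32, -1.11, 1.8, 2.5),
    z = c(-2, -3.5, 0, 0, 0, 0, 0.5, 1)
  )
  expect_equal(fl_angle(fr), 0, tolerance = 1e-9)
  # O3' inside the carbonyl plane on the Ob side -> +90 boundary
  in_plane <- dplyr::mutate(fr, y = replace(y, atom == "O3p", -2),
                            z = replace(z, atom == "O3p", 0))
  expect_equal(fl_angle(in_plane), 90)
  # and on the opposite side the boundary folds to +90 as well
  other <- dplyr::mutate(fr, y = replace(y, atom == "O3p", 2),
                         z = replace(z, atom == "O3p", 0))
  expect_equal(abs(fl_angle(other)), 90)
})

test_that("torsions hit the cis, trans and figure-fixture references", {
  mk <- function(tau) {
    s <- geometry_schedule(
      bd = data.frame(rc = c(-1, 1), value = c(105, 105)),
      fl = data.frame(rc = c(-1, 1), value = c(5, 5)),
      tau = data.frame(rc = c(-1, 1), value = c(tau, tau)),
      d_n_p5p = data.frame(rc = c(-1, 1), value = c(4.5, 4.5)),
      d_c_o3p = data.frame(rc = c(-1, 1), value = c(2.8, 2.8)))
    generate_geometry_frames(s, 0, seed = 1)
  }
  expect_equal(dihedral_angle(mk(0)), 0, tolerance = 1e-7)       # planar cis
  expect_equal(dihedral_angle(mk(180)), 180, tolerance = 1e-7)   # planar trans
  fixture <- read_xyz_frames(system.file("extdata", "tau_minus60_synthetic.xyz",
                                         package = "chiralpmf"))
  expect_equal(dihedral_angle(fixture), -60, tolerance = 1e-6)
  expect_error(
    dihedral_angle(mk(10), atoms = c("Ccarb", "O3p", "H3p", "N")),
    class = "chiralpmf_geometry_error")  # H3' recedes along the Ccarb-O3' line
})

test_that("all observables match brute-force oracles on random frames", {
  set.seed(71)
  worst <- c(bd = 0, fl = 0, tau = 0)
  for (i in 1:300) {
    fr <- random_frame()
    m <- frame_mat(fr)
    worst["bd"] <- max(worst["bd"],
                       abs(bd_angle(fr) - oracle_angle(m["O3p", ], m["Ccarb", ], m["Ocarb", ])))
    worst["fl"] <- max(worst["fl"], abs(fl_angle(fr) - oracle_fl(m)))
    worst["tau"] <- max(worst["tau"],
                        abs(dihedral_angle(fr) -
                              oracle_dihedral(m["Ob", ], m["Ccarb", ], m["Ca", ], m["N", ])))
    kd <- key_distances(fr)
    expect_equal(kd$d_n_o3p, sqrt(sum((m["N", ] - m["O3p", ])^2)))
    expect_equal(kd$rc, kd$d_h_o3p - kd$d_c_o3p)
  }
  expect_lt(max(worst), 1e-9)
})

test_that("observables are rigid-motion invariant; reflection flips only the chiral ones", {
  set.seed(72)
  for (i in 1:25) {
    fr <- random_frame()
    moved <- apply_rigid(fr, random_rotation(), stats::rnorm(3, sd = 5))
    expect_equal(bd_angle(moved), bd_angle(fr), tolerance = 1e-9)
    expect_equal(fl_angle(moved), fl_angle(fr), tolerance = 1e-9)
    expect_equal(dihedral_angle(moved), dihedral_angle(fr), tolerance = 1e-9)
    expect_equal(key_distances(moved), key_distances(fr), tolerance = 1e-9)

    mirr <- reflect_z(fr)
    expect_equal(bd_angle(mirr), bd_angle(fr), tolerance = 1e-9)
    if (abs(abs(fl_angle(fr)) - 90) > 1e-6) {
      expect_equal(fl_angle(mirr), -fl_angle(fr), tolerance = 1e-9)
    }
    if (abs(abs(dihedral_angle(fr)) - 180) > 1e-6) {
      expect_equal(dihedral_angle(mirr), -dihedral_angle(fr), tolerance = 1e-9)
    }
  }
})

test_that("key distances on unit-cube corners give the hand values", {
  fr <- tibble::tibble(
    frame = 1L,
    atom = atom_labels(),
    x = c(0, 1, 0, 1, 0, 1, 0, 1),
    y = c(0, 0, 1, 1, 0, 0, 1, 1),
    z = c(0, 0, 0, 0, 1, 1, 1, 1)
  )
  kd <- key_distances(fr)
  expect_equal(kd$d_c_o3p, 1)          # edge
  expect_equal(kd$d_h_o3p, 1)          # edge
  expect_equal(kd$d_n_o3p, sqrt(2))    # face diagonal
  expect_equal(kd$d_n_p5p, 1)          # edge
  expect_equal(kd$rc, 0)
  err <- expect_error(key_distances(fr[fr$atom != "P5p", ]),
                      class = "chiralpmf_value_error")
  expect_match(conditionMessage(err), "P5p")
})

test_that("window statistics honour circular wraparound and window ranges", {
  w <- build_window_schedule(schedule_segment(-3, 0, 0.5))
  obs <- tibble::tibble(rc = rep(c(-2, -1), each = 4),
                        tau = c(179, -179, 178, -178, 10, 12, 8, 10))
  st <- window_statistics(obs, "tau", w, circular = TRUE, range = c(-4, 0))
  expect_equal(st$mean[st$window_center == -2], 180, tolerance = 1e-9)
  expect_lt(st$sd[st$window_center == -2], 2)
  # non-wrapping data: circular and linear means agree
  st_lin <- window_statistics(obs, "tau", w, circular = FALSE)
  expect_equal(st$mean[st$window_center == -1],
               st_lin$mean[st_lin$window_center == -1], tolerance = 1e-9)
  # identical values collapse to sd 0
  obs2 <- tibble::tibble(rc = rep(-0.5, 5), bd = rep(105, 5))
  st2 <- window_statistics(obs2, "bd", w)
  expect_equal(st2$mean, 105)
  expect_equal(st2$sd, 0)
  expect_equal(st2$n, 5L)
  # range restriction drops windows outside
  st3 <- window_statistics(obs, "tau", w, range = c(-1.4, 0))
  expect_false(any(st3$window_center < -1.4))
})
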