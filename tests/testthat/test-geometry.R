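test_that("surface area matches hand-computed single-pillar and pillar-free beds", {
  # pillar-free bed: floor + ceiling only
  empty <- bed_geometry(10, 1, 90, "circular", 100, 15, 0)
  expect_equal(internal_surface_area(empty), 0.2, tolerance = 1e-12)

  # one circular pillar d = 100 um, depth 90 um in a 1 mm x 1 mm bed
  one <- bed_geometry(1, 1, 90, "circular", 100, 15, 1)
  hand <- (pi * 100e-6 * 90e-6 + 2 * (1e-6 - pi * (50e-6)^2 / 1)) * 1e4
  expect_equal(internal_surface_area(one), hand, tolerance = 1e-12)

  # diamond pillar of side s: perimeter 4 s, footprint s^2
  dia <- bed_geometry(1, 1, 50, "diamond", 10, 10, 1)
  hand_dia <- (4 * 10e-6 * 50e-6 + 2 * (1e-6 - (10e-6)^2)) * 1e4
  expect_equal(internal_surface_area(dia), hand_dia, tolerance = 1e-12)
})

test_that("surface area is additive over beds and increasing in pillar count", {
  bed_n <- function(n) bed_geometry(23, 3.6, 50, "diamond", 10, 10, n)
  a1 <- internal_surface_area(bed_n(1000))
  a2 <- internal_surface_area(bed_n(2000))
  expect_gt(a2, a1)
  dev <- device_geometry(list(bed_n(1000), bed_n(1000)), "serial")
  expect_equal(internal_surface_area(dev), 2 * a1, tolerance = 1e-12)
})

test_that("packaged device fixtures reproduce the characterized surface areas", {
  d3 <- load_device_config(evcapture_fixture("evmap_3bed"))
  d7 <- load_device_config(evcapture_fixture("evmap_7bed"))
  expect_equal(internal_surface_area(d3), 6.8, tolerance = 0.15)
  expect_equal(internal_surface_area(d7), 38.5, tolerance = 0.05)
})

test_that("invalid geometries are rejected", {
  expect_error(bed_geometry(-1, 1, 90, "circular", 100, 15, 10), "positive")
  expect_error(bed_geometry(1, 1, 90, "circular", 100, 15, 2.5), "integer")
  # footprint exceeding the floor: 200 pillars of d = 100 um in 1 mm^2
  expect_error(bed_geometry(1, 1, 90, "circular", 100, 15, 200), "footprint")
})

test_that("EV load capacity follows the packing formula and its scaling laws", {
  # identity: packing 1 over the footprint of a single sphere
  d <- 150
  area_one <- pi * (d * 1e-9 / 2)^2 * 1e4
  expect_equal(ev_load_capacity(area_one, d, packing = 1), 1,
               tolerance = 1e-12)
  # linear in area and packing, inverse-quadratic in diameter
  base <- ev_load_capacity(6.8, 150)
  expect_equal(ev_load_capacity(13.6, 150), 2 * base, tolerance = 1e-12)
  expect_equal(ev_load_capacity(6.8, 150, packing = 0.45),
               0.45 / (pi / (2 * sqrt(3))) * base, tolerance = 1e-12)
  expect_equal(ev_load_capacity(6.8, 300), base / 4, tolerance = 1e-12)
  expect_error(ev_load_capacity(6.8, -150), "positive")
})

test_that("antibody coverage converts mass to molar amount and density", {
  cov <- antibody_coverage(23.1, 150, 38.5)
  expect_equal(cov$amount_pmol, 154, tolerance = 0.005)
  expect_equal(cov$density_pmol_cm2, 4.0, tolerance = 0.005)
  cov3 <- antibody_coverage(3.9, 150, 6.8)
  expect_equal(cov3$amount_pmol, 26.7, tolerance = 0.05)
  expect_equal(cov3$density_pmol_cm2, 3.9, tolerance = 0.05)
  zero <- antibody_coverage(0, 150, 6.8)
  expect_equal(zero$amount_pmol, 0)
  expect_equal(zero$density_pmol_cm2, 0)
})

test_that("open cross-section uses the pillar-row constriction", {
  # empty bed: full width x depth
  empty <- bed_geometry(10, 1, 50, "circular", 10, 10, 0)
  expect_equal(open_cross_section(empty), 1e-3 * 50e-6, tolerance = 1e-12)
  # 7 parallel beds, 3.6 mm x 50 um, spacing = pillar = 10 um -> half open
  bed <- bed_geometry(23, 3.6, 50, "diamond", 10, 10, 210816)
  dev7 <- device_geometry(rep(list(bed), 7), "parallel")
  expect_equal(open_cross_section(dev7), 7 * 3.6e-3 * 50e-6 * 0.5,
               tolerance = 1e-12)
  # a serial device presents its single-bed cross-section
  dev_serial <- device_geometry(rep(list(bed), 3), "serial")
  expect_equal(open_cross_section(dev_serial), open_cross_section(bed))
})

test_that("parallel devices must consist of identical beds", {
  a <- bed_geometry(23, 3.6, 50, "diamond", 10, 10, 1000)
  b <- bed_geometry(23, 3.6, 50, "diamond", 10, 15, 1000)
  expect_error(device_geometry(list(a, b), "parallel"), "identical")
  expect_silent(device_geometry(list(a, b), "serial"))
})

test_that("geometry report collects the derived metrics", {
  d7 <- load_device_config(evcapture_fixture("evmap_7bed"))
  rep7 <- geometry_report(d7, antibody_mass_ug = 23.1)
  expect_s3_class(rep7, "tbl_df")
  expect_equal(rep7$n_pillars, 1475712)
  expect_equal(rep7$surface_area_cm2, internal_surface_area(d7))
  expect_equal(rep7$antibody_pmol, 154, tolerance = 0.01)
  expect_equal(rep7$ev_capacity,
               ev_load_capacity(internal_surface_area(d7), 150))
})
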