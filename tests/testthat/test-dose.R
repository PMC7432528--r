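test_that("source sampling is uniform, deterministic and inside the shape", {
  spec <- toy_spectrum()
  # unit cube: all points inside
  cube <- region(shape_box(c(0, 0, 0), c(1, 1, 1)), "air")
  src <- source_region(cube, spec)
  plan <- sampling_plan(500, seed = 5)
  pts <- sample_source_points(src, plan)
  expect_equal(nrow(pts), 500)
  expect_true(all(pts >= 0 & pts <= 1))
  # same seed, same points; different seed differs
  expect_identical(pts, sample_source_points(src, plan))
  expect_false(identical(pts, sample_source_points(
    src, sampling_plan(500, seed = 6))))

  # cylindrical shell: empirical mean radius matches the closed form
  ro <- 2.35; ri <- 2.085
  shell <- region(shape_cylinder(c(0, 0, 0), c(0, 0, 1), ro, 4, ri), "air")
  ssrc <- source_region(shell, spec)
  p2 <- sample_source_points(ssrc, sampling_plan(20000, seed = 9))
  r <- sqrt(p2[, 1]^2 + p2[, 2]^2)
  analytic <- 2 * (ro^3 - ri^3) / (3 * (ro^2 - ri^2))
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - analytic), 3 * se)
  expect_true(all(r >= ri - 1e-9 & r <= ro + 1e-9))
  expect_true(all(p2[, 3] >= 0 & p2[, 3] <= 4))
})

test_that("vacuum point-source limit reproduces the closed form exactly", {
  tc <- make_toy_cases(seed = 3)
  cs <- tc$vacuum_point
  f <- group_flux(cs$scene, cs$source, cs$point, cs$plan, buildup_none())
  expect_equal(sum(f), cs$expected, tolerance = 1e-13)
  # 2-mfp slab: kernel attenuated by e^{-2}
  cs2 <- tc$slab_2mfp
  f2 <- group_flux(cs2$scene, cs2$source, cs2$point, cs2$plan, buildup_none())
  expect_equal(sum(f2), cs2$expected, tolerance = 1e-9)
  # with build-up on, flux increases but not above B_max
  f2b <- group_flux(cs2$scene, cs2$source, cs2$point, cs2$plan, buildup_model())
  expect_gt(sum(f2b), sum(f2))
})

test_that("zero activity, linearity and superposition are exact", {
  spec0 <- toy_spectrum(activity = 0)
  cube <- region(shape_box(c(0, 0, 0), c(0.1, 0.1, 0.1)), "air")
  sc <- scene_model(list(cube))
  plan <- sampling_plan(200, seed = 2)
  f0 <- group_flux(sc, source_region(cube, spec0), c(1, 0, 0), plan)
  expect_equal(sum(f0), 0)

  src1 <- source_region(cube, toy_spectrum(activity = 1e7))
  src2 <- source_region(cube, toy_spectrum(activity = 2e7))
  h <- dose_conversion_table(toy_groups())
  d1 <- dose_rate(sc, src1, c(1, 0, 0), plan, buildup_none(), h)
  d2 <- dose_rate(sc, src2, c(1, 0, 0), plan, buildup_none(), h)
  expect_equal(d2$dose_rate, 2 * d1$dose_rate, tolerance = 1e-13)

  # superposition over two mirrored sources
  tc <- make_toy_cases(seed = 4)
  cs <- tc$mirrored_pair
  dA <- dose_rate(cs$scene, cs$source[[1]], cs$point, cs$plan, buildup_none())
  dB <- dose_rate(cs$scene, cs$source[[2]], cs$point, cs$plan, buildup_none())
  # dose_map sums over sources; with the same node plan the per-source doses
  # superpose exactly
  both <- dose_map(cs$scene, cs$source,
                   list(x = cs$point[1], y = cs$point[2], z = cs$point[3]),
                   cs$plan, buildup_none(),
                   dose_conversion_table(toy_groups()))
  node_seed <- (cs$plan$seed + alaradose:::fnv1a32(
    sprintf("%.9g_%.9g_%.9g", cs$point[1], cs$point[2], cs$point[3]))) %% 2^31
  np <- sampling_plan(cs$plan$n_samples, seed = node_seed,
                      exclusion_cm = cs$plan$exclusion_cm)
  sum_individual <- sum(vapply(cs$source, function(s)
    dose_rate(cs$scene, s, cs$point, np, buildup_none())$dose_rate,
    numeric(1)))
  expect_equal(both$dose_rate_msv_h, sum_individual, tolerance = 1e-12)
  # symmetric sources give equal doses within MC error
  expect_lt(abs(dA$dose_rate / dB$dose_rate - 1),
            6 * (dA$stderr + dB$stderr) / dA$dose_rate + 1e-3)
})

test_that("dose result bookkeeping: h*flux identity and nuclide split", {
  fix <- build_kori_fixture()
  spec <- build_spectrum(fix$inventories$active)
  src <- source_region(kori_part_region(fix, "active"), spec)
  pt <- kori_worker_point(fix, "active", "cutter")
  h <- dose_conversion_table(spec$group_structure)
  dr <- dose_rate(fix$scene, src, pt, sampling_plan(2000, seed = 11),
                  buildup_model(), h)
  expect_equal(dr$dose_rate, sum(h$h * dr$group_flux), tolerance = 1e-12)
  expect_equal(sum(dr$per_nuclide), dr$dose_rate, tolerance = 1e-9)
  fr <- nuclide_fractions(dr)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(sum(fr), 1, tolerance = 1e-9)

  # single nuclide source -> fraction 1
  co <- build_spectrum(inventory("a", "Co-60", 1e12))
  dco <- dose_rate(fix$scene, source_region(kori_part_region(fix, "active"), co),
                   pt, sampling_plan(500, seed = 3))
  expect_equal(unname(nuclide_fractions(dco)["Co-60"]), 1)

  # two identical nuclides at equal activity split exactly in half
  lib2 <- structure(list(
    nuclides = data.frame(nuclide = c("tA", "tB"), half_life_years = c(5, 5)),
    lines = data.frame(nuclide = c("tA", "tB"), energy_mev = c(1.25, 1.25),
                       yield = c(1, 1))), class = "nuclide_library")
  sp2 <- build_spectrum(inventory("a", c("tA", "tB"), c(1e9, 1e9)),
                        toy_groups(), lib2)
  cube <- region(shape_box(c(0, 0, 0), c(0.1, 0.1, 0.1)), "air")
  d2 <- dose_rate(scene_model(list(cube)), source_region(cube, sp2), c(1, 0, 0),
                  sampling_plan(300, seed = 8), buildup_none(),
                  dose_conversion_table(toy_groups()))
  fr2 <- nuclide_fractions(d2)
  expect_equal(unname(fr2["tA"]), 0.5, tolerance = 1e-12)

  # zero dose rate -> empty map
  z <- dose_rate(fix$scene,
                 source_region(kori_part_region(fix, "active"),
                               build_spectrum(inventory("a", "Co-60", 0))),
                 pt, sampling_plan(100, seed = 1))
  expect_length(nuclide_fractions(z), 0)

  # mismatched group structures are rejected
  h1 <- dose_conversion_table(toy_groups())
  expect_error(dose_rate(fix$scene, src, pt, sampling_plan(100, seed = 1),
                         buildup_model(), h1), "group structure")
})

test_that("exclusion radius protects the near-singular kernel", {
  spec <- toy_spectrum()
  cube <- region(shape_box(c(0, 0, 0), c(0.2, 0.2, 0.2)), "air")
  sc <- scene_model(list(cube))
  src <- source_region(cube, spec)
  inside_pt <- c(0.1, 0.1, 0.1)
  expect_error(group_flux(sc, src, inside_pt,
                          sampling_plan(100, seed = 1, exclusion_cm = 0)),
               "exclusion")
  f <- group_flux(sc, src, inside_pt,
                  sampling_plan(2000, seed = 1, exclusion_cm = 5))
  expect_true(is.finite(sum(f)))
  expect_gt(attr(f, "n_rejected"), 0)
})

test_that("MC standard error scales as 1/sqrt(Ns)", {
  tc <- make_toy_cases(seed = 1)
  cs <- tc$cylinder_quadrature
  h <- dose_conversion_table(toy_groups())
  se_at <- function(ns, seed)
    dose_rate(cs$scene, cs$source, cs$point,
              sampling_plan(ns, seed = seed), buildup_none(), h)$stderr
  seeds <- 11:16
  r <- vapply(seeds, function(s) se_at(1000, s) / se_at(9000, s), numeric(1))
  expect_equal(mean(r), 3, tolerance = 0.2)   # sqrt(9000/1000) = 3
})

test_that("dose maps are deterministic, symmetric and refinement-stable", {
  spec <- toy_spectrum(activity = 1e8)
  ball <- region(shape_sphere(c(0, 0, 0), 0.05), "air")
  sc <- scene_model(list(ball))
  src <- source_region(ball, spec)
  plan <- sampling_plan(400, seed = 21)
  h <- dose_conversion_table(toy_groups())

  g1 <- list(x = c(0.5, 1.0), y = 0, z = 0)
  m1 <- dose_map(sc, src, g1, plan, buildup_none(), h)
  # inverse-square falloff in a quasi-vacuum (air attenuation ~ e^-0.004)
  expect_equal(m1$dose_rate_msv_h[1] / m1$dose_rate_msv_h[2], 4,
               tolerance = 0.01)
  # refinement keeps shared nodes identical (position-keyed seeds)
  g2 <- list(x = c(0.5, 0.75, 1.0), y = 0, z = 0)
  m2 <- dose_map(sc, src, g2, plan, buildup_none(), h)
  expect_identical(m1$dose_rate_msv_h, m2$dose_rate_msv_h[c(1, 3)])
  # mirrored nodes get equal dose within MC error on a symmetric scene
  g3 <- list(x = c(-0.8, 0.8), y = 0, z = 0)
  m3 <- dose_map(sc, src, g3, plan, buildup_none(), h)
  expect_lt(abs(m3$dose_rate_msv_h[1] / m3$dose_rate_msv_h[2] - 1), 0.05)
})
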