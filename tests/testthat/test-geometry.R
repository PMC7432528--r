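test_that("material lookup respects priority, ambient and closed boundaries", {
  fix <- build_kori_fixture()
  sc <- fix$scene
  expect_equal(material_at(sc, c(10, 10, 5))$name, "air")
  # mid-thickness of the active shell at mid-height
  expect_equal(material_at(sc, c(2.2175, 0, 6.2))$name, "stainless_steel")
  # inside the vessel cavity is air
  expect_equal(material_at(sc, c(0, 0, 6.2))$name, "air")
  # a point exactly on the outer surface belongs to the shell region
  expect_equal(material_at(sc, c(2.35, 0, 6.2))$name, "stainless_steel")

  # equal-priority overlap is rejected at scene build time
  mats <- material_library()
  r1 <- region(shape_box(c(0, 0, 0), c(1, 1, 1)), "water", 1, "a")
  r2 <- region(shape_box(c(0.5, 0.5, 0.5), c(2, 2, 2)), "lead", 1, "b")
  expect_error(scene_model(list(r1, r2), materials = mats), "overlap")
  # different priorities resolve: higher wins
  r2b <- region(shape_box(c(0.5, 0.5, 0.5), c(2, 2, 2)), "lead", 2, "b")
  sc2 <- scene_model(list(r1, r2b), materials = mats)
  expect_equal(material_at(sc2, c(0.75, 0.75, 0.75))$name, "lead")
  expect_equal(material_at(sc2, c(0.25, 0.25, 0.25))$name, "water")
})

test_that("ray tracing yields exact chords, symmetric and length-consistent", {
  mats <- material_library()
  # ray entirely in air
  sc0 <- scene_model(list(), ambient = "air", materials = mats)
  pr <- trace_ray(sc0, c(0, 0, 0), c(1, 0, 0))
  expect_equal(nrow(pr$segments), 1L)
  expect_equal(pr$segments$length_cm, 100)

  # perpendicular crossing of a 26 cm slab
  slab <- region(shape_box(c(1, -1, -1), c(1.26, 1, 1)), "stainless_steel")
  sc1 <- scene_model(list(slab), materials = mats)
  pr1 <- trace_ray(sc1, c(0, 0, 0), c(2, 0, 0))
  expect_equal(pr1$segments$length_cm[pr1$segments$material == "stainless_steel"],
               26, tolerance = 1e-9)
  expect_equal(sum(pr1$segments$length_cm), 200, tolerance = 1e-9)

  # reversal gives the same multiset of (material, length)
  fix <- build_kori_fixture()
  a <- c(-3, 0.4, 6.0); b <- c(3, -0.2, 6.4)
  f <- trace_ray(fix$scene, a, b)
  r <- trace_ray(fix$scene, b, a)
  key <- function(p) {
    agg <- tapply(p$segments$length_cm, p$segments$material, sum)
    agg[order(names(agg))]
  }
  expect_equal(key(f), key(r), tolerance = 1e-9)

  # property: segment lengths sum to the Euclidean distance on random rays
  set.seed(101)
  for (i in 1:20) {
    a <- runif(3, -4, 4); b <- runif(3, -4, 4)
    if (sqrt(sum((a - b)^2)) < 0.1) next
    p <- trace_ray(fix$scene, a, b)
    expect_equal(sum(p$segments$length_cm), p$distance_cm, tolerance = 1e-9)
    expect_equal(p$distance_cm, sqrt(sum((a - b)^2)) * 100, tolerance = 1e-9)
  }
  expect_error(trace_ray(fix$scene, a, a), "zero-length")
})

test_that("analytic chords agree with fine-step ray marching", {
  fix <- build_kori_fixture()
  rays <- list(list(c(-3, 0, 6.2), c(3, 0.3, 6.2)),     # through both walls
               list(c(0, 0, 6.2), c(3, 0, 6.2)),        # cavity outwards
               list(c(-3, -1, -1.5), c(2, 1, 0.5)),     # through the cap shell
               list(c(2.2, 0, 2.0), c(2.7, 0.1, 10.0))) # oblique along shell
  for (ray in rays) {
    p <- trace_ray(fix$scene, ray[[1]], ray[[2]])
    exact <- tapply(p$segments$length_cm, p$segments$material, sum)
    march <- march_lengths(fix$scene, ray[[1]], ray[[2]], step_cm = 0.01)
    for (m in names(exact)) {
      expect_lt(abs(march[[m]] - exact[[m]]) / max(exact[[m]], 1), 1e-3)
    }
  }
})

test_that("optical depth interpolates, adds, and enforces table ranges", {
  mats <- material_library()
  steel <- mats$stainless_steel
  # slab one mean free path thick at 1.25 MeV, by construction
  t_cm <- 1 / mu_linear(steel, 1.25)
  slab <- region(shape_box(c(1, -1, -1), c(1 + t_cm / 100, 1, 1)),
                 "stainless_steel")
  sc <- scene_model(list(slab), ambient = "vacuum", materials = mats)
  p <- trace_ray(sc, c(0, 0, 0), c(2, 0, 0))
  expect_equal(optical_depth(p, 1.25), 1.0, tolerance = 1e-9)

  # two stacked slabs: depths add
  slab2 <- region(shape_box(c(1.5, -1, -1), c(1.5 + t_cm / 100, 1, 1)),
                  "stainless_steel", name = "s2")
  sc2 <- scene_model(list(slab, slab2), ambient = "vacuum", materials = mats)
  p2 <- trace_ray(sc2, c(0, 0, 0), c(2, 0, 0))
  expect_equal(optical_depth(p2, 1.25), 2.0, tolerance = 1e-9)

  # monotone in path length through a single material
  p3 <- trace_ray(sc, c(0, 0, 0), c(1.2, 0, 0))   # ends inside the slab
  expect_lt(optical_depth(p3, 1.25), optical_depth(p, 1.25) + 1e-12)

  # energy outside a material table errors with the material name
  lead <- region(shape_box(c(1, -1, -1), c(1.1, 1, 1)), "lead")
  scl <- scene_model(list(lead), ambient = "vacuum", materials = mats)
  pl <- trace_ray(scl, c(0, 0, 0), c(2, 0, 0))
  expect_error(optical_depth(pl, 0.02), "lead")
})

test_that("log-log attenuation interpolation hits tabulated points", {
  steel <- material_library()$stainless_steel
  expect_equal(mu_over_rho(steel, 1.25), 0.05350, tolerance = 1e-12)
  expect_equal(mu_over_rho(steel, c(0.5, 1.0)), c(0.08414, 0.05995),
               tolerance = 1e-12)
  expect_error(mu_over_rho(steel, 5), "range")
})

test_that("scene JSON round-trips", {
  fix <- build_kori_fixture()
  tmp <- tempfile(fileext = ".json")
  write_scene_json(fix$scene, tmp)
  back <- read_scene_json(tmp)
  expect_equal(length(back$regions), length(fix$scene$regions))
  for (i in seq_along(back$regions)) {
    expect_identical(back$regions[[i]]$material, fix$scene$regions[[i]]$material)
    expect_equal(back$regions[[i]]$shape, fix$scene$regions[[i]]$shape,
                 tolerance = 1e-12)
  }
})
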