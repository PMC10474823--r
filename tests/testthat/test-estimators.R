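test_that("named planform models fix their ellipse fraction", {
  expect_equal(planform_model("triangle")$f, 0)
  expect_equal(planform_model("ellipse")$f, 1)
  expect_equal(planform_model("ellipse-triangle")$f, 2 / 3)
  expect_equal(planform_model("ellipse_triangle")$name, "ellipse-triangle")
  expect_error(planform_model("mixture"), "requires an explicit")
  expect_error(planform_model("mixture", f = 1.2), "\\[0, 1\\]")
  expect_error(planform_model("ellipse", f = 0.5), "fixed")
  expect_true(planform_model("mixture", f = 0.4)$extension)
  expect_false(planform_model("mixture", f = 2 / 3)$extension)
})

test_that("hand-wing areas match the quadrature and shoelace oracles", {
  expect_equal(hand_wing_area("triangle", 10, 5), 50)
  # half-ellipse with semi-axes 10 and 2.5, both wings
  oracle <- 2 * half_ellipse_area_quadrature(10, 2.5)
  expect_equal(hand_wing_area("ellipse", 10, 5), oracle,
               tolerance = 1e-6)
  # ellipse-triangle = 2/3 ellipse + 1/3 triangle
  expect_equal(hand_wing_area("ellipse-triangle", 10, 5),
               (2 * oracle + 50) / 3, tolerance = 1e-6)
  # cross-check against the shoelace area of the composite hand polygon
  poly <- reference_planform_polygon(10, 5, 20, 2 / 3)  # box collapses
  expect_equal(hand_wing_area("ellipse-triangle", 10, 5),
               shoelace(poly$x, poly$y), tolerance = 1e-5)
  expect_error(hand_wing_area("ellipse", -1, 5), "invalid measurement")
  expect_error(hand_wing_area("ellipse", 10, 0), "invalid measurement")
})

test_that("medial box area is (WS - 2 WL) * S1 with a policy for violations", {
  expect_equal(medial_box_area(40, 10, 5), 100)
  expect_equal(medial_box_area(20, 10, 5), 0)
  expect_equal(medial_box_area(40.6, 10.3, 4.8), 96)
  expect_equal(medial_box_area(40.6, 10.3, 4.8),
               shoelace(c(0, 20, 20, 0), c(0, 0, 4.8, 4.8)))
  expect_error(medial_box_area(19, 10, 5), "geometry violation")
  expect_error(medial_box_area(19, 10, 5, specimen_id = "ROM1"), "ROM1")
  expect_equal(medial_box_area(19, 10, 5, policy = "clamp"), 0)
})

test_that("total wing area reproduces the three closed forms", {
  tri <- total_wing_area("triangle", WS = 40, WL = 10, S1 = 5)
  ell <- total_wing_area("ellipse", WS = 40, WL = 10, S1 = 5)
  et <- total_wing_area("ellipse-triangle", WS = 40, WL = 10, S1 = 5)
  expect_equal(tri$total_area, 150)
  expect_equal(tri$total_area, (40 - 10) * 5)  # algebraic simplification
  expect_equal(ell$total_area, pi / 2 * 50 + 100)
  expect_equal(et$total_area, (pi + 1) / 3 * 50 + 100)
  # components decompose exactly
  for (est in list(tri, ell, et)) {
    expect_equal(est$total_area, est$hand_area + est$box_area)
    expect_true(all(unlist(est) >= 0))
  }
  # full-planform shoelace oracle for each model
  for (f in c(0, 2 / 3, 1)) {
    poly <- reference_planform_polygon(10, 5, 40, f)
    expect_equal(total_wing_area("mixture", 40, 10, 5, f = f)$total_area,
                 shoelace(poly$x, poly$y), tolerance = 1e-5)
  }
})

test_that("mixture family reproduces the named models and stays ordered", {
  set.seed(11)
  for (i in 1:25) {
    WL <- runif(1, 2, 30); S1 <- runif(1, 1, 15)
    WS <- runif(1, 2 * WL, 6 * WL)
    expect_equal(hand_wing_area("mixture", WL, S1, f = 0),
                 hand_wing_area("triangle", WL, S1), tolerance = 1e-12)
    expect_equal(hand_wing_area("mixture", WL, S1, f = 1),
                 hand_wing_area("ellipse", WL, S1), tolerance = 1e-12)
    expect_equal(hand_wing_area("mixture", WL, S1, f = 2 / 3),
                 hand_wing_area("ellipse-triangle", WL, S1),
                 tolerance = 1e-12)
    a_tri <- total_wing_area("triangle", WS, WL, S1)$total_area
    a_et <- total_wing_area("ellipse-triangle", WS, WL, S1)$total_area
    a_ell <- total_wing_area("ellipse", WS, WL, S1)$total_area
    expect_true(a_tri < a_et && a_et < a_ell)
    # ellipse-triangle decomposition: (2 ellipse + triangle) / 3 hand
    expect_equal(a_et,
                 (2 * hand_wing_area("ellipse", WL, S1) +
                    hand_wing_area("triangle", WL, S1)) / 3 +
                   medial_box_area(WS, WL, S1))
  }
})

test_that("areas are scale-equivariant and aspect ratios scale-invariant", {
  set.seed(12)
  for (i in 1:10) {
    WL <- runif(1, 2, 30); S1 <- runif(1, 1, 15)
    WS <- runif(1, 2 * WL, 6 * WL); k <- runif(1, 0.2, 8)
    for (m in c("triangle", "ellipse", "ellipse-triangle")) {
      a1 <- total_wing_area(m, WS, WL, S1)$total_area
      a2 <- total_wing_area(m, k * WS, k * WL, k * S1)$total_area
      expect_equal(a2, k^2 * a1, tolerance = 1e-12)
      expect_equal(aspect_ratio(k * WS, a2), aspect_ratio(WS, a1),
                   tolerance = 1e-12)
    }
  }
})

test_that("aspect ratio is squared wingspan over area", {
  expect_equal(aspect_ratio(10, 25), 4)
  expect_equal(aspect_ratio(1, 1), 1)
  expect_equal(aspect_ratio(40, 178.5398), 1600 / 178.5398)
  expect_error(aspect_ratio(10, 0), "invalid area")
  expect_error(aspect_ratio(10, -3), "invalid area")
  expect_error(aspect_ratio(0, 5), "invalid")
})

test_that("estimate_wing_areas augments a table for every model", {
  tab <- data.frame(specimen_id = c("a", "b"), wingspan = c(40, 60),
                    wing_length = c(10, 20), s1 = c(5, 8))
  out <- estimate_wing_areas(tab)
  expect_equal(out$area_triangle, (tab$wingspan - tab$wing_length) * tab$s1)
  expect_equal(out$aspect_ratio_ellipse,
               tab$wingspan^2 / out$area_ellipse)
  expect_named(out, c(names(tab), "area_triangle", "aspect_ratio_triangle",
                      "area_ellipse", "aspect_ratio_ellipse",
                      "area_ellipse_triangle",
                      "aspect_ratio_ellipse_triangle"))
  expect_error(estimate_wing_areas(tab[, -2]), "missing required")
})
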