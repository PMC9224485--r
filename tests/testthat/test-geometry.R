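f118 <- library_filter("F118")
f63 <- library_filter("F63")
f1 <- library_filter("F1")
f9 <- library_filter("F9*")

test_that("thread counting matches the worked weave example", {
  n <- thread_counts(f118)
  expect_equal(n$n_x, 57.65, tolerance = 1e-3)
  expect_equal(n$n_y, 74.56, tolerance = 1e-3)
  nr <- thread_counts(f118, rounded = TRUE)
  expect_equal(nr$n_x, 58)
  expect_equal(nr$n_y, 74)
  expect_equal(nr$n_x + nr$n_y, 132)
  # counts vanish as the mesh opens up
  wide <- mesh_filter("wide", "HI", l_h = 100, d_f = 55e-6, thickness = 55e-6)
  nw <- thread_counts(wide)
  expect_lt(nw$n_x + nw$n_y, 1e-3)
})

test_that("mesh surface parameters reproduce all four filter values", {
  # printed values: 2.302, 3.313, 5.434, 6.176; agreement within 0.2%
  expect_equal(mesh_surface_parameter(f118), 2.302, tolerance = 2e-3)
  expect_equal(mesh_surface_parameter(f63), 3.313, tolerance = 2e-3)
  expect_equal(mesh_surface_parameter(f9), 5.434, tolerance = 2e-3)
  expect_equal(mesh_surface_parameter(f1), 6.176, tolerance = 2e-3)
})

test_that("Y is invariant to the reference area", {
  for (A_F in c(0.25e-4, 1e-4, 4e-4)) {
    expect_equal(mesh_surface_parameter(f118, A_F),
                 mesh_surface_parameter(f118), tolerance = 1e-12)
    expect_equal(brick_layer_surface_parameter(brick_geometry(), A_F),
                 brick_layer_surface_parameter(brick_geometry()),
                 tolerance = 1e-12)
  }
})

test_that("stack thickness and Y are additive and match the study table", {
  # (designation, L in 1e-5 m, Y) for all multi-layer configurations
  table1 <- list(
    list("F118+F63", 11.30, 5.62),
    list("F118+F63+F1", 16.23, 11.79),
    list("F1+F1", 9.86, 12.35),
    list("F1+F1+F1", 14.79, 18.53),
    list("F9*+F9*", 9.59, 10.87),
    list("F9*+F9*+F9*", 14.38, 16.30),
    list("F1+F9*+F1", 14.65, 17.79),
    list("F9*+F1+F9*", 14.52, 17.04))
  for (row in table1) {
    p <- stack_properties(build_stack(row[[1]]))
    expect_equal(p$L, row[[2]] * 1e-5, tolerance = 2e-3,
                 label = paste("L of", row[[1]]))
    expect_equal(p$Y, row[[3]], tolerance = 1e-3,
                 label = paste("Y of", row[[1]]))
  }
  # a single-layer stack is just the layer
  p1 <- stack_properties(filter_stack(f118))
  expect_equal(p1$L, f118$thickness)
  expect_equal(p1$Y, mesh_surface_parameter(f118))
  expect_error(filter_stack(), "at least one layer")
})

test_that("brick face area follows A_S = 2w^2 + 4w*x_k", {
  g <- brick_geometry()
  expect_equal(brick_total_area(g), 2590e-12)
  expect_equal(brick_total_area(brick_geometry(w = 10e-6, x_k = 2e-6)),
               280e-12)
  thin <- brick_geometry(x_k = 1e-12)
  expect_equal(brick_total_area(thin), 2 * thin$w^2, tolerance = 1e-5)
})

test_that("brick counts use the unrounded linear count", {
  g <- brick_geometry()
  expect_equal(sqrt(bricks_per_layer(g)), 285.31, tolerance = 1e-4)
  expect_equal(bricks_per_layer(g), 81400, tolerance = 1e-4)
  expect_equal(bricks_per_layer(g, A_F = 4e-4), 4 * bricks_per_layer(g))
})

test_that("brick-layer Y matches the stratum corneum value and scales correctly", {
  g <- brick_geometry()
  expect_equal(brick_layer_surface_parameter(g), 2.108, tolerance = 1e-3)
  # N-layer wall: additive
  expect_equal(5 * brick_layer_surface_parameter(g),
               brick_layer_surface_parameter(g) * 5)
  # direct-formula oracle under uniform length scaling; the count drops as
  # 1/lambda^2 while each brick's area grows as lambda^2, so Y is invariant
  for (lam in c(0.5, 2, 10)) {
    gs <- brick_geometry(w = g$w * lam, x_k = g$x_k * lam, x_c = g$x_c * lam)
    direct <- ((0.01 / (gs$w + gs$x_c))^2) *
      (2 * gs$w^2 + 4 * gs$w * gs$x_k) / 1e-4
    expect_equal(brick_layer_surface_parameter(gs), direct, tolerance = 1e-12)
    expect_equal(brick_layer_surface_parameter(gs),
                 brick_layer_surface_parameter(g), tolerance = 1e-12)
  }
})

test_that("the filter library loads and builds stacks by designation", {
  lib <- filter_library()
  expect_named(lib, c("label", "wettability", "mesh_size_um",
                      "thread_diameter_um", "thickness_um"))
  expect_equal(nrow(lib), 4)
  st <- build_stack("F118+F63+F1")
  expect_length(st$layers, 3)
  expect_error(build_stack("F999"), "not found")
})
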