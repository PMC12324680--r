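test_that("square packing of the reference winding gives 22 turns over 5 layers", {
  pair <- table1_pair()
  w <- pair$winding
  expect_equal(w$turns_per_layer, 22L) # floor(16 / 0.71)
  expect_equal(w$n_layers, 5L)
  loops <- discretize_winding(pair)
  expect_equal(nrow(loops), 192L) # turn count conserved, both coils
  # last layer is partial: 8 turns per winding at the outermost radius
  outer_radius <- 40e-3 + 4.5 * 0.71e-3
  expect_equal(sum(abs(loops$radius - outer_radius) < 1e-12), 16L)
})

test_that("a single-turn winding reduces to one loop at the wire centre", {
  w <- winding_spec(inner_radius = 10e-3, axial_width = 1e-3, n_turns = 1,
                    wire = wire_spec(1e-3))
  loops <- discretize_winding(coil_pair(w, spacing = 20e-3))
  expect_equal(nrow(loops), 2L)
  expect_equal(loops$radius, rep(10e-3 + 0.5e-3, 2))
  expect_equal(sort(loops$axial_offset), c(-10e-3, 10e-3))
})

test_that("the pair is mirror-symmetric with winding centroids at half the spacing", {
  loops <- discretize_winding(table1_pair())
  a_off <- loops$axial_offset[loops$coil == "A"]
  b_off <- loops$axial_offset[loops$coil == "B"]
  expect_equal(sort(b_off), sort(-a_off)) # exact mirror image
  # loop-mean offset sits within half a wire diameter of -spacing/2
  # (the partial layer shifts it slightly off the geometric centroid)
  expect_lt(abs(mean(a_off) - (-21.7e-3)), 0.5e-3)
})

test_that("all loops stay inside the physical winding envelope", {
  specs <- list(
    table1_pair(),
    coil_pair(winding_spec(25e-3, 10e-3, 37, wire_spec(0.9e-3)), 30e-3),
    coil_pair(winding_spec(60e-3, 5e-3, 12, wire_spec(1.2e-3)), 70e-3)
  )
  for (pair in specs) {
    w <- pair$winding
    loops <- discretize_winding(pair)
    expect_equal(nrow(loops), 2L * w$n_turns)
    expect_true(all(loops$radius >= w$inner_radius))
    expect_true(all(loops$radius <= w$inner_radius +
                      w$n_layers * w$wire$diameter))
    rel <- abs(abs(loops$axial_offset) - pair$spacing / 2)
    expect_true(all(rel <= w$axial_width / 2))
  }
})

test_that("unpackable geometries are rejected", {
  w <- winding_spec(10e-3, 1e-3, 500, wire_spec(1e-3)) # 500 layers of 1 turn
  expect_error(discretize_winding(coil_pair(w, 20e-3)), "max_layers")
  expect_error(winding_spec(axial_width = 0.1e-3), "wire diameter")
})

test_that("wire length sums loop circumferences", {
  # one loop of radius 1/(2 pi) has unit circumference
  t <- 1e-3
  w <- winding_spec(1 / (2 * pi) - t / 2, t, 1, wire_spec(t))
  expect_equal(wire_length(coil_pair(w, 0.1)), 2, tolerance = 1e-12) # 2 loops
  # reference pair, frozen from the layer-radius sum 2 pi sum(a_j)
  expect_equal(wire_length(table1_pair()), 50.146, tolerance = 1e-4)
  # strictly increasing in the number of turns at the same packing
  l1 <- wire_length(coil_pair(winding_spec(n_turns = 96), 43.4e-3))
  l2 <- wire_length(coil_pair(winding_spec(n_turns = 192), 43.4e-3))
  expect_gt(l2, l1)
  expect_equal(wire_length(table1_pair(), lead_length = 1),
               wire_length(table1_pair()) + 1)
})

test_that("geometric resistance follows rho L / A", {
  # hand case: 1 m of wire with a 1 mm^2 conductor cross-section
  d <- 2e-3 / sqrt(pi) # area exactly 1 mm^2
  t <- d
  w <- winding_spec(1 / (2 * pi) - t / 2, t, 1, wire_spec(t, d))
  pair <- coil_pair(w, 0.1)
  # the pair has two loops -> 2 m of wire
  expect_equal(resistance_from_geometry(pair), 2 * 1.68e-8 / 1e-6,
               tolerance = 1e-10)
  # linear in resistivity
  w2 <- winding_spec(1 / (2 * pi) - t / 2, t, 1, wire_spec(t, d, 3.36e-8))
  expect_equal(resistance_from_geometry(coil_pair(w2, 0.1)),
               2 * resistance_from_geometry(pair), tolerance = 1e-10)
})

test_that("predicted pair resistance brackets the measured 2.74 ohm", {
  # 22 AWG conductor (0.6438 mm) inside the 0.71 mm packing diameter
  r_pred <- resistance_from_geometry(table1_pair())
  expect_equal(r_pred, 2.588, tolerance = 1e-3) # frozen from rho L / A
  expect_lt(abs(r_pred - 2.74) / 2.74, 0.10)
})
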