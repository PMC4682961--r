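test_that("circular clump geometry: area, nesting, degenerate cases", {
  # R = 0 -> all-normal map
  expect_true(all(circular_clump(c(40, 40), R = 0) == "normal"))

  # marked-site count within 1% of pi (R/dx)^2 on the full-size domain
  ct <- circular_clump(c(448, 448), dx = 0.02, R = 2.4)
  expect_equal(sum(ct != "normal"), pi * 120^2, tolerance = 0.01)

  # monotone nesting in R
  m22 <- circular_clump(c(448, 448), R = 2.2) != "normal"
  m24 <- circular_clump(c(448, 448), R = 2.4) != "normal"
  expect_true(all(!m22 | m24))

  expect_error(circular_clump(c(50, 50), dx = 0.02, R = 2.4), "fit")
})

test_that("fibrosis mask honours the exact-count and seeding contracts", {
  region <- rep(c(TRUE, FALSE), c(1000, 500))
  expect_equal(sum(fibrosis_mask(region, 0, 1)), 0)
  m55 <- fibrosis_mask(region, 55, 1)
  expect_equal(sum(m55), 550)
  expect_true(all(which(m55) <= 1000))  # never outside the region

  m55b <- fibrosis_mask(region, 55, 2)
  expect_equal(sum(m55b), 550)
  expect_false(identical(m55, m55b))            # different seeds differ
  expect_identical(m55, fibrosis_mask(region, 55, 1))  # same seed repeats
  expect_error(fibrosis_mask(region, 100, 1), "100")
})

test_that("fibroblast attachment modes", {
  clump <- clump_mask <- circular_clump(c(100, 100), R = 0.8) != "normal"
  expect_null(fibroblast_attachment(clump, "none"))
  u <- fibroblast_attachment(clump, "uniform")
  expect_equal(sum(u$attach), sum(clump))
  expect_warning(fibroblast_attachment(clump, "uniform", p_a = 30),
                 "ignored")
  r <- fibroblast_attachment(clump, "random", p_a = 40, seed = 3)
  expect_equal(sum(r$attach), round(0.40 * sum(clump)))
  expect_true(all(clump[r$attach]))
  expect_error(fibroblast_attachment(clump, "random", p_a = 40), "seed")
})

test_that("cable patterns reproduce the stated counts and layout", {
  pa <- cable_pattern("A")
  expect_equal(length(pa$cell_type), 280)
  expect_equal(sum(pa$cell_type == "type-I"), 160)
  expect_null(pa$fibroblast)
  # the EAD segment is one contiguous block strictly inside the cable
  seg <- which(pa$cell_type == "type-I")
  expect_equal(seg, seq(min(seg), max(seg)))
  expect_true(min(seg) > 1 && max(seg) < 280)

  pb <- cable_pattern("B")
  expect_equal(sum(pb$fibroblast$attach), 160)
  expect_equal(which(pb$fibroblast$attach), seg)

  pc <- cable_pattern("C")
  att <- which(pc$fibroblast$attach)
  expect_equal(length(att), 40)
  expect_equal(att, seq(min(att), max(att)))      # contiguous
  expect_true(min(att) > min(seg) && max(att) < max(seg))  # strictly inside

  pd <- cable_pattern("D", p_a = 40, seed = 5)
  expect_equal(sum(pd$fibroblast$attach), round(0.4 * 160))
  expect_true(all(which(pd$fibroblast$attach) %in% seg))
  expect_identical(pd, cable_pattern("D", p_a = 40, seed = 5))
  expect_error(cable_pattern("D"), "seed")
  expect_error(cable_pattern("E"))
})

test_that("reduced-coupling field takes two values with the clump footprint", {
  f <- reduced_coupling_clump(c(200, 200), R = 1, d_ratio = 0.2)
  expect_setequal(unique(f), c(0.2, 1))
  inside <- eadclump:::clump_mask(c(200, 200), 0.02, 1)
  expect_true(all(f[inside] == 0.2) && all(f[!inside] == 1))
  expect_equal(unique(reduced_coupling_clump(c(50, 50), R = 0.3,
                                             d_ratio = 1)), 1)
  expect_error(reduced_coupling_clump(c(50, 50), R = 0.3, d_ratio = 1.2),
               "d_ratio")
})

test_that("build_scenario composes safely and reproducibly", {
  g <- build_scenario(nx = 120, ny = 60, R = 0.5, d_ratio = 0.7, p_f = 20,
                      attach_mode = "random", p_a = 40, seed = 9,
                      center = c(1.2, 0.6))
  # obstacle sites never carry fibroblasts
  expect_false(any(g$obstacle & g$fibroblast$attach))
  # obstacles only inside the clump
  inclump <- g$cell_type != "normal"
  expect_true(all(inclump[g$obstacle]))
  # same spec + seed -> identical grid
  g2 <- build_scenario(nx = 120, ny = 60, R = 0.5, d_ratio = 0.7, p_f = 20,
                       attach_mode = "random", p_a = 40, seed = 9,
                       center = c(1.2, 0.6))
  expect_identical(g[names(g) != "type_params"], g2[names(g2) != "type_params"])
  expect_equal(attr(g, "scenario")$seed, 9)
})
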