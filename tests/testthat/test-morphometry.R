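# Morphometry against closed-form annulus/ellipse oracles; tolerances are one
# pixel-equivalent (boundary pixelization scales with perimeter * pixel size).

px_area_tol <- function(R, pixel_size) 2 * pi * R * pixel_size / 1000

test_that("segmentation thresholds, keeps the largest component, errors on empty", {
  img <- section_image(matrix(700, 20, 20))
  expect_true(all(segment_cortex(img) == 1L))
  expect_error(segment_cortex(section_image(matrix(600, 20, 20))),
               "segmentation error")
  # annulus plus a small debris island: only the annulus survives
  gen <- gen_section_mask(R_o = 1.0, R_i = 0.6)
  truth <- attr(gen, "truth")
  d <- gen$density
  d[2, 2] <- 1200
  img2 <- section_image(d, gen$pixel_size)
  expect_identical(segment_cortex(img2), truth$mask)
})

test_that("areas match closed forms and are additive and scale-consistent", {
  gen <- gen_section_mask(R_o = 1.0, R_i = 0.6)
  truth <- attr(gen, "truth")
  mask <- segment_cortex(gen)
  ar <- section_areas(mask, gen$pixel_size)
  tol <- px_area_tol(1.0, gen$pixel_size)
  expect_equal(ar$Tt.Ar, truth$Tt.Ar, tolerance = tol / truth$Tt.Ar)
  expect_equal(ar$Ct.Ar, truth$Ct.Ar, tolerance = tol / truth$Ct.Ar)
  expect_equal(ar$Es.Ar, truth$Es.Ar, tolerance = tol / truth$Es.Ar)
  expect_identical(ar$Tt.Ar, ar$Ct.Ar + ar$Es.Ar)   # additive by construction
  ar2 <- section_areas(mask, 2 * gen$pixel_size)
  expect_equal(ar2$Tt.Ar, 4 * ar$Tt.Ar)
  # solid disc has no endosteal area
  disc <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  disc <- matrix(as.integer(disc > 0), nrow(mask), ncol(mask))
  expect_equal(section_areas(disc, gen$pixel_size)$Es.Ar, 0)
})

test_that("cortical thickness recovers planted walls within a pixel", {
  px <- 12
  gen <- gen_section_mask(R_o = 1.0, R_i = 0.6, pixel_size = px)
  mask <- segment_cortex(gen)
  expect_equal(cortical_thickness(mask, px), 0.4, tolerance = px / 1000 / 0.4)
  expect_equal(cortical_thickness(mask, px, method = "rays"), 0.4,
               tolerance = px / 1000 / 0.4)
  # constant-wall elliptical annulus
  gen2 <- gen_section_mask(R_o = 1.0, R_i = 0.6, ellipticity = 1.3,
                           wall = "offset", pixel_size = px)
  mask2 <- segment_cortex(gen2)
  expect_equal(cortical_thickness(mask2, px), 0.4, tolerance = px / 1000 / 0.4)
  # thicker wall measures thicker
  gen3 <- gen_section_mask(R_o = 1.0, R_i = 0.5, pixel_size = px)
  expect_gt(cortical_thickness(segment_cortex(gen3), px),
            cortical_thickness(mask, px))
})

test_that("principal moments match closed forms and are rotation invariant", {
  gen <- gen_section_mask(R_o = 1.0, R_i = 0.6)
  truth <- attr(gen, "truth")
  mask <- segment_cortex(gen)
  mom <- principal_moments(mask, gen$pixel_size)
  expect_equal(mom$I_min, truth$I_min, tolerance = 0.01)
  expect_equal(mom$I_max, truth$I_max, tolerance = 0.01)
  expect_equal(mom$I_min, mom$I_max, tolerance = 0.01)  # circular symmetry

  ell <- gen_section_mask(R_o = 1.0, R_i = 0.6, ellipticity = 1.4)
  tr_e <- attr(ell, "truth")
  m_e <- segment_cortex(ell)
  mom_e <- principal_moments(m_e, ell$pixel_size)
  expect_lt(mom_e$I_min, mom_e$I_max)
  expect_equal(mom_e$I_min, tr_e$I_min, tolerance = 0.01)
  expect_equal(mom_e$I_max, tr_e$I_max, tolerance = 0.01)
  # principal axes align with the ellipse axes (here the grid axes)
  expect_lt(min(abs(sin(mom_e$angle)), abs(cos(mom_e$angle))), 0.05)

  # 90-degree rotation leaves principal values unchanged
  mom_r <- principal_moments(t(m_e), ell$pixel_size)
  expect_equal(mom_r$I_min, mom_e$I_min, tolerance = 1e-9)
  expect_equal(mom_r$I_max, mom_e$I_max, tolerance = 1e-9)

  # translation invariance: pad asymmetrically
  padded <- rbind(cbind(matrix(0L, nrow(m_e), 7), m_e),
                  matrix(0L, 9, ncol(m_e) + 7))
  mom_t <- principal_moments(padded, ell$pixel_size)
  expect_equal(mom_t$I_min, mom_e$I_min, tolerance = 1e-9)
  expect_equal(mom_t$I_max, mom_e$I_max, tolerance = 1e-9)
})

test_that("tissue mineral density averages calibrated densities over the mask", {
  g <- matrix(1100, 10, 10)
  img <- section_image(g)
  mask <- matrix(1L, 10, 10)
  expect_identical(tissue_mineral_density(img, mask), 1100)
  g2 <- matrix(c(1000, 1200), 10, 10)
  expect_equal(tissue_mineral_density(section_image(g2), mask), 1100)
  gen <- gen_section_mask(R_o = 1.0, R_i = 0.6, density = 1150, noise_sd = 30,
                          seed = 11)
  truth <- attr(gen, "truth")
  n_bone <- sum(truth$mask)
  tmd <- tissue_mineral_density(gen, truth$mask)
  expect_equal(tmd, 1150, tolerance = 4 * 30 / sqrt(n_bone) / 1150)
})

test_that("annulus fit recovers radii and rejects non-annular masks", {
  px <- 12
  gen <- gen_section_mask(R_o = 1.0, R_i = 0.6, pixel_size = px)
  mask <- segment_cortex(gen)
  fit <- fit_annulus(mask, px)
  half_px <- 0.5 * px / 1000
  expect_equal(fit$R_o, 1.0, tolerance = half_px / 1.0)
  expect_equal(fit$R_i, 0.6, tolerance = half_px / 0.6)
  # mildly eccentric ellipse: mean radius between semi-axes
  ell <- gen_section_mask(R_o = 1.0, R_i = 0.7, ellipticity = 1.2,
                          pixel_size = px)
  f_e <- fit_annulus(segment_cortex(ell), px)
  q <- sqrt(1.2)
  expect_true(f_e$R_o > 1.0 / q && f_e$R_o < 1.0 * q)
  # solid disc is not an annulus
  disc <- matrix(as.integer(
    EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask))) > 0),
    nrow(mask), ncol(mask))
  expect_error(fit_annulus(disc, px), "topology error")
  expect_error(cortical_thickness(disc, px), "topology error")
  # two endosteal cavities are not an annulus either
  twohole <- disc
  twohole[60:66, 60:66] <- 0L
  twohole[90:96, 90:96] <- 0L
  expect_error(fit_annulus(twohole, px), "topology error")
})

test_that("section_morphology assembles a consistent metrics row", {
  gen <- gen_section_mask(R_o = 1.0, R_i = 0.6, density = 1200)
  row <- section_morphology(gen)
  truth <- attr(gen, "truth")
  expect_equal(row$Tt.Ar, row$Ct.Ar + row$Es.Ar)
  expect_equal(row$TMD, 1200)
  expect_equal(row$Ct.Th, truth$Ct.Th, tolerance = 0.03)
  expect_true(row$I_min <= row$I_max)
})
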