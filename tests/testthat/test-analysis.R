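# Profile, partition and dissociation-constant analyses on synthetic
# configurations with known structure.

test_that("uniform configurations give a flat profile", {
  # ideal beads uniform over the whole box (slab = full box width)
  tr <- generate_fixture("ideal_slab", box = c(40, 10, 10), n = 8000,
                         slab_halfwidth = 20, nframes = 60, seed = 2)
  prof <- density_profile(tr, recenter = FALSE, symmetrize = FALSE,
                          check_clusters = FALSE)
  expect_lt(max(prof$phi_polymer) / min(prof$phi_polymer), 1.1)
})

test_that("binned volume fractions conserve the bead count", {
  tr <- generate_fixture("hs_gas", box = c(40, 10, 10), radius = 0.4,
                         phi = 0.03, nframes = 5, seed = 7)
  nb <- nrow(tr$frames[[1]])
  prof <- density_profile(tr, recenter = FALSE, symmetrize = FALSE,
                          check_clusters = FALSE)
  vbin <- attr(prof, "bin_width") * 10 * 10
  vbead <- 4 / 3 * pi * 0.4^3
  expect_equal(sum(prof$phi_polymer) * vbin / vbead, nb, tolerance = 1e-9)
})

test_that("a synthetic slab is recentred onto the central bins", {
  tr <- generate_fixture("ideal_slab", box = c(50, 10, 10), n = 400,
                         slab_halfwidth = 5, nframes = 3, seed = 3)
  prof <- density_profile(tr, check_clusters = FALSE)
  bw <- attr(prof, "bin_width")
  outside <- abs(prof$x) > 5 + bw
  expect_true(all(prof$phi_polymer[outside] == 0))
  expect_gt(sum(prof$phi_polymer[!outside]), 0)
})

test_that("symmetrization is idempotent", {
  tr <- generate_fixture("ideal_slab", box = c(50, 10, 10), n = 300,
                         slab_halfwidth = 8, seed = 9)
  prof <- density_profile(tr, check_clusters = FALSE, symmetrize = TRUE)
  again <- (prof$phi_polymer + rev(prof$phi_polymer)) / 2
  expect_equal(again, prof$phi_polymer, tolerance = 1e-12)
})

test_that("measured partition coefficient is the region ratio", {
  prof <- data.frame(x = seq(-49, 49, by = 2),
                     phi_polymer = 0.07, phi_particle = 0.001)
  prof$phi_particle[abs(prof$x) < 10] <- 0.014
  class(prof) <- c("profile_table", "data.frame")
  pm <- partition_coefficient_measured(prof, phase_regions(10, 40))
  expect_equal(pm$P, 14)
  expect_equal(pm$deltaF, -log(14))
  # equal phases: P = 1, deltaF = 0
  prof$phi_particle <- 0.01
  pm <- partition_coefficient_measured(prof)
  expect_equal(pm$P, 1)
  expect_equal(pm$deltaF, 0)
  # empty dilute phase: explicit lower bound, not a silent number
  prof$phi_particle <- ifelse(abs(prof$x) < 10, 0.01, 0)
  expect_warning(pm <- partition_coefficient_measured(prof), "lower bound")
  expect_true(pm$lower_bound)
  expect_error(partition_coefficient_measured(prof, phase_regions(1, 400)),
               "no bins")
})

test_that("dissociation constant from a hand-built configuration", {
  # 3 stickers and 2 clients in the dense slab |x| < 5 of a 20 nm box;
  # exactly one sticker within binding range of a client
  box <- c(20, 20, 20)
  pos <- rbind(
    c(10, 10, 10),       # sticker, bound (client 1 at distance 1.0)
    c(12, 14, 10),       # sticker, free
    c(8, 6, 10),         # sticker, free
    c(10, 11, 10),       # client 1
    c(13, 6, 14))        # client 2
  tr <- structure(list(
    frames = list(pos), images = NULL, steps = 1L,
    type = c(1L, 1L, 1L, 4L, 4L),
    mol = c(1L, 1L, 1L, 2L, 3L),
    is_polymer = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    box = box, radius_by_type = c(0.3, 0.3, 0.3, 1.5),
    virtual_by_type = c(TRUE, TRUE, FALSE, FALSE),
    dt = NA_real_, record_every = NA_integer_, temperature = 300,
    client_R = 1.5, client_ra = 0.3), class = "cg_trajectory")
  reg <- phase_regions(5, 8)
  kd <- measure_KD(tr, reg, binding_range = 1.8)
  V <- 2 * 5 * 20 * 20
  expect_equal(kd$rho_client, 2 / V)
  expect_equal(kd$rho, 3 / V)
  expect_equal(kd$rho_bound, 1 / V)
  expect_equal(kd$KD, (2 / V) * (2 / V) / (1 / V))
  # no clients at all is an error, not a zero
  tr2 <- tr
  tr2$type <- c(1L, 1L, 1L, 3L, 3L)
  expect_error(measure_KD(tr2, reg), "client")
})

test_that("region constructors validate and rescale", {
  expect_error(phase_regions(10, 5), "dense")
  r <- scale_to_box(phase_regions(10, 40), Lx = 60)
  expect_equal(r$dense, 6)
  expect_equal(r$dilute, 24)
})
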