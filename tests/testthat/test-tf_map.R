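test_that("Morlet CWT is linear and localizes tones to the right row", {
  cfg <- cwt_config()
  freqs <- cfg$freqs
  x <- sin(2 * pi * 15 * (0:999) / 250)
  co <- morlet_cwt(x, 250, cfg)
  expect_equal(dim(co), c(64L, 1000L))

  expect_equal(morlet_cwt(x * 0, 250, cfg), co * 0)
  expect_equal(Mod(morlet_cwt(-2.5 * x, 250, cfg)), 2.5 * Mod(co),
               tolerance = 1e-12)

  for (f0 in c(10, 15, 20, 25)) {
    xf <- sin(2 * pi * f0 * (0:999) / 250)
    peak <- which.max(rowMeans(Mod(morlet_cwt(xf, 250, cfg))))
    expect_lte(abs(freqs[peak] - f0), diff(freqs)[1] + 1e-9)
  }

  expect_error(morlet_cwt(x, 250, cwt_config(freqs = c(10, 200))),
               "Nyquist|fs/2")
})

test_that("CWT rows agree with a direct-convolution oracle", {
  set.seed(4)
  x <- rnorm(400)
  cfg <- cwt_config(freqs = c(12, 20))
  co <- morlet_cwt(x, 250, cfg)
  for (fi in 1:2) {
    w <- mifusion:::morlet_wavelet(cfg$freqs[fi], 250, cfg$omega0)
    half <- (length(w) - 1L) %/% 2L
    n <- length(x)
    xp <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
    direct <- vapply(seq_len(n), function(t)
      sum(xp[t:(t + 2L * half)] * rev(w)), complex(1))
    expect_lt(max(Mod(direct - co[fi, ])), 1e-8)
  }
})

test_that("scalogram time-binning partitions samples evenly", {
  co <- matrix(complex(real = 1, imaginary = 0), 4, 1000)
  sc <- scalogram(co, 64L)
  expect_equal(dim(sc), c(4L, 64L))
  expect_true(all(abs(sc - 1) < 1e-12))  # constant magnitude preserved

  # partition oracle: lengths differ by <= 1 and cover every sample
  bounds <- round(1000 * (0:64) / 64)
  lens <- diff(bounds)
  expect_true(all(lens %in% c(15L, 16L)))
  expect_equal(sum(lens), 1000L)

  expect_equal(scalogram(co, 1000L), Mod(co))
  expect_error(scalogram(co[, 1:10], 64L), "exceeds")
})

test_that("rendering normalizes, resizes and colormaps correctly", {
  cfg <- cwt_config()
  z <- matrix(0, 64, 64)
  img <- render_image(list(z), cfg)
  lut0 <- jet_colormap(256L)[1, ]
  expect_true(all(abs(sweep(img$pixels, 3, lut0)) < 1e-12))

  # mean idempotence: two identical maps render as one
  set.seed(2)
  m1 <- matrix(abs(rnorm(64 * 64)), 64, 64)
  expect_equal(render_image(list(m1, m1), cfg)$pixels,
               render_image(list(m1), cfg)$pixels)

  # hot cell stays within one pixel after resizing 32x32 -> 64x64
  hot <- matrix(0, 32, 32)
  hot[10, 20] <- 1
  px <- render_image(list(hot), cfg)$pixels
  heat <- px[, , 1] + px[, , 2] - px[, , 3]  # red/yellow = hot for jet
  idx <- which(heat == max(heat), arr.ind = TRUE)[1, ]
  expect_lte(abs(idx[1] - 19.5), 1.5)
  expect_lte(abs(idx[2] - 39.5), 1.5)

  expect_error(render_image(list(), cfg), "empty")
  expect_true(all(px >= 0 & px <= 1))
})

test_that("trial_to_image composes the branch pipeline deterministically", {
  e <- make_synth(n_trials = 6L, seed = 3L)
  mods <- fit_csp_ovr(e)
  tr <- trial_matrix(e, 1L)
  i1 <- trial_to_image(tr, mods, e$fs)
  i2 <- trial_to_image(tr, mods, e$fs)
  expect_identical(i1$pixels, i2$pixels)
  expect_equal(dim(i1$pixels), c(64L, 64L, 3L))
  expect_true(all(i1$pixels >= 0 & i1$pixels <= 1))

  e3 <- make_synth(n_classes = 3L, n_trials = 4L, seed = 3L)
  mods3 <- fit_csp_ovr(e3)
  # ovr_planes mode accepts exactly three models
  cfg3 <- cwt_config(image_mode = "ovr_planes")
  i3 <- trial_to_image(trial_matrix(e3, 1L), mods3, e3$fs, config = cfg3)
  expect_equal(dim(i3$pixels), c(64L, 64L, 3L))
  expect_error(trial_to_image(trial_matrix(e, 1L), mods, e$fs,
                              config = cfg3), "3 one-vs-rest")

  imgs <- epochs_to_images(e, mods)
  expect_equal(dim(imgs), c(64L, 64L, 3L, 12L))
})

test_that("a burst in the second second concentrates energy in the right bins", {
  x <- numeric(1000)
  idx <- 251:500  # 1..2 s at 250 Hz
  x[idx] <- sin(2 * pi * 15 * (idx - 1) / 250)
  sc <- scalogram(morlet_cwt(x, 250, cwt_config()), 64L)
  energy <- colSums(sc^2)
  expect_gte(sum(energy[17:32]) / sum(energy), 0.6)
})

test_that("images survive the text PPM round trip", {
  e <- make_synth(n_trials = 4L, seed = 8L)
  mods <- fit_csp_ovr(e)
  img <- trial_to_image(trial_matrix(e, 1L), mods, e$fs)
  path <- tempfile(fileext = ".ppm")
  write_image_ppm(img, path)
  lines <- readLines(path)
  expect_equal(lines[1], "P3")
  expect_equal(lines[2], "64 64")
  vals <- as.integer(strsplit(paste(lines[-(1:3)], collapse = " "),
                              " +")[[1]])
  expect_equal(length(vals), 64 * 64 * 3)
  expect_true(all(vals >= 0 & vals <= 255))
})
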