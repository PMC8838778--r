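test_that("band features match brute-force loops over the definitions", {
  set.seed(20)
  fs <- 1000; n <- 64
  cfg <- cwd_config(frame_len = n)
  fr <- rnorm(n)
  tfd <- choi_williams(fr, cfg, fs)
  pD <- joint_density(tfd)
  edges <- cbind(c(0, 100, 250, 300, 350, 400, 450),
                 c(100, 250, 300, 350, 400, 450, 500))
  for (b in seq_len(nrow(edges))) {
    band <- edges[b, ]
    be <- band_energy(pD, tfd$freqs, band)
    bb <- brute_band_energy(pD, tfd$freqs, band)
    expect_equal(be$mean, bb$mean, tolerance = 1e-10)
    expect_equal(be$E, bb$E, tolerance = 1e-10)
    expect_equal(as.numeric(band_freq_peak(pD, tfd$freqs, band)),
                 brute_band_freq_peak(pD, tfd$freqs, band),
                 tolerance = 1e-8)
    expect_equal(as.numeric(band_freq_mean(pD, tfd$freqs, band)),
                 brute_band_freq_mean(pD, tfd$freqs, band),
                 tolerance = 1e-8)
    expect_equal(band_spectral_info(tfd$mfN, tfd$freqs, band),
                 brute_band_spectral_info(tfd$mfN, tfd$freqs, band),
                 tolerance = 1e-10)
  }
  # and the internal fast path agrees with the generic operations
  bands <- band_set(fs, edges = edges)
  ff <- exhalr:::frame_tf_features(tfd, bands, cfg$eps)
  for (b in 1:7) {
    expect_equal(unname(ff[paste0("e_bn", b)]),
                 brute_band_energy(pD, tfd$freqs, edges[b, ])$mean,
                 tolerance = 1e-10)
    expect_equal(unname(ff[paste0("f_cres", b)]),
                 brute_band_freq_peak(pD, tfd$freqs, edges[b, ]),
                 tolerance = 1e-8)
    expect_equal(unname(ff[paste0("f_med", b)]),
                 brute_band_freq_mean(pD, tfd$freqs, edges[b, ]),
                 tolerance = 1e-8)
    expect_equal(unname(ff[paste0("ie_bn", b)]),
                 brute_band_spectral_info(tfd$mfN, tfd$freqs, edges[b, ]),
                 tolerance = 1e-10)
  }
})

test_that("band energies partition the distribution and localise tones", {
  fs <- 44100; n <- 1024
  tone <- sin(2 * pi * 2000 * (0:(n - 1)) / fs)
  tfd <- choi_williams(tone, cwd_config(), fs)
  pD <- joint_density(tfd)
  bands <- band_set(fs)
  means <- vapply(1:7, function(b)
    band_energy(pD, tfd$freqs, bands[b, ])$mean, 0)
  # bands partition the axis: the per-time means sum to 1/n_t
  expect_equal(sum(means) * ncol(pD), 1, tolerance = 1e-9)
  # a 2 kHz tone puts the most energy in band 6 (1500-3000 Hz)
  expect_equal(which.max(means), 6L)
  # its in-band peak and mean frequency sit at the tone within a bin
  bin <- fs / (2 * n)
  expect_equal(as.numeric(band_freq_peak(pD, tfd$freqs, bands[6, ])),
               2000, tolerance = bin + 1e-9)
  expect_equal(as.numeric(band_freq_mean(pD, tfd$freqs, bands[6, ])),
               2000, tolerance = 2 * bin + 1e-9)
  expect_error(band_energy(pD, tfd$freqs, c(30000, 40000)), "outside")
})

test_that("uniform and degenerate densities give closed-form features", {
  # uniform density over a band: mean frequency = band midpoint
  nf <- 512; nt <- 64
  freqs <- seq(0, 1000, length.out = nf + 1)[1:nf]
  mfN <- numeric(nf)
  inb <- freqs >= 200 & freqs < 400
  mfN[inb] <- 1 / sum(inb)
  mtN <- rep(1 / nt, nt)
  pD <- outer(mfN, mtN)
  fm <- as.numeric(band_freq_mean(pD, freqs, c(200, 400)))
  bin <- 1000 / nf
  expect_equal(fm, 300, tolerance = bin / 2 + 1e-9)
  # uniform spectral information: -log2(1/256) = 8 bits
  mf2 <- rep(1 / 256, 256)
  f2 <- seq_len(256)
  expect_equal(band_spectral_info(mf2, f2, c(1, 257)), 8)
  # a delta distribution floors empty bins at -log2(eps) = 30 bits
  mf3 <- c(1, rep(0, 255))
  expect_equal(band_spectral_info(mf3, f2, c(2, 257)), 30)
})

test_that("entropies follow the closed forms and the additive identity", {
  e <- entropies(rep(1 / 1024, 1024), rep(1 / 512, 512))
  expect_equal(unname(e), c(10, 9, 19))
  d <- entropies(c(1, numeric(99)), c(1, numeric(49)))
  expect_equal(unname(d), c(0, 0, 0))
  set.seed(21)
  p <- runif(100); p <- p / sum(p)
  q <- runif(50); q <- q / sum(q)
  ee <- entropies(p, q)
  expect_identical(unname(ee["h_tf"]), unname(ee["h_t"] + ee["h_f"]))
  expect_error(entropies(p * 2, q), "sum to 1")
})

test_that("kurtosis recovers uniform, Gaussian and two-point values", {
  n <- 1024
  tms <- seq(0, 1, length.out = n)
  expect_equal(tf_kurtosis(rep(1 / n, n), tms), 1.8, tolerance = 0.01)
  g <- dnorm(tms, 0.5, 0.05); g <- g / sum(g)
  expect_equal(tf_kurtosis(g, tms), 3.0, tolerance = 0.05)
  two <- numeric(n); two[c(200, 800)] <- 0.5
  expect_equal(tf_kurtosis(two, tms), 1.0, tolerance = 1e-9)
  one <- numeric(n); one[5] <- 1
  expect_error(tf_kurtosis(one, tms), "variance")
})

test_that("joint moments factorise on separable input and match sums", {
  nt <- 1024; nf <- 1024
  mtN <- rep(1 / nt, nt); mfN <- rep(1 / nf, nf)
  sep <- outer(mfN, mtN)
  m <- joint_moments(sep, mtN, mfN)
  # discrete-sum oracle for the uniform marginal moment
  um <- function(k, n) sum((seq_len(n) / n)^k) / n
  expect_equal(unname(m["momm11"]), um(1, nt) * um(1, nf))
  expect_equal(unname(m["momm77"]), um(7, nt) * um(7, nf))
  expect_equal(unname(m["momm15"]), um(15, nt) * um(15, nf))
  # which converge to the continuum 1/(n+1) per axis
  expect_equal(unname(m["momm11"]), 1 / 4, tolerance = 4e-3)
  expect_equal(unname(m["momm77"]), 1 / 64, tolerance = 1e-2)
  expect_equal(unname(m["momm15"]), 1 / 256, tolerance = 2e-2)
  # separable matrix: momC = momM exactly (up to summation order)
  expect_equal(unname(m["momc11"]), unname(m["momm11"]), tolerance = 1e-12)
  expect_equal(unname(m["momc77"]), unname(m["momm77"]), tolerance = 1e-12)
  expect_equal(unname(m["momc15"]), unname(m["momm15"]), tolerance = 1e-12)
  # all mass at the last (time, frequency) cell: every moment is 1
  d1 <- numeric(8); d1[8] <- 1
  md <- joint_moments(outer(d1, d1), d1, d1)
  expect_equal(unname(md), rep(1, 6))
})

test_that("extraction yields 38 named features with the stated structure", {
  sig <- synth_blow(blow_params("cold", "healthy", duration = 2, seed = 31))
  tf <- extract_tf_features(sig)
  expect_length(tf, 38)
  expect_identical(names(tf), tf_feature_names())
  band_feats <- grep("^(e_bn|f_cres|f_med|ie_bn)[1-7]$", names(tf))
  expect_length(band_feats, 28)
  expect_identical(unname(tf["h_tf"]), unname(tf["h_t"] + tf["h_f"]))
  # scale invariance: all densities are normalised
  tf2 <- extract_tf_features(audio_signal(sig$samples * 5.3,
                                          sig$sample_rate))
  expect_equal(tf, tf2, tolerance = 1e-9)
  expect_error(extract_tf_features(audio_signal(rnorm(100), 44100)),
               "shorter")
})

test_that("cold and hot blows order bands 6 and 3 oppositely", {
  for (seed in c(101, 102, 103)) {
    cold <- extract_tf_features(
      synth_blow(blow_params("cold", "healthy", duration = 2, seed = seed)))
    hot <- extract_tf_features(
      synth_blow(blow_params("hot", "healthy", duration = 2, seed = seed)))
    expect_gt(cold["e_bn6"], cold["e_bn3"])
    expect_gt(hot["e_bn3"], hot["e_bn6"])
  }
})
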