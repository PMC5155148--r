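test_that("window extraction is shape-, weight- and order-faithful", {
  st <- random_window_stack(7, 49, seed = 1)
  M <- extract_window_matrix(st, c(3, 3), 7)
  expect_equal(dim(M), c(49L, 49L))
  # constant frame gives a constant column
  st2 <- image_stack(array(rep(c(2, 5, 9), each = 25), c(5, 5, 3)), 65)
  M2 <- extract_window_matrix(st2, c(2, 2), 5)
  expect_equal(M2[, 2], rep(5, 25))
  # permuting the frame order permutes columns identically
  perm <- c(3, 1, 2)
  M3 <- extract_window_matrix(st2, c(2, 2), 5, frame_range = perm)
  expect_equal(M3, M2[, perm])
  # taper weights multiply rows
  w <- seq(0.5, 2, length.out = 25)
  M4 <- extract_window_matrix(st2, c(2, 2), 5, weights = w)
  expect_equal(M4, M2 * w)
  expect_error(extract_window_matrix(st, c(0, 3), 7), "outside")
  expect_error(extract_window_matrix(st, c(3, 3), 7, frame_range = integer(0)),
               "empty")
})

test_that("eigenimage decompositions reconstruct the data and obey the rank bound", {
  set.seed(10)
  for (i in 1:10) {
    N <- 10; K <- sample(c(4, 10, 25), 1)
    M <- matrix(rnorm(N * K), N, K)
    dec <- compute_eigenimages(M)
    expect_true(all(diff(dec$singular_values) <= 1e-12))
    expect_lte(sum(dec$singular_values > 1e-10 * dec$singular_values[1]), min(N, K))
    # orthonormal eigenimages
    G <- crossprod(dec$eigenimages)
    expect_lt(max(abs(G - diag(ncol(dec$eigenimages)))), 1e-8)
    # U S V' reproduces the matrix
    rec <- dec$eigenimages %*%
      (dec$singular_values[seq_len(ncol(dec$eigenimages))] * t(dec$right_vectors))
    expect_lt(norm(rec - M, "F") / norm(M, "F"), 1e-10)
    # singular values^2 equal the eigenvalues of G G^T from an independent
    # dense eigensolver
    ev <- eigen(tcrossprod(M), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(dec$singular_values[seq_len(min(N, K))]^2,
                 pmax(ev[seq_len(min(N, K))], 0), tolerance = 1e-8)
  }
})

test_that("K identical frames give exactly one eigenimage proportional to the frame", {
  frame <- rgamma(25, 2, 1)
  M <- matrix(frame, 25, 12)
  dec <- compute_eigenimages(M)
  expect_equal(sum(dec$singular_values > 1e-10 * dec$singular_values[1]), 1L)
  u1 <- dec$eigenimages[, 1]
  expect_equal(abs(cor(u1, frame)), 1, tolerance = 1e-12)
})

test_that("subspace splitting follows the sigma0 threshold semantics", {
  M <- matrix(rnorm(25 * 40), 25, 40)
  dec <- compute_eigenimages(M)
  all_sig <- split_subspaces(dec, sigma0_absolute(0))
  expect_equal(all_sig$signal_indices, 1:25)
  expect_length(all_sig$null_indices, 0)
  none_sig <- split_subspaces(dec, sigma0_absolute(2 * dec$singular_values[1]))
  expect_length(none_sig$signal_indices, 0)
  rel <- split_subspaces(dec, sigma0_relative(0.5))
  expect_equal(rel$sigma0, 0.5 * dec$singular_values[1])
  expect_true(all(dec$singular_values[rel$signal_indices] >= rel$sigma0))
  expect_true(all(dec$singular_values[rel$null_indices] < rel$sigma0))
  # noise-free single blinking emitter after mean removal: signal dimension 1
  sc <- single_emitter_scene(background = 0)
  sim <- simulate_stack(sc, 40, noise = "none", seed = 2)
  M2 <- extract_window_matrix(sim$stack, c(6, 6), 7)
  dec2 <- split_subspaces(compute_eigenimages(M2), sigma0_relative(0.5))
  expect_length(dec2$signal_indices, 1)
})

test_that("PSF projections satisfy the Pythagorean identity and the eigenimage limit", {
  set.seed(3)
  M <- matrix(rgamma(49 * 80, 2, 1), 49, 80)
  dec <- split_subspaces(compute_eigenimages(M), sigma0_relative(0.1))
  a <- sample_psf_vector(test_psf(), c(3.27, 2.81), window_pixels(c(3, 3), 7))
  pr <- project_psf(dec, a)
  expect_equal(pr$d_PR^2 + pr$d_PN^2, 1, tolerance = 1e-9)
  # steering equal to a signal eigenimage
  pr2 <- project_psf(dec, dec$eigenimages[, 1])
  expect_equal(pr2$d_PR, 1, tolerance = 1e-9)
  expect_equal(pr2$d_PN, 0, tolerance = 1e-9)
  expect_error(project_psf(dec, a[1:10]), "length")
})

test_that("at a true emitter of a noise-free window the steering vector lies in the range", {
  # no background: the window matrix is exactly rank 1 (the PSF pattern)
  sc <- single_emitter_scene(background = 0)
  sim <- simulate_stack(sc, 60, noise = "none", seed = 4)
  M <- extract_window_matrix(sim$stack, c(6, 6), 7)
  dec <- split_subspaces(compute_eigenimages(M), sigma0_relative(0.01))
  a <- sample_psf_vector(sc$psf, c(6, 6), window_pixels(c(6, 6), 7))
  pr <- project_psf(dec, a)
  expect_lt(pr$d_PN, 1e-6)
})

test_that("the indicator is the alpha-power of the projection ratio", {
  expect_equal(indicator(list(d_PR = 0.4, d_PN = 0.4), alpha = 3), 1)
  expect_equal(indicator(list(d_PR = 0.8, d_PN = 0.4), alpha = 2), 4)
  expect_equal(indicator(list(d_PR = 0.123, d_PN = 0.5), alpha = 1,
                         traditional = TRUE), 2)
  # eps floor guards exact-null points
  expect_true(is.finite(indicator(list(d_PR = 1, d_PN = 0), alpha = 4)))
  expect_error(indicator(list(d_PR = 1, d_PN = 1), alpha = 0), "alpha")
})

test_that("a window-sized image reduces to the single-window MUSIC image (stitching identity)", {
  st <- random_window_stack(5, 40, seed = 6)
  psf <- test_psf()
  map <- run_musical(st, psf, N_w = 5, alpha = 2, subpixel = 3,
                     sigma0 = sigma0_relative(0.1))
  expect_equal(map$params$windows_used, 1L)
  oracle <- oracle_window_indicator(extract_window_matrix(st, c(2, 2), 5),
                                    psf, 5, 3, alpha = 2, tau = 0.1)
  expect_equal(map$values, oracle, tolerance = 1e-8)
})

test_that("an all-zero stack yields a degenerate but finite map without crashing", {
  st <- image_stack(array(0, c(9, 9, 10)), 65)
  map <- suppressWarnings(run_musical(st, test_psf(), N_w = 7, subpixel = 2))
  expect_true(all(map$values == 0))
  expect_equal(map$params$windows_all_zero, 9L)
})

test_that("the map is invariant to frame permutation and to intensity rescaling", {
  sc <- make_pair_scene(130, test_psf(), c(11, 11), p_on = 0.5, background = 10)
  sim <- simulate_stack(sc, 60, seed = 8)
  psf <- test_psf()
  m1 <- run_musical(sim$stack, psf, N_w = 7, subpixel = 4)
  perm <- sample(60)
  m2 <- run_musical(sim$stack, psf, N_w = 7, subpixel = 4, frame_range = perm)
  expect_equal(m2$values, m1$values, tolerance = 1e-8)
  st3 <- image_stack(sim$stack$data * 7.3, 65)
  m3 <- run_musical(st3, psf, N_w = 7, subpixel = 4)
  expect_equal(m3$values, m1$values, tolerance = 1e-8)
})

test_that("fewer frames than window pixels triggers the minimum-frames warning", {
  st <- random_window_stack(7, 20, seed = 12)
  w <- capture_warnings(run_musical(st, test_psf(), N_w = 7, subpixel = 2))
  expect_match(w, "K >= N is desirable", all = FALSE)
  st2 <- random_window_stack(7, 49, seed = 12)
  expect_no_warning(run_musical(st2, test_psf(), N_w = 7, subpixel = 2))
  expect_error(run_musical(random_window_stack(5, 10, seed = 1), test_psf(),
                           N_w = 7, subpixel = 2), "smaller than the window")
})

test_that("peak sharpness is non-increasing in alpha on a clean single emitter", {
  sc <- single_emitter_scene(shape = c(13L, 13L), background = 5)
  sim <- simulate_stack(sc, 60, noise = "none", seed = 13)
  widths <- sapply(c(1, 2, 4, 8), function(a) {
    m <- run_musical(sim$stack, sc$psf, N_w = 7, alpha = a, subpixel = 10)
    pr <- sample_line_profile(m, c(6, 3.2), c(6, 8.8), 301)
    measure_fwhm(pr)$fwhm
  })
  expect_true(all(diff(widths) <= 1e-9))
})

test_that("indicator peaks at emitters dominate empty regions by orders of magnitude", {
  sc <- make_pair_scene(2 * 65, test_psf(), c(17, 17), p_on = 0.5, background = 5)
  sim <- simulate_stack(sc, 80, noise = "none", seed = 14)
  m <- run_musical(sim$stack, sc$psf, N_w = 7, alpha = 4, subpixel = 10)
  at_emitter <- sapply(1:2, function(j) {
    g <- round((unlist(sc$emitters[j, c("row", "col")]) + 0.5) * 10 - 0.5)
    m$values[g[1] + 1, g[2] + 1]
  })
  # far corner region, > 2 PSF FWHM from both emitters
  far <- max(m$values[1:20, 1:20])
  expect_gt(min(at_emitter) / max(far, .Machine$double.xmin), 1e3)
})

test_that("a pair at half the diffraction FWHM is merged in the mean image but split by MUSICAL", {
  psf <- test_psf(593)
  sep <- 0.5 * psf_fwhm(psf)     # ~102 nm, ~1.6 pixels
  sc <- make_pair_scene(sep, psf, c(15, 15), brightness = 2000, p_on = 0.5,
                        background = 10)
  sim <- simulate_stack(sc, 4 * 49, noise = "poisson", seed = 15)
  mu <- mean_image(sim$stack)
  r <- sc$emitters$row[1]
  # mean image along the joining line: a single interior maximum
  mu_line <- mu[r + 1, 4:12]
  expect_length(musical:::local_maxima(mu_line), 1L)
  m <- run_musical(sim$stack, psf, N_w = 7, alpha = 4, subpixel = 10)
  pr <- sample_line_profile(m, c(r, sc$emitters$col[1] - 1.5),
                            c(r, sc$emitters$col[2] + 1.5), 241)
  ct <- two_peak_contrast(pr)
  expect_true(attr(ct, "resolved"))
  expect_gt(as.numeric(ct), 0)
})

test_that("threshold_map floors values below the fractional percentile cut", {
  base <- structure(list(values = matrix(1:100, 10, 10), pixel_size = 6.5,
                         subpixel = 10, params = list()),
                    class = "indicator_map")
  th <- threshold_map(base, fraction = 0.5, percentile = 100)
  expect_equal(sum(th$values > 0), 51)         # 50..100 survive
  expect_true(all(th$values[th$values > 0] >= 50))
  unchanged <- threshold_map(base, fraction = 0)
  expect_equal(unchanged$values, base$values)
  const <- base; const$values[] <- 3
  expect_equal(threshold_map(const, 0.4, 99.9)$values, const$values)
})

test_that("sigma0 rule spellings parse consistently", {
  expect_equal(parse_sigma0("rel:0.05")$tau, 0.05)
  expect_equal(parse_sigma0("abs:12.5")$value, 12.5)
  expect_equal(parse_sigma0(3)$type, "absolute")
  expect_error(parse_sigma0("bogus"), "sigma0")
  expect_error(sigma0_relative(1.5), "tau")
})
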