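gauss_chrom <- function(rts, areas, t_max = 50, dt = 0.02, sd = 0.12) {
  time <- seq(0, t_max, by = dt)
  signal <- rep(0, length(time))
  for (i in seq_along(rts))
    signal <- signal + areas[i] * dnorm(time, rts[i], sd)
  tibble::tibble(time = time, signal = signal)
}

test_that("peak detection integrates isolated Gaussians to 2%", {
  ch <- gauss_chrom(20, 5)
  pk <- detect_peaks(ch$time, ch$signal, min_height = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$area, 5, tolerance = 0.02 * 5)
  expect_equal(pk$rt, 20, tolerance = 0.03)
  expect_true(pk$left < pk$rt && pk$rt < pk$right)
  # flat signal -> empty table
  flat <- detect_peaks(ch$time, rep(1, length(ch$time)), min_height = 0.1)
  expect_equal(nrow(flat), 0)
  # two resolved Gaussians -> two peaks at their times
  ch2 <- gauss_chrom(c(10, 30), c(4, 6))
  pk2 <- detect_peaks(ch2$time, ch2$signal, min_height = 1)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$rt, c(10, 30), tolerance = 0.03)
})

test_that("retention-time correction undoes a uniform shift", {
  tpl <- tibble::tibble(rt = c(5, 25, 45), area = c(3, 5, 4))
  ref <- tibble::tibble(sample_id = "ref", rt = tpl$rt, area = tpl$area)
  shifted <- tibble::tibble(sample_id = "sh", rt = tpl$rt + 0.2, area = tpl$area)
  corr <- rt_correct(dplyr::bind_rows(ref, shifted), anchors = c(5, 25, 45))
  sh <- corr[corr$sample_id == "sh", ]
  expect_lt(max(abs(sh$rt - tpl$rt)), 0.02)
  # a sample already on the anchors is unchanged
  rf <- corr[corr$sample_id == "ref", ]
  expect_equal(rf$rt, tpl$rt, tolerance = 1e-12)
  # warp is monotone on random jitter
  set.seed(41)
  jit <- tibble::tibble(sample_id = "j",
                        rt = sort(seq(2, 48, length.out = 15) + rnorm(15, 0, 0.05)),
                        area = runif(15, 1, 5))
  cj <- rt_correct(jit, anchors = c(5, 25, 45))
  expect_true(all(diff(cj$rt[order(cj$rt_raw)]) > 0))
  # fewer than two matched anchors: left uncorrected with a warning
  lone <- tibble::tibble(sample_id = "x", rt = 10, area = 1)
  expect_warning(un <- rt_correct(lone, anchors = c(10, 40)), "uncorrected")
  expect_equal(un$rt, 10)
})

test_that("common peaks require presence in every sample", {
  full <- tibble::tibble(
    sample_id = rep(c("A", "B", "C"), each = 3),
    rt = rep(c(5, 15, 25), 3) + rep(c(0, 0.02, -0.02), each = 3),
    area = runif(9, 1, 3))
  m <- match_common_peaks(full, rt_window = 0.3)
  expect_equal(ncol(m$areas), 3)
  expect_true(all(m$areas > 0))
  expect_equal(m$consensus_rt, sort(m$consensus_rt))
  # dropping one sample's middle peak removes that column
  partial <- full[-5, ]
  m2 <- match_common_peaks(partial, rt_window = 0.3)
  expect_equal(ncol(m2$areas), 2)
  expect_false(any(abs(m2$consensus_rt - 15) < 1))
  # zero common peaks is an error advising a larger window
  far <- tibble::tibble(sample_id = c("A", "B"), rt = c(5, 30), area = c(1, 1))
  expect_error(match_common_peaks(far, rt_window = 0.1), "larger rt_window")
})

test_that("jittered synthetic chromatograms recover the 20 template peaks", {
  hits <- 0
  for (s in 1:10) {
    ch <- gen_chromatograms(4, synthetic_truth(), rt_jitter_sd = 0.05,
                            baseline_noise_sd = 0.05, seed = s)
    pk <- detect_peaks_all(ch, min_height = 2)
    pkc <- rt_correct(pk, anchors = c(5.4, 24.3, 47.3), window = 0.4)
    m <- try(match_common_peaks(pkc, rt_window = 0.3), silent = TRUE)
    if (!inherits(m, "try-error") && ncol(m$areas) == 20) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the reference vector is a column median robust to one outlier", {
  A <- matrix(rep(c(2, 4, 6, 8), each = 5), 5)
  colnames(A) <- paste0("P", 1:4)
  m <- structure(list(areas = A, consensus_rt = 1:4,
                      samples = paste0("S", 1:5)),
                 class = "common_peak_matrix")
  expect_equal(unname(reference_vector(m)), c(2, 4, 6, 8))
  A2 <- A; A2[3, ] <- A[3, ] * 50
  m2 <- m; m2$areas <- A2
  expect_equal(unname(reference_vector(m2, "median")), c(2, 4, 6, 8))
  expect_false(all(reference_vector(m2, "mean") == c(2, 4, 6, 8)))
})

test_that("cosine similarity matches its closed forms", {
  expect_equal(cosine_similarity(c(3, 1, 4), c(3, 1, 4)), 1, tolerance = 1e-9)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0, 1), c(1, 1, 0)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("similarity matrices are symmetric, unit-diagonal, scale-invariant", {
  set.seed(42)
  A <- matrix(runif(5 * 8, 1, 10), 5,
              dimnames = list(paste0("S", 1:5), paste0("P", 1:8)))
  m <- structure(list(areas = A, consensus_rt = 1:8,
                      samples = rownames(A)),
                 class = "common_peak_matrix")
  S <- similarity_matrix(m)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 6), tolerance = 1e-9)
  # double-loop oracle
  vecs <- rbind(A, R = apply(A, 2, median))
  for (i in 1:6) for (j in 1:6)
    expect_equal(S[i, j], cosine_similarity(vecs[i, ], vecs[j, ]))
  # scaling one sample's areas leaves its similarities unchanged
  m3 <- m; m3$areas[2, ] <- 3 * m3$areas[2, ]
  S3 <- similarity_matrix(m3)
  expect_equal(S3[2, 1], S[2, 1], tolerance = 1e-12)
  # duplicated rows are perfectly similar
  m4 <- m; m4$areas[3, ] <- m4$areas[1, ]
  expect_equal(similarity_matrix(m4)[1, 3], 1, tolerance = 1e-12)
})

test_that("noiseless identical samples give an all-ones similarity matrix", {
  tpl <- tibble::tibble(rt = c(8, 20, 35), area = c(4, 7, 3), cv = c(0, 0, 0))
  ch <- gen_chromatograms(3, synthetic_truth(peak_templates = tpl),
                          rt_jitter_sd = 0, baseline_noise_sd = 0, seed = 1)
  pk <- detect_peaks_all(ch, min_height = 1)
  m <- match_common_peaks(pk, rt_window = 0.3)
  S <- similarity_matrix(m)
  expect_equal(unname(S), matrix(1, 4, 4), tolerance = 1e-9)
})

test_that("PCA selection resolves block-correlated peaks and obeys the trace identity", {
  set.seed(43)
  n <- 60
  b1 <- rnorm(n)
  b2 <- residuals(lm(rnorm(n) ~ b1))   # exactly uncorrelated with b1 in sample
  A <- cbind(b1, b1 * 2, b1 * 0.5, b2, b2 * 3, b2 * 0.1) + 100
  colnames(A) <- paste0("P", 1:6)
  m <- structure(list(areas = A, consensus_rt = 1:6,
                      samples = paste0("S", 1:n)),
                 class = "common_peak_matrix")
  ps <- pca_select_peaks(m)
  expect_equal(ps$eigenvalues[1:2], c(3, 3), tolerance = 1e-6)
  expect_equal(ps$n_retained, 2)
  expect_setequal(ps$selected_peaks, paste0("P", 1:6))
  expect_equal(sum(ps$eigenvalues), 6, tolerance = 1e-6)
  # independent noise: eigenvalues near 1, none dominant
  set.seed(44)
  A2 <- matrix(rnorm(500 * 4), 500) + 50
  colnames(A2) <- paste0("P", 1:4)
  m2 <- structure(list(areas = A2, consensus_rt = 1:4,
                       samples = paste0("S", 1:500)),
                  class = "common_peak_matrix")
  ps2 <- pca_select_peaks(m2)
  expect_true(all(abs(ps2$eigenvalues - 1) < 0.25))
  # loadings reproduce the correlation matrix when all components kept
  ps_all <- pca_select_peaks(m, eig_min = 0)
  L <- ps_all$loadings
  expect_equal(L %*% t(L), cor(A), tolerance = 1e-8, ignore_attr = TRUE)
})
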