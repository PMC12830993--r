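test_that("Mahalanobis distance matches hand-computed cases", {
  expect_equal(mahalanobis_distance(c(3, 4), c(3, 4), diag(2)), 0)
  # 1-D: |x - mu| / sigma
  expect_equal(mahalanobis_distance(8, 0, matrix(4)), 4.0)
  # 2-D with diagonal covariance, explicit inverse by hand
  expect_equal(
    mahalanobis_distance(c(2, 1), c(0, 0), matrix(c(2, 0, 0, 0.5), 2)),
    2.0)
  expect_error(mahalanobis_distance(c(1, 1), c(0, 0),
                                    matrix(c(1, 1, 1, 1), 2)),
               "singular|positive definite")
})

test_that("Mahalanobis distance agrees with brute-force inversion", {
  # independent oracle: explicit solve() of the covariance
  brute <- function(x, mu, sigma) sqrt(drop(t(x - mu) %*% solve(sigma) %*% (x - mu)))
  set.seed(4242)
  for (i in 1:100) {
    d <- sample(1:5, 1)
    a <- matrix(rnorm(d * d), d)
    sigma <- crossprod(a) + diag(d) * 0.5
    mu <- rnorm(d)
    x <- rnorm(d, sd = 3)
    expect_equal(mahalanobis_distance(x, mu, sigma), brute(x, mu, sigma),
                 tolerance = 1e-10)
  }
})

test_that("fitting two separable classes classifies all training events", {
  co <- tiny_cohort()
  res <- classify_events(co$model, co$bm)
  truth <- co$bm$events$class
  classified <- res$outcome == "classified"
  expect_equal(sum(classified & res$label != truth), 0)
  expect_gt(mean(classified), 0.95)
})

test_that("the fit is invariant to exact duplication of every row", {
  co <- tiny_cohort()
  x <- co$bm$values
  lab <- co$bm$events$class
  m1 <- fit_rejection_lda(x, lab)
  m2 <- fit_rejection_lda(rbind(x, x), c(lab, lab))
  expect_equal(m1$n_components, m2$n_components)
  s1 <- predict(m1, x)
  s2 <- predict(m2, x)
  # LDA axis signs are arbitrary; compare distances, which are sign-free
  expect_equal(s2$dist_lymphoma, s1$dist_lymphoma, tolerance = 0.05)
  expect_equal(s2$dist_pdx, s1$dist_pdx, tolerance = 0.05)
  expect_identical(s1$label, s2$label)
})

test_that("the component cap is honoured and capped at feasible rank", {
  co <- tiny_cohort()
  m <- fit_rejection_lda(co$bm$values, co$bm$events$class,
                         variance_fraction = 0.999, component_cap = 5)
  expect_lte(m$n_components, 5)
  m2 <- fit_rejection_lda(co$bm$values, co$bm$events$class,
                          variance_fraction = 1, component_cap = 10000)
  expect_lte(m2$n_components, nrow(co$bm$values) - 2)
})

test_that("degenerate label inputs are rejected", {
  co <- tiny_cohort()
  expect_error(fit_rejection_lda(co$bm$values,
                                 rep("lymphoma", nrow(co$bm$values))),
               "two classes")
  expect_error(classify_events(co$model, matrix(0, 2, 10)), "features")
})

test_that("classification rejects beyond the SD threshold and emits softmax probabilities", {
  co <- tiny_cohort()
  res <- classify_events(co$model, co$bm)
  classified <- res[res$outcome == "classified", ]
  expect_true(all(abs(classified$prob_lymphoma + classified$prob_pdx - 1)
                  < 1e-12))
  expect_true(all(classified$probability >= 0.5))
  expect_true(all(pmin(classified$dist_lymphoma, classified$dist_pdx)
                  <= co$model$sd_threshold))
  rejected <- res[res$outcome == "unclassifiable", ]
  expect_true(all(pmin(rejected$dist_lymphoma, rejected$dist_pdx)
                  > co$model$sd_threshold))

  # winning label is the argmin-distance class
  expect_identical(classified$label,
                   ifelse(classified$dist_lymphoma <= classified$dist_pdx,
                          "lymphoma", "pdx"))
})

test_that("feature vectors far from both centres are always unclassifiable", {
  co <- tiny_cohort()
  # scramble the spectral bins: a physically implausible spectrum
  far <- co$bm$values[1:5, , drop = FALSE]
  far <- far[, c(4501:9000, 1:4500), drop = FALSE]
  colnames(far) <- colnames(co$bm$values)
  res <- classify_events(co$model, far)
  expect_true(all(pmin(res$dist_lymphoma, res$dist_pdx) > 4))
  expect_true(all(res$outcome == "unclassifiable"))
})

test_that("the projection pipeline is affine (PCA reconstruction is a fixed point)", {
  co <- tiny_cohort()
  m <- co$model
  x <- co$bm$values[1:8, , drop = FALSE]
  scores <- sweep(x, 2, m$center) %*% m$rotation
  recon <- sweep(scores %*% t(m$rotation), 2, m$center, `+`)
  r1 <- classify_events(m, x)
  r2 <- classify_events(m, recon)
  expect_equal(r2$ld1, r1$ld1, tolerance = 1e-9)
})

test_that("an equidistant point within threshold splits probability and takes the first class", {
  co <- tiny_cohort()
  m <- co$model
  # construct a score exactly midway in Mahalanobis terms along the axis
  mu1 <- m$class_means$lymphoma; s1 <- sqrt(m$class_cov$lymphoma[1, 1])
  mu2 <- m$class_means$pdx; s2 <- sqrt(m$class_cov$pdx[1, 1])
  t_mid <- (mu1 * s2 + mu2 * s1) / (s1 + s2)   # |t-mu1|/s1 == |t-mu2|/s2
  dists <- c(abs(t_mid - mu1) / s1, abs(t_mid - mu2) / s2)
  expect_equal(dists[1], dists[2], tolerance = 1e-10)
  expect_equal(unname(which.min(dists)), 1L)  # tie: first declared class
  # equal distances give exactly split softmax probabilities
  p <- exp(-dists^2 / 2) / sum(exp(-dists^2 / 2))
  expect_equal(unname(p), c(0.5, 0.5))
})

test_that("lowering the SD threshold never decreases rejections", {
  co <- tiny_cohort()
  grid <- c(6, 4, 3, 2, 1, 0.5, 0.25)
  counts <- vapply(grid, function(thr)
    sum(classify_events(co$model, co$bm, sd_threshold = thr)$outcome ==
          "unclassifiable"), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("specimen calls use majority vote with tie flagged indeterminate", {
  mk <- function(labels) tibble::tibble(
    event_id = sprintf("e%d", seq_along(labels)),
    outcome = ifelse(is.na(labels), "unclassifiable", "classified"),
    label = labels)
  spec <- function(n) tibble::tibble(event_id = sprintf("e%d", 1:n),
                                     specimen_id = "S1")
  r <- classify_specimens(mk(rep("lymphoma", 10)), spec(10))
  expect_equal(r$call, "lymphoma"); expect_equal(r$concordance, 1.0)

  r <- classify_specimens(mk(c(rep("pdx", 9), "lymphoma")), spec(10))
  expect_equal(r$call, "pdx"); expect_equal(r$concordance, 0.9)

  r <- classify_specimens(mk(c(rep("pdx", 4), rep("lymphoma", 4))), spec(8))
  expect_equal(r$call, "indeterminate"); expect_equal(r$concordance, 0.5)

  r <- classify_specimens(mk(rep(NA_character_, 3)), spec(3))
  expect_equal(r$call, "indeterminate"); expect_true(is.na(r$concordance))
})

test_that("tidy and glance summarise the fitted model", {
  co <- tiny_cohort()
  td <- tidy(co$model)
  expect_equal(nrow(td), 2)
  expect_true(all(td$sd > 0))
  gl <- glance(co$model)
  expect_equal(gl$n_train, nrow(co$bm$values))
  expect_gte(gl$variance_captured, 0.95)
})

test_that("model archives round-trip through disk", {
  co <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(co$model, path)
  m2 <- read_model(path)
  expect_identical(predict(m2, co$bm$values[1:3, ]),
                   predict(co$model, co$bm$values[1:3, ]))
})
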