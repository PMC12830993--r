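test_that("the accounting helpers implement the two-denominator convention", {
  a <- accuracy_pair(correct = 90, misclassified = 10, unclassifiable = 20)
  expect_equal(a$classifiable, 100)
  expect_equal(a$total, 120)
  expect_equal(a$acc_classifiable, 90)
  expect_equal(a$acc_all, 75)
  expect_true(is.na(accuracy_pair(0, 0, 5)$acc_classifiable))

  r <- binary_rates(tp = 8, fn = 2, fp = 1, tn = 9)
  expect_equal(r$sensitivity, 80)
  expect_equal(r$specificity, 90)

  d <- duty_cycle(attempts = 200, unclassifiable = 30, bad = 10)
  expect_equal(d$classifiable, 160)
  expect_equal(d$duty_cycle, 80)
})

test_that("fold plans are specimen-grouped, stratified and reproducible", {
  co <- tiny_cohort()
  plan <- make_folds(co$specimens, k = 3, seed = 8)
  expect_identical(plan, make_folds(co$specimens, k = 3, seed = 8))
  # every specimen in exactly one fold
  expect_equal(sort(plan$specimen_id), sort(co$specimens$specimen_id))
  # each class appears in every fold when counts permit
  tab <- table(plan$class, plan$fold)
  expect_true(all(tab > 0))
  # k = number of specimens gives leave-one-specimen-out
  loso <- make_folds(co$specimens, k = nrow(co$specimens), seed = 1)
  expect_equal(sort(unique(loso$fold)), seq_len(nrow(co$specimens)))
  expect_error(make_folds(co$specimens[1:3, ], k = 5), "Fewer specimens")
})

test_that("no fold plan ever leaks a specimen between train and test", {
  co <- tiny_cohort()
  ev <- co$bm$events
  for (s in 1:50) {
    plan <- make_folds(co$specimens, k = sample(2:5, 1), seed = s)
    joined <- dplyr::left_join(ev, plan, by = c("specimen_id", "class"))
    for (f in unique(plan$fold)) {
      expect_length(intersect(joined$specimen_id[joined$fold == f],
                              joined$specimen_id[joined$fold != f]), 0)
    }
  }
})

test_that("cross-validation accounting is conserved per fold and overall", {
  co <- tiny_cohort()
  folds <- make_folds(co$specimens, k = 4, seed = 2)
  cv <- cross_validate(co$bm, folds)
  with(cv$per_fold, {
    expect_equal(correct + misclassified + unclassifiable, total)
    expect_equal(correct + misclassified, classifiable)
  })
  expect_equal(sum(cv$per_fold$total), nrow(co$bm$values))
  expect_equal(cv$totals$correct + cv$totals$misclassified +
                 cv$totals$unclassifiable, cv$totals$total)
  # confusion margins equal class totals
  margins <- rowSums(as.matrix(cv$confusion[, -1]))
  expect_equal(unname(margins),
               unname(as.vector(table(co$bm$events$class)[cv$confusion$truth])))
  # separable synthetic cohort: nothing misclassified
  expect_equal(cv$totals$misclassified, 0)
  expect_equal(cv$accuracy_per_classifiable, 100)
})

test_that("duplicating a specimen's events changes counts but not accuracy", {
  co <- tiny_cohort()
  bm <- co$bm
  dup_spec <- co$specimens$specimen_id[1]
  idx <- which(bm$events$specimen_id == dup_spec)
  bm2 <- bm
  bm2$values <- rbind(bm$values, bm$values[idx, , drop = FALSE])
  extra <- bm$events[idx, ] %>%
    dplyr::mutate(event_id = paste0(event_id, "_dup"))
  bm2$events <- dplyr::bind_rows(bm$events, extra)
  rownames(bm2$values) <- bm2$events$event_id
  folds <- make_folds(co$specimens, k = 4, seed = 2)
  cv <- cross_validate(co$bm, folds)
  cv2 <- cross_validate(bm2, folds)
  expect_equal(cv2$totals$total, cv$totals$total + length(idx))
  # grouping shields accuracy: still perfectly classified
  expect_equal(cv2$totals$misclassified, 0)
  expect_equal(cv2$accuracy_per_classifiable, 100)
})

test_that("specimen permutation builds balanced pseudo-groups reproducibly", {
  specs <- tibble::tibble(
    specimen_id = sprintf("S%03d", 1:110),
    class = rep(c("lymphoma", "pdx"), c(20, 90)))
  perm <- permute_specimen_labels(specs, seed = 4)
  expect_identical(perm, permute_specimen_labels(specs, seed = 4))
  expect_equal(as.integer(table(perm$perm_class)), c(55L, 55L))
  # each pseudo-group mixes both true classes
  mix <- table(perm$perm_class, perm$class)
  expect_true(all(mix > 0))
  expect_error(permute_specimen_labels(specs[1:3, ], seed = 1),
               "at least 4")
  # relabelling preserves the event count
  co <- tiny_cohort()
  bmp <- apply_permutation(co$bm,
                           permute_specimen_labels(co$specimens, seed = 4))
  expect_equal(nrow(bmp$events), nrow(co$bm$events))
  expect_true(all(c("class", "true_class") %in% names(bmp$events)))
})

test_that("SMOTE balances the minority class and never touches test folds", {
  set.seed(99)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(10, 5), 5))
  labels <- rep(c("a", "b"), c(20, 5))
  aug <- smote_augment(x, labels, k_neighbours = 3)
  expect_equal(as.integer(table(aug$labels)), c(20L, 20L))
  # synthetic points interpolate within the minority cloud
  syn <- aug$x[-(1:25), , drop = FALSE]
  expect_true(all(syn >= min(x[21:25, ]) - 1e-9 &
                    syn <= max(x[21:25, ]) + 1e-9))
  expect_warning(smote_augment(x, labels, k_neighbours = 10), "reducing")

  co <- tiny_cohort()
  folds <- make_folds(co$specimens, k = 3, seed = 6)
  plain <- cross_validate(co$bm, folds)
  smoted <- smote_cross_validate(co$bm, folds, seed = 1)
  # identical test composition fold by fold
  expect_identical(
    smoted$results %>% dplyr::arrange(event_id) %>%
      dplyr::select(event_id, fold),
    plain$results %>% dplyr::arrange(event_id) %>%
      dplyr::select(event_id, fold))
  # on an easily separated cohort the report is materially unchanged
  expect_equal(smoted$accuracy_per_classifiable,
               plain$accuracy_per_classifiable, tolerance = 1)
})

test_that("ROC analysis matches enumeration and the Mann-Whitney identity", {
  d <- tibble::tibble(prob_lymphoma = c(0.1, 0.4, 0.6, 0.9),
                      truth = c("pdx", "pdx", "lymphoma", "lymphoma"))
  r <- roc_curve(d)
  expect_equal(r$auc, 1.0)

  # perfectly separated scores
  d2 <- tibble::tibble(prob_lymphoma = c(rnorm(50, 0), rnorm(50, 10)),
                       truth = rep(c("pdx", "lymphoma"), each = 50))
  expect_equal(roc_curve(d2)$auc, 1.0)

  # chance-level scores
  set.seed(12)
  d3 <- tibble::tibble(prob_lymphoma = runif(2000),
                       truth = sample(c("pdx", "lymphoma"), 2000, TRUE))
  expect_lt(abs(roc_curve(d3)$auc - 0.5), 0.05)

  # oracle identity: AUC == U / (n1 * n2)
  set.seed(13)
  d4 <- tibble::tibble(prob_lymphoma = rnorm(60, rep(c(0, 1), each = 30)),
                       truth = rep(c("pdx", "lymphoma"), each = 30))
  u <- stats::wilcox.test(prob_lymphoma ~ truth, data = d4,
                          exact = FALSE)$statistic
  expect_equal(roc_curve(d4)$auc, unname(u) / (30 * 30), tolerance = 1e-12)

  expect_error(roc_curve(tibble::tibble(prob_lymphoma = 1:3 / 4,
                                        truth = rep("pdx", 3))),
               "Both classes")
})

test_that("blind evaluation accounts for every attempt exactly once", {
  co <- tiny_cohort()
  bcfg <- cohort_config(n_specimens_per_class = c(lymphoma = 4, pdx = 6),
                        events_per_specimen = 5, seed = 55,
                        bad_event_rates = c(no_lockmass = 0.05,
                                            short_duration = 0.05,
                                            low_tic = 0.05))
  blind <- simulate_blind_set(bcfg)
  prep <- preprocess_scans(blind$scans, metadata = blind$metadata)
  rep <- blind_evaluate(co$model, prep, blind$truth)
  expect_equal(rep$attempts, nrow(prep$events))
  expect_equal(rep$classifiable,
               rep$attempts - rep$bad - rep$unclassifiable)
  expect_equal(sum(rep$contingency[, -1]), rep$classifiable)
  expect_equal(rep$duty_cycle, 100 * rep$classifiable / rep$attempts)
  # per-class sensitivity of one class is the specificity of the other
  expect_equal(rep$rates$sensitivity[1], rep$rates$specificity[2])
  gl <- glance(rep)
  expect_equal(gl$classifiable, rep$classifiable)
})

test_that("reports serialise to matching JSON and CSV", {
  co <- tiny_cohort()
  folds <- make_folds(co$specimens, k = 3, seed = 6)
  cv <- cross_validate(co$bm, folds)
  dir <- withr::local_tempdir()
  paths <- write_reports(cv, dir, "cv", seed = 6, config = co$cfg)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths["json"], simplifyVector = TRUE)
  tab <- readr::read_csv(paths["csv"], show_col_types = FALSE)
  expect_equal(js$totals$correct, cv$totals$correct)
  expect_equal(tab[[2]][nrow(tab)], cv$totals$total)
  expect_equal(js$provenance$seed, 6)
  # same inputs, same bytes
  paths2 <- write_reports(cv, dir, "cv2", seed = 6, config = co$cfg)
  expect_identical(readLines(paths["json"]), readLines(paths2["json"]))
})
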