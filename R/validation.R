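#' Accuracy under the two reporting denominators
#'
#' The accounting convention reports classification accuracy both per
#' classifiable data point (correct / (correct + misclassified)) and per
#' all data points (correct / (correct + misclassified + unclassifiable)),
#' since rejected events render no decision but still cost duty cycle.
#'
#' @param correct,misclassified,unclassifiable Event counts.
#' @return Tibble with `total`, `classifiable`, `acc_classifiable` and
#'   `acc_all` (percentages).
#' @export
#' @examples
#' accuracy_pair(1246, 0, 68)   # 100.00% / 94.82%
accuracy_pair <- function(correct, misclassified, unclassifiable) {
  classifiable <- correct + misclassified
  total <- classifiable + unclassifiable
  tibble(
    total = total,
    classifiable = classifiable,
    acc_classifiable = ifelse(classifiable > 0,
                              100 * correct / classifiable, NA_real_),
    acc_all = ifelse(total > 0, 100 * correct / total, NA_real_)
  )
}

#' Sensitivity and specificity from a 2x2 contingency
#'
#' Standard true-positive and true-negative rates over the events for
#' which a classification was rendered (unclassifiable and bad data are
#' excluded from the denominators).
#'
#' @param tp,fn,fp,tn Contingency counts with one class taken as
#'   positive.
#' @return Tibble with `sensitivity` and `specificity` (percentages).
#' @export
#' @examples
#' binary_rates(tp = 410, fn = 3, fp = 14, tn = 1503)
binary_rates <- function(tp, fn, fp, tn) {
  tibble(sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp))
}

#' Duty cycle of a sampling series
#'
#' Fraction of sampling attempts that yield a class prediction; attempts
#' rejected by the model (unclassifiable) or failing raw QC (bad) count
#' against it.
#'
#' @param attempts Total sampling attempts.
#' @param unclassifiable Model-rejected attempts.
#' @param bad QC-failed attempts.
#' @return Tibble with `classifiable` count and `duty_cycle` (%).
#' @export
#' @examples
#' duty_cycle(2079, 115, 34)   # 1930 classifiable, ~93%
duty_cycle <- function(attempts, unclassifiable, bad = 0) {
  classifiable <- attempts - unclassifiable - bad
  tibble(classifiable = classifiable,
         duty_cycle = 100 * classifiable / attempts)
}

#' Plan specimen-grouped, class-stratified folds
#'
#' Assigns whole specimens to folds so that all sampling events of a
#' specimen are held out together (no within-specimen leakage), with
#' class-stratified allocation so every class appears in every fold when
#' counts permit.
#'
#' @param specimens Tibble with `specimen_id`, `class` and any further
#'   stratification columns (one row per specimen; duplicated rows are
#'   collapsed).
#' @param k Number of folds (default 5); `k` equal to the specimen count
#'   gives leave-one-specimen-out.
#' @param seed Integer seed.
#' @param strata Column name(s) whose combination stratifies the
#'   allocation (default `"class"`). Under a permutation null, stratify
#'   on both the pseudo-group and the true class so no fold carries a
#'   residual class imbalance (see [permutation_null()]).
#' @return A `fold_plan` tibble: `specimen_id`, `class`, `fold`.
#' @export
make_folds <- function(specimens, k = 5, seed = 1L, strata = "class") {
  specimens <- dplyr::distinct(
    specimens, dplyr::pick(dplyr::all_of(unique(c("specimen_id", "class",
                                                  strata)))))
  if (anyDuplicated(specimens$specimen_id)) {
    abort("A specimen maps to more than one class/stratum.")
  }
  if (nrow(specimens) < k) abort("Fewer specimens than folds.")
  plan <- with_seed(seed, {
    shuffled <- specimens %>%
      group_by(dplyr::pick(dplyr::all_of(strata))) %>%
      dplyr::slice_sample(prop = 1) %>%
      ungroup()
    # one fold cycle running across the strata blocks: per-stratum
    # allocations stay within one specimen of balance, and k equal to the
    # specimen count degenerates to leave-one-specimen-out
    shuffled %>%
      mutate(fold = rep_len(seq_len(k), n())) %>%
      arrange(.data$specimen_id)
  })
  class(plan) <- c("fold_plan", class(plan))
  attr(plan, "k") <- k
  attr(plan, "seed") <- seed
  attr(plan, "strata") <- strata
  plan
}

#' Specimen-grouped cross-validation of the rejection classifier
#'
#' For each fold, fits the PCA-LDA rejection model on the training
#' specimens' events and classifies the held-out fold's events, then
#' aggregates correct / misclassified / unclassifiable counts per fold
#' and overall, the confusion matrix (with an unclassifiable column), the
#' two accuracy denominators and the duty cycle.
#'
#' @param bm A `binned_matrix` whose annotations include `specimen_id`
#'   and `class` (QC-good events only).
#' @param folds A [make_folds()] plan.
#' @param smote Augment each training fold with SMOTE (see
#'   [fit_rejection_lda()]); test folds are never augmented.
#' @param seed Seed for the (only) stochastic step, SMOTE; ignored
#'   otherwise, as the fold computation is deterministic given the plan.
#' @param ... Passed to [fit_rejection_lda()].
#' @return A `cv_report`.
#' @export
cross_validate <- function(bm, folds, smote = FALSE, seed = 1L, ...) {
  stopifnot(inherits(bm, "binned_matrix"),
            all(c("specimen_id", "class") %in% names(bm$events)))
  ev <- bm$events %>% left_join(as_tibble(folds) %>%
                                  select("specimen_id", "fold"),
                                by = "specimen_id")
  if (anyNA(ev$fold)) abort("Some events belong to specimens missing from the fold plan.")
  kf <- sort(unique(ev$fold))

  results <- purrr::map_dfr(kf, function(f) {
    tr <- which(ev$fold != f)
    te <- which(ev$fold == f)
    if (length(intersect(ev$specimen_id[tr], ev$specimen_id[te])) > 0) {
      abort("Fold plan leaks a specimen across train and test.")
    }
    if (length(unique(ev$class[tr])) < 2) {
      abort(paste0("Fold ", f, " has a single-class training set."))
    }
    model <- with_seed(seed + f,
      fit_rejection_lda(bm$values[tr, , drop = FALSE], ev$class[tr],
                        smote = smote, ...))
    classify_events(model, bm$values[te, , drop = FALSE]) %>%
      mutate(event_id = ev$event_id[te],
             fold = f,
             specimen_id = ev$specimen_id[te],
             truth = ev$class[te])
  })

  build_cv_report(results, classes = sort(unique(ev$class)),
                  folds = folds, smote = smote)
}

build_cv_report <- function(results, classes, folds = NULL, smote = FALSE) {
  per_fold <- results %>%
    group_by(.data$fold) %>%
    summarise(
      total = n(),
      correct = sum(.data$outcome == "classified" &
                      .data$label == .data$truth, na.rm = TRUE),
      misclassified = sum(.data$outcome == "classified" &
                            .data$label != .data$truth, na.rm = TRUE),
      unclassifiable = sum(.data$outcome == "unclassifiable"),
      .groups = "drop"
    )
  per_fold <- dplyr::bind_cols(
    per_fold,
    accuracy_pair(per_fold$correct, per_fold$misclassified,
                  per_fold$unclassifiable)[, c("classifiable",
                                               "acc_classifiable",
                                               "acc_all")])

  tot <- per_fold %>%
    summarise(across(c("total", "correct", "misclassified",
                       "unclassifiable", "classifiable"), sum))
  acc <- accuracy_pair(tot$correct, tot$misclassified, tot$unclassifiable)

  conf <- results %>%
    mutate(pred = ifelse(.data$outcome == "unclassifiable",
                         "unclassifiable", .data$label)) %>%
    count(.data$truth, .data$pred) %>%
    tidyr::pivot_wider(names_from = "pred", values_from = "n",
                       values_fill = 0L)
  for (cl in c(classes, "unclassifiable")) {
    if (!cl %in% names(conf)) conf[[cl]] <- 0L
  }
  conf <- conf %>% select("truth", all_of(classes), "unclassifiable")

  dc <- duty_cycle(tot$total, tot$unclassifiable)

  structure(list(
    per_fold = per_fold,
    totals = dplyr::bind_cols(tot,
                              acc[, c("acc_classifiable", "acc_all")]),
    accuracy_per_classifiable = acc$acc_classifiable,
    accuracy_per_all = acc$acc_all,
    accuracy_per_classifiable_foldmean = mean(per_fold$acc_classifiable),
    duty_cycle = dc$duty_cycle,
    confusion = conf,
    results = results,
    classes = classes,
    fold_plan = folds,
    smote = smote
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", nrow(x$per_fold), "-fold specimen-grouped CV",
      if (isTRUE(x$smote)) " (SMOTE-augmented training)", "\n", sep = "")
  print(as.data.frame(x$per_fold), digits = 4)
  with(x$totals, cat(sprintf(
    "total: %d points, %d correct, %d misclassified, %d unclassifiable\n",
    total, correct, misclassified, unclassifiable)))
  cat(sprintf("accuracy per classifiable: %.2f%%  per all: %.2f%%  duty cycle: %.2f%%\n",
              x$accuracy_per_classifiable, x$accuracy_per_all, x$duty_cycle))
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$per_fold

#' @export
glance.cv_report <- function(x, ...) {
  dplyr::bind_cols(x$totals,
                   tibble(acc_classifiable_foldmean =
                            x$accuracy_per_classifiable_foldmean,
                          duty_cycle = x$duty_cycle,
                          smote = isTRUE(x$smote)))
}

#' SMOTE-augmented cross-validation
#'
#' [cross_validate()] with minority-class SMOTE oversampling applied to
#' each training fold in PCA-score space, before the LDA step. Test folds
#' are never augmented, so the report differs from the plain CV only in
#' fold internals.
#'
#' @inheritParams cross_validate
#' @param smote_k Neighbour count for SMOTE.
#' @return A `cv_report`.
#' @export
smote_cross_validate <- function(bm, folds, smote_k = 5, seed = 1L, ...) {
  cross_validate(bm, folds, smote = TRUE, smote_k = smote_k, seed = seed, ...)
}

#' Permute class annotations at the specimen level
#'
#' Builds the permutation-label null: specimens are reassigned to two
#' pseudo-groups of (near-)equal specimen count, stratified over the true
#' classes so that each pseudo-group contains a comparable mixture of
#' both, destroying the class signal while preserving the grouped
#' (repeated-measures) structure that the full-group cross-validation
#' must respect.
#'
#' @param specimens Tibble with `specimen_id` and `class`.
#' @param seed Integer seed.
#' @return Tibble `specimen_id`, `class` (true), `perm_class`
#'   (`"group1"` / `"group2"`).
#' @export
permute_specimen_labels <- function(specimens, seed = 1L) {
  specimens <- dplyr::distinct(specimens, .data$specimen_id, .data$class)
  if (nrow(specimens) < 4) abort("Need at least 4 specimens to permute.")
  if (length(unique(specimens$class)) < 2) {
    abort("Both true classes must be present.")
  }
  with_seed(seed, {
    specimens %>%
      group_by(.data$class) %>%
      dplyr::slice_sample(prop = 1) %>%
      mutate(.half = rep_len(c(1L, 2L), n())) %>%
      ungroup() %>%
      mutate(perm_class = paste0("group", .data$.half)) %>%
      select("specimen_id", "class", "perm_class") %>%
      arrange(.data$specimen_id)
  })
}

#' Relabel a binned matrix with permuted annotations
#'
#' @param bm A `binned_matrix` with `specimen_id` annotations.
#' @param permutation Output of [permute_specimen_labels()].
#' @return The matrix with `class` replaced by the pseudo-group label
#'   (the true class is kept as `true_class`).
#' @export
apply_permutation <- function(bm, permutation) {
  ev <- bm$events %>%
    rename(true_class = "class") %>%
    left_join(permutation %>% select("specimen_id", "perm_class"),
              by = "specimen_id") %>%
    rename(class = "perm_class")
  if (anyNA(ev$class)) abort("Permutation is missing some specimens.")
  bm$events <- ev
  bm
}

#' Permutation-label null of the grouped cross-validation
#'
#' Destroys the class signal by reassigning whole specimens to two
#' pseudo-groups ([permute_specimen_labels()]) and re-runs the
#' specimen-grouped cross-validation. The fold plan is stratified on the
#' pseudo-group x true-class pair: without that, the residual true-class
#' imbalance between training pseudo-groups is anti-correlated with the
#' held-out fold's composition and drags the null accuracy systematically
#' below chance (the classifier "anti-learns" the real signal). With a
#' valid null, the per-classifiable accuracy collapses to ~50%.
#'
#' @inheritParams cross_validate
#' @param seed Seed driving both the permutation and the fold plan.
#' @param k Number of folds.
#' @return A `cv_report` on the permuted labels, with the permutation
#'   table attached as `$permutation`.
#' @export
permutation_null <- function(bm, k = 5, seed = 1L, ...) {
  specs <- dplyr::distinct(bm$events, .data$specimen_id, .data$class)
  perm <- permute_specimen_labels(specs, seed = seed)
  bmp <- apply_permutation(bm, perm)
  strat <- dplyr::distinct(bmp$events, .data$specimen_id, .data$class,
                           .data$true_class)
  folds <- make_folds(strat, k = k, seed = seed + 1L,
                      strata = c("class", "true_class"))
  report <- cross_validate(bmp, folds, ...)
  report$permutation <- perm
  report
}

#' Receiver operating characteristic curve and AUC
#'
#' Standard ROC over a sweeping threshold on a per-event score (by
#' convention the positive-class probability, or a signed discriminant
#' score). The area under the curve equals the Mann-Whitney U statistic
#' divided by `n1 * n2`.
#'
#' @param data Tibble holding scores and labels.
#' @param score,truth Column names (strings) of the score and the true
#'   label.
#' @param positive Label treated as positive.
#' @return A `roc_result`: list with `curve` (tibble of `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(data, score = "prob_lymphoma", truth = "truth",
                      positive = "lymphoma") {
  labels <- data[[truth]]
  scores <- data[[score]]
  keep <- !is.na(scores) & !is.na(labels)
  labels <- labels[keep]; scores <- scores[keep]
  if (length(unique(labels)) < 2) {
    abort("Both classes must be present to build a ROC curve.")
  }
  r <- pROC::roc(response = factor(labels == positive, c(FALSE, TRUE)),
                 predictor = scores, direction = "<", quiet = TRUE)
  structure(list(
    curve = tibble(threshold = r$thresholds,
                   fpr = 1 - r$specificities,
                   tpr = r$sensitivities) %>% arrange(.data$fpr, .data$tpr),
    auc = as.numeric(r$auc),
    positive = positive,
    n_positive = sum(labels == positive),
    n_negative = sum(labels != positive)
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (positive: %s; %d vs %d events)\n",
              x$auc, x$positive, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_positive = x$n_positive, n_negative = x$n_negative)
}

#' Evaluate a fitted model on a blinded sampling series
#'
#' Classifies every sampling attempt of a blinded set, then unseals the
#' truth and accounts for the series the way a blind validation table
#' does: attempts, bad (QC-failed) and unclassifiable counts, the 2x2
#' contingency over classified events only, per-class sensitivity and
#' specificity, the duty cycle, the mean winning prediction probability
#' and the mean per-specimen spatial concordance, the last two reported
#' as mean +/- `sd_multiplier` x SD (default half an SD).
#'
#' @param model A fitted `rejection_lda`.
#' @param prep Output of [preprocess_scans()] on the blind scans (all
#'   attempts in `$events`, QC-good events in `$matrix`).
#' @param truth A `sealed_truth` (or open truth tibble) with `event_id`,
#'   `specimen_id`, `class`.
#' @param sd_multiplier Width multiplier for the dispersion half-bands
#'   (0.5 by default; set 1 for conventional +/- 1 SD).
#' @return A `blind_report`.
#' @export
blind_evaluate <- function(model, prep, truth, sd_multiplier = 0.5) {
  truth_tbl <- if (inherits(truth, "sealed_truth")) unseal_truth(truth)
               else truth
  events <- prep$events
  res <- classify_events(model, prep$matrix) %>%
    left_join(truth_tbl %>% select("event_id", "specimen_id", truth = "class"),
              by = "event_id")

  attempts <- nrow(events)
  bad <- sum(events$qc_status != "good")
  unclassifiable <- sum(res$outcome == "unclassifiable")
  classified <- res %>% filter(.data$outcome == "classified")
  dc <- duty_cycle(attempts, unclassifiable, bad)

  classes <- model$classes
  contingency <- classified %>%
    count(truth = .data$truth, predicted = .data$label) %>%
    tidyr::pivot_wider(names_from = "predicted", values_from = "n",
                       values_fill = 0L)
  for (cl in classes) if (!cl %in% names(contingency)) contingency[[cl]] <- 0L
  contingency <- contingency %>% select("truth", all_of(classes))

  rates <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(classified$truth == cl & classified$label == cl)
    fn <- sum(classified$truth == cl & classified$label != cl)
    fp <- sum(classified$truth != cl & classified$label == cl)
    tn <- sum(classified$truth != cl & classified$label != cl)
    dplyr::bind_cols(tibble(class = cl, tp = tp, fn = fn, fp = fp, tn = tn),
                     binary_rates(tp, fn, fp, tn))
  })

  spec_calls <- classify_specimens(res, truth_tbl)
  conc <- spec_calls$concordance[!is.na(spec_calls$concordance)]
  prob <- classified$probability

  structure(list(
    attempts = attempts, bad = bad, unclassifiable = unclassifiable,
    classifiable = dc$classifiable, duty_cycle = dc$duty_cycle,
    contingency = contingency, rates = rates,
    mean_probability = 100 * mean(prob),
    probability_halfband = 100 * sd_multiplier * sd(prob),
    mean_concordance = 100 * mean(conc),
    concordance_halfband = 100 * sd_multiplier * sd(conc),
    sd_multiplier = sd_multiplier,
    specimen_calls = spec_calls,
    results = res
  ), class = "blind_report")
}

#' @export
print.blind_report <- function(x, ...) {
  cat("<blind_report>", x$attempts, "attempts:", x$bad, "bad,",
      x$unclassifiable, "unclassifiable,", x$classifiable, "classifiable\n")
  cat(sprintf("duty cycle: %.2f%%\n", x$duty_cycle))
  print(as.data.frame(x$rates), digits = 4)
  cat(sprintf("mean prediction probability: (%.0f +/- %.0f)%%\n",
              x$mean_probability, x$probability_halfband))
  cat(sprintf("mean spatial concordance:   (%.0f +/- %.0f)%%\n",
              x$mean_concordance, x$concordance_halfband))
  invisible(x)
}

#' @export
tidy.blind_report <- function(x, ...) x$rates

#' @export
glance.blind_report <- function(x, ...) {
  tibble(attempts = x$attempts, bad = x$bad,
         unclassifiable = x$unclassifiable, classifiable = x$classifiable,
         duty_cycle = x$duty_cycle,
         mean_probability = x$mean_probability,
         mean_concordance = x$mean_concordance)
}
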