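#' Fit a PCA-LDA classifier with a Mahalanobis rejection option
#'
#' Reduces the TIC-normalized feature matrix with principal component
#' analysis (components retained up to `variance_fraction` of training
#' variance, optionally hard-capped), projects the retained scores onto
#' the linear discriminant axes (one axis for two classes), and stores
#' per-class cluster centres and covariances in discriminant space. New
#' events are classified by Mahalanobis distance to the cluster centres;
#' events farther than `sd_threshold` standard deviations from every
#' centre are rejected as unclassifiable rather than forced into a class.
#'
#' Because events are far fewer than the 9,000 spectral bins, the PCA is
#' computed from the eigendecomposition of the event-space Gram matrix
#' (the "snapshot" method), which is exactly equivalent to the singular
#' value decomposition of the centred data.
#'
#' Per-class covariances are shrunk toward the pooled within-class
#' covariance, `(1 - shrinkage) * S_c + shrinkage * S_pooled`, guarding
#' the estimate for small classes.
#'
#' @param x A `binned_matrix` (labels taken from its `class` annotation
#'   unless given) or a plain numeric matrix.
#' @param labels Class label per row; first factor level (or alphabetical
#'   order for character input) breaks distance ties.
#' @param variance_fraction Fraction of training variance the retained
#'   components must explain (default 0.95).
#' @param component_cap Optional hard cap on retained components (the
#'   instrument-software analysis path fixes this at 262); the cap is
#'   always additionally limited to the feasible rank.
#' @param sd_threshold Mahalanobis rejection radius in SD units
#'   (default 4).
#' @param shrinkage Shrinkage weight toward the pooled covariance
#'   (default 0.1).
#' @param smote Oversample minority-class training scores with SMOTE (in
#'   PCA space, before the LDA step).
#' @param smote_k Neighbour count for SMOTE (reduced with a warning when
#'   the minority class is too small).
#' @return A fitted `rejection_lda` model.
#' @export
fit_rejection_lda <- function(x, labels = NULL, variance_fraction = 0.95,
                              component_cap = NULL, sd_threshold = 4,
                              shrinkage = 0.1, smote = FALSE, smote_k = 5) {
  if (inherits(x, "binned_matrix")) {
    if (is.null(labels)) labels <- x$events$class
    x <- x$values
  }
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  classes <- levels(labels)
  k <- length(classes)
  if (k < 2) abort("Need at least two classes to fit a classifier.")
  if (any(table(labels) < 2)) abort("Every class needs at least 2 events.")
  n <- nrow(x)

  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  gram <- tcrossprod(xc)
  eig <- eigen(gram, symmetric = TRUE)
  evals <- pmax(eig$values, 0)
  tol <- max(evals) * 1e-10
  rank <- sum(evals > tol)
  frac <- cumsum(evals) / sum(evals)
  r <- which(frac >= variance_fraction)[1]
  if (is.na(r)) r <- rank
  r <- min(r, rank, n - k, if (is.null(component_cap)) Inf else component_cap)
  r <- max(r, k - 1L)

  d <- sqrt(evals[seq_len(r)])
  u <- eig$vectors[, seq_len(r), drop = FALSE]
  rotation <- crossprod(xc, u) %*% diag(1 / d, r, r)   # p x r, orthonormal
  scores <- u %*% diag(d, r, r)                        # n x r = xc %*% rotation

  train_scores <- scores
  train_labels <- labels
  smote_info <- NULL
  if (smote) {
    aug <- smote_augment(scores, labels, k_neighbours = smote_k)
    train_scores <- aug$x
    train_labels <- aug$labels
    smote_info <- aug$info
  }

  lda_fit <- MASS::lda(train_scores, grouping = train_labels)
  ld <- predict(lda_fit, train_scores)$x               # n x (k-1)

  class_means <- lapply(classes, function(cl)
    colMeans(ld[train_labels == cl, , drop = FALSE]))
  names(class_means) <- classes
  covs <- lapply(classes, function(cl)
    cov_matrix(ld[train_labels == cl, , drop = FALSE]))
  names(covs) <- classes
  pooled <- Reduce(`+`, lapply(classes, function(cl) {
    m <- sum(train_labels == cl)
    (m - 1) * covs[[cl]]
  })) / (length(train_labels) - k)
  class_cov <- lapply(covs, function(s) (1 - shrinkage) * s + shrinkage * pooled)

  structure(list(
    center = center, rotation = rotation,
    explained = evals[seq_len(r)] / sum(evals),
    variance_fraction = variance_fraction, component_cap = component_cap,
    n_components = r, lda = lda_fit, classes = classes,
    class_means = class_means, class_cov = class_cov, pooled_cov = pooled,
    sd_threshold = sd_threshold, shrinkage = shrinkage,
    n_train = n, smote = smote_info
  ), class = "rejection_lda")
}

cov_matrix <- function(x) {
  s <- stats::cov(x)
  if (!is.matrix(s)) s <- matrix(s, 1, 1)
  s
}

#' Mahalanobis distance to a cluster centre
#'
#' `d = sqrt((x - mu)' Sigma^-1 (x - mu))`, computed through the Cholesky
#' factor of the covariance; in one dimension this reduces to
#' `|x - mu| / sigma`, i.e. the number of standard deviations from the
#' centre.
#'
#' @param x Numeric vector or matrix of row vectors.
#' @param center Cluster centre.
#' @param cov Covariance matrix (must be positive definite).
#' @return Numeric distance per row of `x`.
#' @export
mahalanobis_distance <- function(x, center, cov) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(cov)) cov <- matrix(cov, 1, 1)
  ch <- tryCatch(chol(cov), error = function(e)
    abort("Covariance is singular or not positive definite."))
  z <- backsolve(ch, t(sweep(x, 2, center)), transpose = TRUE)
  sqrt(colSums(z^2))
}

# Project raw feature vectors through PCA then LDA.
project_scores <- function(model, x) {
  if (inherits(x, "binned_matrix")) x <- x$values
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(model$rotation)) {
    abort(paste0("Expected ", nrow(model$rotation), " features, got ",
                 ncol(x), "."))
  }
  pc <- sweep(x, 2, model$center) %*% model$rotation
  predict(model$lda, pc)$x
}

#' Classify events with the rejection rule
#'
#' Projects each event's feature vector through the fitted PCA and LDA
#' bases, computes its Mahalanobis distance to every class centre, and
#' either assigns the nearest class (with Gaussian-likelihood softmax
#' probabilities `p_c` proportional to `exp(-d_c^2 / 2)`) or rejects the
#' event as `unclassifiable` when the nearest centre is farther than the
#' model's `sd_threshold`. Distance ties are broken in favour of the
#' first declared class.
#'
#' @param model A fitted [fit_rejection_lda()] model.
#' @param x A `binned_matrix` or numeric matrix of feature vectors.
#' @param sd_threshold Optional override of the model's rejection radius.
#' @return Tibble with one row per event: `event_id`, `outcome`
#'   (`classified` / `unclassifiable`), `label`, `probability` (winning
#'   class), one `dist_*` and one `prob_*` column per class, and the
#'   discriminant scores `ld1`, ...
#' @export
classify_events <- function(model, x, sd_threshold = NULL) {
  stopifnot(inherits(model, "rejection_lda"))
  ids <- if (inherits(x, "binned_matrix")) x$events$event_id else rownames(x)
  ld <- project_scores(model, x)
  if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(ld)))
  thr <- if (is.null(sd_threshold)) model$sd_threshold else sd_threshold

  dmat <- vapply(model$classes, function(cl)
    mahalanobis_distance(ld, model$class_means[[cl]], model$class_cov[[cl]]),
    numeric(nrow(ld)))
  if (!is.matrix(dmat)) dmat <- matrix(dmat, nrow = 1,
                                       dimnames = list(NULL, model$classes))
  d2 <- dmat^2
  pm <- exp(-(d2 - apply(d2, 1, min)) / 2)
  pm <- pm / rowSums(pm)

  win <- apply(dmat, 1, which.min)          # ties -> first declared class
  dmin <- dmat[cbind(seq_len(nrow(dmat)), win)]
  rejected <- dmin > thr

  out <- tibble(
    event_id = ids,
    outcome = ifelse(rejected, "unclassifiable", "classified"),
    label = ifelse(rejected, NA_character_, model$classes[win]),
    probability = ifelse(rejected, NA_real_,
                         pm[cbind(seq_len(nrow(pm)), win)])
  )
  colnames(dmat) <- paste0("dist_", model$classes)
  colnames(pm) <- paste0("prob_", model$classes)
  ldt <- as_tibble(ld, .name_repair = "minimal")
  names(ldt) <- paste0("ld", seq_len(ncol(ld)))
  dplyr::bind_cols(out, as_tibble(dmat), as_tibble(pm), ldt)
}

#' @export
predict.rejection_lda <- function(object, newdata, ...) {
  classify_events(object, newdata, ...)
}

#' Aggregate event calls into specimen-level calls
#'
#' A specimen is called by majority vote among its classified events; the
#' spatial concordance is the fraction of classified events agreeing with
#' the majority. Ties, or specimens with no classified event, are flagged
#' indeterminate.
#'
#' @param results Classification tibble from [classify_events()].
#' @param specimens Tibble mapping `event_id` to `specimen_id` (extra
#'   columns are kept).
#' @return Tibble with one row per specimen: `specimen_id`, `call`
#'   (label or `"indeterminate"`), `concordance`, `n_classified`,
#'   `n_events`.
#' @export
classify_specimens <- function(results, specimens) {
  joined <- if ("specimen_id" %in% names(results)) results
            else results %>%
              left_join(specimens %>% select("event_id", "specimen_id"),
                        by = "event_id")
  joined %>%
    group_by(.data$specimen_id) %>%
    summarise(
      n_events = n(),
      n_classified = sum(.data$outcome == "classified"),
      call = specimen_majority(.data$label[.data$outcome == "classified"]),
      concordance = specimen_concordance(
        .data$label[.data$outcome == "classified"]),
      .groups = "drop"
    )
}

specimen_majority <- function(labels) {
  if (length(labels) == 0) return("indeterminate")
  tab <- table(labels)
  top <- tab[tab == max(tab)]
  if (length(top) > 1) "indeterminate" else names(top)
}

specimen_concordance <- function(labels) {
  if (length(labels) == 0) return(NA_real_)
  max(table(labels)) / length(labels)
}

#' @export
print.rejection_lda <- function(x, ...) {
  cat("<rejection_lda> ", length(x$classes), " classes (",
      paste(x$classes, collapse = ", "), ")\n", sep = "")
  cat("  ", x$n_components, " PCs capturing ",
      sprintf("%.1f%%", 100 * sum(x$explained)),
      " of variance (target ", sprintf("%.0f%%", 100 * x$variance_fraction),
      if (!is.null(x$component_cap)) paste0(", cap ", x$component_cap), ")\n",
      sep = "")
  cat("  rejection threshold:", x$sd_threshold, "SD; shrinkage",
      x$shrinkage, "\n")
  if (!is.null(x$smote)) cat("  SMOTE:", x$smote$added, "synthetic",
                             x$smote$class, "points added\n")
  invisible(x)
}

#' @export
tidy.rejection_lda <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    mu <- x$class_means[[cl]]
    tibble(class = cl,
           axis = seq_along(mu),
           centre = unname(mu),
           sd = sqrt(diag(as.matrix(x$class_cov[[cl]]))))
  })
}

#' @export
glance.rejection_lda <- function(x, ...) {
  tibble(n_train = x$n_train,
         n_classes = length(x$classes),
         n_components = x$n_components,
         variance_captured = sum(x$explained),
         sd_threshold = x$sd_threshold,
         shrinkage = x$shrinkage,
         smote = !is.null(x$smote))
}

#' Broom-style generics
#'
#' [tidy()] and [glance()] generics re-exported for the package's model
#' and report classes.
#' @param x Object to summarise.
#' @param ... Passed to methods.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
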