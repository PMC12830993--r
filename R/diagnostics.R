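#' UMAP embedding of a feature matrix
#'
#' Two-dimensional uniform manifold approximation and projection of the
#' TIC-normalized feature matrix for unsupervised inspection of class
#' structure. Deterministic for a fixed seed. The embedding is a
#' visualization aid only: no classification decision in this package
#' depends on its output.
#'
#' @param bm A `binned_matrix` (or numeric matrix).
#' @param n_neighbors Neighbourhood size (default 25).
#' @param n_components Embedding dimensions (default 2).
#' @param n_epochs Optimisation epochs (default 200).
#' @param seed Random seed (default 123).
#' @param metric Distance metric (default Euclidean).
#' @param iterations Recorded as metadata for provenance; the embedding
#'   itself is driven by `n_epochs`, the single epoch-like parameter the
#'   algorithm exposes.
#' @return Tibble of event annotations plus `umap1`, `umap2`, ...;
#'   parameters attached as the `"params"` attribute.
#' @export
umap_embed <- function(bm, n_neighbors = 25, n_components = 2,
                       n_epochs = 200, seed = 123, metric = "euclidean",
                       iterations = 250) {
  values <- if (inherits(bm, "binned_matrix")) bm$values else bm
  ann <- if (inherits(bm, "binned_matrix")) bm$events
         else tibble(event_id = rownames(values) %||%
                       sprintf("row%d", seq_len(nrow(values))))
  stopifnot(n_neighbors >= 2, n_components >= 1, n_epochs >= 1)
  if (nrow(values) < n_neighbors + 1) {
    abort("Need at least n_neighbors + 1 events to embed.")
  }
  coords <- with_seed(seed,
    uwot::umap(values, n_neighbors = n_neighbors,
               n_components = n_components, n_epochs = n_epochs,
               metric = metric, n_sgd_threads = 1, n_threads = 1))
  colnames(coords) <- paste0("umap", seq_len(n_components))
  out <- dplyr::bind_cols(ann, as_tibble(coords))
  attr(out, "params") <- list(n_neighbors = n_neighbors,
                              n_components = n_components,
                              n_epochs = n_epochs, seed = seed,
                              metric = metric, iterations = iterations)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson feature-correlation map
#'
#' Pairwise Pearson correlation between the (1-Da) spectral features
#' across a subset of events, giving a 900 x 900 fingerprint of feature
#' co-variation that can be compared between specimens. Features with
#' zero variance over the subset are masked (undefined coefficients) and
#' never imputed.
#'
#' @param bm A `binned_matrix`, typically the [rebin_1da()] output.
#' @param events Optional character vector of event ids (or
#'   logical/integer index) selecting the subset; default all.
#' @param tag Free-text label stored with the map (e.g. specimen or
#'   class).
#' @return A `correlation_map`: list with `r` (correlation matrix, `NA`
#'   where masked), `mask` (logical vector of defined features) and
#'   `tag`.
#' @export
correlation_map <- function(bm, events = NULL, tag = "") {
  values <- if (inherits(bm, "binned_matrix")) bm$values else bm
  if (!is.null(events)) {
    idx <- if (is.character(events)) match(events, rownames(values))
           else events
    values <- values[idx, , drop = FALSE]
  }
  if (nrow(values) < 3) {
    abort("Need at least 3 events; Pearson coefficients are unstable below that.")
  }
  sds <- apply(values, 2, sd)
  defined <- sds > 0
  r <- matrix(NA_real_, ncol(values), ncol(values),
              dimnames = list(colnames(values), colnames(values)))
  if (any(defined)) {
    r[defined, defined] <- cor(values[, defined, drop = FALSE])
  }
  structure(list(r = r, mask = defined, tag = tag, n_events = nrow(values)),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("<correlation_map> ", nrow(x$r), "x", ncol(x$r), " features, ",
      sum(x$mask), " defined, from ", x$n_events, " events",
      if (nzchar(x$tag)) paste0(" [", x$tag, "]"), "\n", sep = "")
  invisible(x)
}

#' Similarity between two correlation maps
#'
#' Pearson correlation between the vectorized upper triangles of two
#' maps over their jointly defined entries, scoring how alike two
#' feature-covariation fingerprints are (1 identical, -1 opposite).
#'
#' @param query,control `correlation_map` objects on the same feature
#'   grid.
#' @return Similarity in `[-1, 1]`.
#' @export
map_similarity <- function(query, control) {
  stopifnot(inherits(query, "correlation_map"),
            inherits(control, "correlation_map"))
  if (!identical(dim(query$r), dim(control$r))) {
    abort("Maps are on different feature grids.")
  }
  up <- upper.tri(query$r)
  a <- query$r[up]
  b <- control$r[up]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) abort("No jointly defined entries.")
  a <- a[keep]; b <- b[keep]
  if (sd(a) == 0 || sd(b) == 0) {
    abort("A map is constant over the joint support; similarity undefined.")
  }
  cor(a, b)
}

#' Per-event discriminant scores for jitter plotting
#'
#' Exports the 1-D LDA score of every event together with its class and
#' specimen, the raw material of a jitter plot showing the degree of
#' mixing between the two classes along the discriminant axis. The
#' attached `overlap` attribute is the fraction of all events lying in
#' the interval where the two class score ranges overlap (~0 for
#' separable classes, ~1 for identical distributions).
#'
#' @param model A fitted two-class `rejection_lda`.
#' @param bm A `binned_matrix` with `class` (and ideally `specimen_id`)
#'   annotations.
#' @return Tibble `event_id`, `specimen_id`, `class`, `score`; overlap
#'   statistic in `attr(, "overlap")`.
#' @export
jitter_data <- function(model, bm) {
  stopifnot(inherits(model, "rejection_lda"),
            inherits(bm, "binned_matrix"))
  if (length(model$classes) != 2) {
    abort("Jitter data is defined for the two-class model.")
  }
  scores <- project_scores(model, bm)[, 1]
  out <- tibble(
    event_id = bm$events$event_id,
    specimen_id = bm$events$specimen_id %||%
      rep(NA_character_, nrow(bm$events)),
    class = bm$events$class,
    score = scores
  )
  attr(out, "overlap") <- score_overlap(scores, out$class)
  out
}

#' Overlap fraction of two score distributions
#'
#' Fraction of all events whose score falls inside the intersection of
#' the two classes' score ranges (empty for disjoint ranges).
#'
#' @param scores Numeric 1-D discriminant scores.
#' @param labels Two-level class label per score.
#' @return Fraction in `[0, 1]`.
#' @export
score_overlap <- function(scores, labels) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2)
  r1 <- range(scores[labels == levels(labels)[1]])
  r2 <- range(scores[labels == levels(labels)[2]])
  lo <- max(r1[1], r2[1])
  hi <- min(r1[2], r2[2])
  if (hi <= lo) return(0)
  mean(scores >= lo & scores <= hi)
}
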