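# Synthetic minority oversampling (SMOTE) in PCA-score space.
#
# Classical SMOTE: each synthetic point lies on the segment between a
# minority point and one of its k nearest minority neighbours,
# new = x + U(0,1) * (neighbour - x). Applied after PCA projection and
# before the LDA step, so the discriminant sees a balanced training set
# while the test data are never augmented.

smote_augment <- function(x, labels, k_neighbours = 5) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- factor(labels)
  counts <- table(labels)
  target <- max(counts)
  add_x <- list()
  add_lab <- character()
  info <- NULL
  for (cl in names(counts)) {
    m <- counts[[cl]]
    need <- target - m
    if (need == 0) next
    if (m < 2) {
      warn(paste0("SMOTE: class '", cl,
                  "' has fewer than 2 points; duplicating instead."))
      idx <- which(labels == cl)
      pick <- sample(idx, need, replace = TRUE)
      add_x[[cl]] <- x[pick, , drop = FALSE]
      add_lab <- c(add_lab, rep(cl, need))
      next
    }
    k <- min(k_neighbours, m - 1)
    if (k < k_neighbours) {
      warn(paste0("SMOTE: reducing neighbours from ", k_neighbours, " to ",
                  k, " for class '", cl, "' (only ", m, " points)."))
    }
    xm <- x[labels == cl, , drop = FALSE]
    d <- as.matrix(stats::dist(xm))
    diag(d) <- Inf
    nn <- apply(d, 1, function(row) order(row)[seq_len(k)])
    nn <- matrix(nn, nrow = k)                      # k x m
    base <- sample.int(m, need, replace = TRUE)
    neigh <- nn[cbind(sample.int(k, need, replace = TRUE), base)]
    gap <- runif(need)
    syn <- xm[base, , drop = FALSE] +
      gap * (xm[neigh, , drop = FALSE] - xm[base, , drop = FALSE])
    add_x[[cl]] <- syn
    add_lab <- c(add_lab, rep(cl, need))
    info <- list(class = cl, added = as.integer(need), k = k)
  }
  if (length(add_x) == 0) {
    return(list(x = x, labels = labels,
                info = list(class = NA_character_, added = 0L,
                            k = k_neighbours)))
  }
  list(x = rbind(x, do.call(rbind, add_x)),
       labels = factor(c(as.character(labels), add_lab),
                       levels = levels(labels)),
       info = info)
}
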