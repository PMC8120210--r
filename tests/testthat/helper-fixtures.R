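# shared fixture builders and oracles

# mean Jaccard overlap of ground-truth labels vs a predicted label map,
# matching each true cell to the predicted label with maximal overlap
mean_jaccard <- function(true_labels, pred_labels) {
  ids <- sort(unique(true_labels[true_labels > 0]))
  mean(vapply(ids, function(i) {
    gt <- true_labels == i
    ov <- table(pred_labels[gt])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) return(0)
    j <- as.integer(names(ov)[which.max(ov)])
    pr <- pred_labels == j
    sum(gt & pr) / sum(gt | pr)
  }, 0))
}

# brute-force 4-connected adjacency by scanning every pixel pair
adjacency_oracle <- function(labels) {
  n <- max(labels)
  adj <- matrix(FALSE, n, n)
  for (x in seq_len(nrow(labels))) for (y in seq_len(ncol(labels))) {
    a <- labels[x, y]
    if (a == 0) next
    if (x < nrow(labels)) {
      b <- labels[x + 1, y]
      if (b > 0 && b != a) adj[a, b] <- adj[b, a] <- TRUE
    }
    if (y < ncol(labels)) {
      b <- labels[x, y + 1]
      if (b > 0 && b != a) adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  adj
}

# axial angular difference in degrees, in [0, 90]
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# log-linear regression oracle for a monoexponential decay toward `f0`
tau_loglinear_oracle <- function(t, y, f0) {
  -1 / unname(coef(lm(log(y - f0) ~ t))[2])
}
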