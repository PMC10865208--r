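# Independent brute-force oracles: plain-R re-derivations of the package's
# statistics from their definitions, used to cross-check the optimized
# implementations. They share no code path with the package internals.

# ReliefF by exhaustive enumeration: full pairwise diffs, explicit neighbour
# sort per class (ties broken by row index), prior- or uniform-weighted miss
# classes, missing diffs replaced by the feature's mean observed pair diff.
relieff_brute <- function(x, labels, k, miss_weighting = "class_prior") {
  x <- as.matrix(x)
  n <- nrow(x); M <- ncol(x)
  cls <- sort(unique(labels))
  y <- match(labels, cls)
  prior <- as.numeric(table(factor(y, levels = seq_along(cls)))) / n

  xn <- x; md <- numeric(M)
  for (f in seq_len(M)) {
    obs <- x[!is.na(x[, f]), f]
    rng <- if (length(obs)) diff(range(obs)) else 0
    if (rng > 0) {
      xn[, f] <- (x[, f] - min(obs)) / rng
      v <- xn[!is.na(xn[, f]), f]
      tot <- 0; np <- 0
      for (a in seq_along(v)) for (b in seq_along(v)) if (a < b) {
        tot <- tot + abs(v[a] - v[b]); np <- np + 1
      }
      md[f] <- if (np > 0) tot / np else 0
    } else {
      xn[, f] <- ifelse(is.na(x[, f]), NA_real_, 0)
      md[f] <- 0
    }
  }
  dif <- function(i, j, f) {
    a <- xn[i, f]; b <- xn[j, f]
    if (is.na(a) || is.na(b)) md[f] else abs(a - b)
  }
  W <- numeric(M)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j) {
      sum(vapply(seq_len(M), function(f) dif(i, j, f), numeric(1)))
    }, numeric(1))
    hit <- numeric(M); missacc <- numeric(M); nmiss <- 0
    for (ci in seq_along(cls)) {
      cand <- setdiff(which(y == ci), i)
      if (!length(cand)) next
      cand <- cand[order(d[cand], cand)]
      sel <- cand[seq_len(min(k, length(cand)))]
      meand <- vapply(seq_len(M), function(f) {
        mean(vapply(sel, function(j) dif(i, j, f), numeric(1)))
      }, numeric(1))
      if (ci == y[i]) {
        hit <- meand
      } else {
        nmiss <- nmiss + 1
        w <- if (miss_weighting == "uniform") 1 else
          prior[ci] / (1 - prior[y[i]])
        missacc <- missacc + w * meand
      }
    }
    if (miss_weighting == "uniform" && nmiss > 0) missacc <- missacc / nmiss
    W <- W + missacc - hit
  }
  setNames(W / n, colnames(x))
}

# Macro F1 straight from the label lists, one-vs-rest per class.
f1_brute <- function(true, pred, classes = 0:3) {
  per <- vapply(classes, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  mean(per)
}

# Verify every synthetic SMOTE row lies on a segment between some original
# minority row and one of that row's k nearest same-class neighbours
# (exhaustive search over minority pairs, same index tie rule).
smote_segments_ok <- function(orig_x, orig_y, out_ft, k, tol = 1e-8) {
  syn_rows <- which(out_ft$synthetic)
  for (i in syn_rows) {
    s <- as.numeric(out_ft$x[i, ])
    cl <- out_ft$labels[i]
    rows <- which(orig_y == cl)
    xc <- as.matrix(orig_x[rows, , drop = FALSE])
    nc <- nrow(xc)
    kc <- min(k, nc - 1)
    d <- as.matrix(dist(xc))
    found <- FALSE
    for (a in seq_len(nc)) {
      ord <- order(d[a, ], seq_len(nc))
      nbrs <- setdiff(ord, a)[seq_len(kc)]
      for (b in nbrs) {
        dir <- xc[b, ] - xc[a, ]
        rel <- s - xc[a, ]
        if (sum(dir^2) == 0) {
          if (max(abs(rel)) < tol) { found <- TRUE; break }
          next
        }
        u <- sum(rel * dir) / sum(dir^2)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            max(abs(rel - u * dir)) < tol) { found <- TRUE; break }
      }
      if (found) break
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# Two well-separated Gaussian blobs for classifier sanity checks.
make_blobs <- function(n_per = 50, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
               matrix(rnorm(n_per * 2, mean = sep), ncol = 2))
  })
  feature_table(data.frame(f1 = x[, 1], f2 = x[, 2]),
                labels = rep(c(0L, 1L), each = n_per))
}

# Small labelled table with arbitrary continuous features and given class
# counts (labels in the 0:3 coding).
make_counted_ft <- function(counts, n_feat = 2, seed = 1) {
  labels <- rep(as.integer(names(counts)), times = as.integer(counts))
  withr::with_seed(seed, {
    x <- as.data.frame(matrix(rnorm(length(labels) * n_feat),
                              ncol = n_feat))
  })
  names(x) <- paste0("f", seq_len(n_feat))
  feature_table(x, labels)
}
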