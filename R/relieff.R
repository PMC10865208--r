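#' Rank features with multiclass ReliefF
#'
#' ReliefF scores each feature by contrasting its values between neighbouring
#' observations: for every sampled instance the algorithm finds the `k`
#' nearest same-class neighbours (hits) and the `k` nearest neighbours of
#' every other class (misses), and rewards features that differ little to
#' hits but strongly to misses. The weight accumulated over `m` instances is
#'
#' \deqn{W_f \mathrel{+}= \big(\textstyle\sum_{c \ne class(i)} p_c \,
#'   \overline{diff}_{miss,c}(f) - \overline{diff}_{hit}(f)\big) / m}
#'
#' with per-feature diffs min-max-normalized to \[0, 1\] (so `|W| <= 1` and
#' positive rescaling of a feature cannot change its weight), and the miss
#' classes averaged either by their prior probability
#' (`miss_weighting = "class_prior"`, the default: class `c` gets
#' `P(c) / (1 - P(class(i)))`) or uniformly. A diff involving a missing
#' entry contributes the feature's mean observed pairwise diff, which keeps
#' incomplete rows usable. Neighbour searches break distance ties by row
#' index, so results are deterministic; with `m = n` (the default, every
#' training row visited once) no randomness is involved at all.
#'
#' The returned `score` column is the companion statistic
#' `S_f = sum(diff_hit - diff_miss) / n`, i.e. the opposite orientation of
#' `W`; ranking and selection are always driven by `W` (larger = more
#' relevant).
#'
#' @param ft A `feature_table` of pre-balance training rows (run feature
#'   selection before SMOTE), or a numeric matrix/data frame when `labels`
#'   is given.
#' @param labels Class labels, only when `ft` is a bare matrix.
#' @param k Neighbours per class (default 50); clamped per class (with a
#'   warning) when a class has fewer members.
#' @param m Number of sampled instances; default `NULL` means all rows.
#' @param tau Selection threshold on `W` (default 0.07). Features with
#'   `W >= tau` are marked selected.
#' @param miss_weighting `"class_prior"` or `"uniform"`.
#' @param seed Seed used only when `m` is smaller than the number of rows.
#' @return A `feature_ranking`: data frame with columns `feature`, `weight`
#'   (W), `score` (S), `rank` and `selected`, ordered by decreasing weight.
#' @export
relieff_rank <- function(ft, labels = NULL, k = 50, m = NULL, tau = 0.07,
                         miss_weighting = c("class_prior", "uniform"),
                         seed = 1L) {
  miss_weighting <- match.arg(miss_weighting)
  if (inherits(ft, "feature_table")) {
    x <- as.matrix(ft$x); labels <- ft$labels
  } else {
    x <- as.matrix(ft)
    if (is.null(labels)) stop("labels required for a bare matrix", call. = FALSE)
  }
  n <- nrow(x); M <- ncol(x)
  if (M < 1L) stop("no features to rank", call. = FALSE)
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("ReliefF needs at least two classes", call. = FALSE)
  y <- match(labels, cls) - 1L
  counts <- tabulate(y + 1L, nbins = length(cls))
  if (any(counts - 1L < k)) {
    warning("k = ", k, " clamped for class(es) ",
            paste(cls[counts - 1L < k], collapse = ", "),
            " with fewer members", call. = FALSE)
  }
  prior <- counts / n

  # min-max scale so diffs live in [0, 1]; constant columns become all-zero
  xn <- x
  md <- numeric(M)
  for (f in seq_len(M)) {
    v <- x[, f]
    obs <- v[!is.na(v)]
    rng <- if (length(obs)) diff(range(obs)) else 0
    if (rng > 0) {
      xn[, f] <- (v - min(obs)) / rng
      md[f] <- mean_pairwise_absdiff(xn[!is.na(xn[, f]), f])
    } else {
      xn[, f] <- ifelse(is.na(v), NA_real_, 0)
      md[f] <- 0
    }
  }

  idx <- if (is.null(m) || m >= n) seq_len(n) else {
    withr::with_seed(as.integer(seed), sort(sample.int(n, m)))
  }
  W <- relieff_core(t(xn), y, as.integer(k), as.integer(idx - 1L), md, prior,
                    miss_weighting == "uniform")
  names(W) <- colnames(x)
  ord <- order(-W, seq_along(W))  # ties: keep column order
  ranking <- data.frame(
    feature = colnames(x)[ord],
    weight = as.numeric(W[ord]),
    score = as.numeric(-W[ord]),
    rank = seq_len(M),
    selected = as.numeric(W[ord]) >= tau,
    stringsAsFactors = FALSE)
  structure(ranking, class = c("feature_ranking", "data.frame"),
            k = k, tau = tau, m = length(idx),
            miss_weighting = miss_weighting)
}

# O(n log n) mean of |x_i - x_j| over all pairs, via the sorted-order identity
mean_pairwise_absdiff <- function(v) {
  n <- length(v)
  if (n < 2L) return(0)
  vs <- sort(v)
  s <- sum((2 * seq_len(n) - n - 1) * vs)
  2 * s / (n * (n - 1))
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d features, k = %s, tau = %s, %d selected\n",
              nrow(x), attr(x, "k"), attr(x, "tau"), sum(x$selected)))
  print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more\n", sep = "")
  invisible(x)
}

#' Restrict a feature table to the selected features
#'
#' Keeps the features the ranking marked as selected (weight at or above the
#' threshold), ordered by rank. With `n_top` given, rank-based selection is
#' used instead: the `n_top` highest-weighted features regardless of the
#' threshold.
#'
#' @param ranking A `feature_ranking` from [relieff_rank()].
#' @param ft The `feature_table` to restrict (any split; typically the full
#'   ED or BD so train and eval rows are restricted identically).
#' @param n_top Optional integer overriding threshold selection.
#' @return The restricted `feature_table`.
#' @export
select_features <- function(ranking, ft, n_top = NULL) {
  stopifnot(inherits(ranking, "feature_ranking"),
            inherits(ft, "feature_table"))
  keep <- if (!is.null(n_top)) {
    ranking$feature[seq_len(min(n_top, nrow(ranking)))]
  } else {
    ranking$feature[ranking$selected]
  }
  if (length(keep) == 0L) {
    stop("no feature reaches the selection threshold tau = ",
         attr(ranking, "tau"), "; lower tau or use n_top", call. = FALSE)
  }
  missing_cols <- setdiff(keep, names(ft$x))
  if (length(missing_cols)) {
    stop("ranking features absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ft$x <- ft$x[, keep, drop = FALSE]
  ft
}
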