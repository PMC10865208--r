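#' Balance training classes with SMOTE oversampling
#'
#' Synthetic minority oversampling: every class is brought up to the size of
#' the pre-balance majority class (strategy "auto", one-versus-rest over the
#' minority classes). Each synthetic row is `x + u * (x_nn - x)` for a seed
#' row `x` drawn uniformly (with replacement) from the minority class, one
#' of its `k` nearest same-class neighbours `x_nn` (Euclidean distance), and
#' `u ~ Uniform(0, 1)` — i.e. a point on the segment between two genuine
#' minority samples. Original rows pass through verbatim; synthetic rows are
#' tagged in the `synthetic` field and keep their class label. Binary flag
#' columns are interpolated like any other numeric column, so fractional
#' values may appear; round downstream if 0/1 semantics are required.
#'
#' When a minority class holds fewer than `k + 1` members, `k` is clamped to
#' the class size minus one with a warning.
#'
#' @param ft A `feature_table` of training rows only, with no missing
#'   feature values (fill or drop missing upstream, e.g. [fill_missing()]).
#' @param k Number of nearest same-class neighbours (default 5).
#' @param seed Integer seed; fixed seed gives bit-identical synthetic rows.
#' @return The balanced `feature_table`; every class count equals the
#'   pre-balance majority count.
#' @examples
#' ft <- feature_table(data.frame(a = rnorm(30), b = rnorm(30)),
#'                     labels = rep(c(1, 1, 2), 10))
#' table(smote_balance(ft, k = 3, seed = 1)$labels)
#' @export
smote_balance <- function(ft, k = 5, seed = 1L) {
  stopifnot(inherits(ft, "feature_table"))
  if (!is.null(ft$split) && any(ft$split != "train")) {
    stop("smote_balance expects training rows only", call. = FALSE)
  }
  x <- as.matrix(ft$x)
  if (anyNA(x)) {
    stop("missing feature values present; fill or drop them upstream ",
         "(fill_missing() / complete_cases()) before balancing", call. = FALSE)
  }
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  counts <- table(ft$labels)
  majority <- max(counts)
  syn_x <- list(); syn_lab <- integer(0); syn_id <- character(0)
  withr::with_seed(as.integer(seed), {
    for (cl in as.integer(names(counts))) {
      n_cl <- counts[[as.character(cl)]]
      n_syn <- majority - n_cl
      if (n_syn == 0L) next
      if (n_cl < 2L) {
        stop("class ", cl, " has a single sample; SMOTE needs >= 2",
             call. = FALSE)
      }
      kc <- min(k, n_cl - 1L)
      if (kc < k) {
        warning("class ", cl, ": k clamped from ", k, " to ", kc,
                " (class size ", n_cl, ")", call. = FALSE)
      }
      rows <- which(ft$labels == cl)
      xc <- x[rows, , drop = FALSE]
      d <- as.matrix(stats::dist(xc))
      # per minority row: indices (within class) of its kc nearest neighbours
      nn <- t(vapply(seq_len(n_cl), function(i) {
        ord <- order(d[i, ], seq_len(n_cl))  # index breaks distance ties
        ord <- ord[ord != i]
        ord[seq_len(kc)]
      }, integer(kc)))
      if (kc == 1L) nn <- matrix(nn, ncol = 1L)
      seed_idx <- sample.int(n_cl, n_syn, replace = TRUE)
      nn_pick <- sample.int(kc, n_syn, replace = TRUE)
      u <- stats::runif(n_syn)
      base <- xc[seed_idx, , drop = FALSE]
      neigh <- xc[nn[cbind(seed_idx, nn_pick)], , drop = FALSE]
      syn_x[[length(syn_x) + 1L]] <- base + u * (neigh - base)
      syn_lab <- c(syn_lab, rep(cl, n_syn))
      syn_id <- c(syn_id, sprintf("syn_c%d_%04d", cl, seq_len(n_syn)))
    }
  })
  if (length(syn_x) == 0L) return(ft)
  syn_x <- do.call(rbind, syn_x)
  colnames(syn_x) <- names(ft$x)
  new_x <- rbind(ft$x, as.data.frame(syn_x))
  rownames(new_x) <- NULL
  feature_table(
    new_x,
    labels = c(ft$labels, syn_lab),
    patient_id = c(ft$patient_id, syn_id),
    split = if (is.null(ft$split)) NULL else
      c(ft$split, rep("train", length(syn_lab))),
    condition = ft$condition,
    synthetic = c(ft$synthetic, rep(TRUE, length(syn_lab))))
}
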