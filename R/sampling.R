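## Representative-sample selection, outlier screening, Kennard-Stone
## splitting, and the conditional square-root transform rule.

#' PCA scores with a deterministic sign convention
#'
#' Mean-centered principal component analysis. Each component's sign is
#' fixed so the loading element with the largest magnitude is positive,
#' making repeated runs bit-identical.
#'
#' @param X numeric matrix (samples x variables).
#' @param k number of components.
#' @param scale. unit-variance scale the columns first.
#' @return Scores matrix (n x k) with attributes `loadings` and
#'   `var_explained`.
#' @export
pca_scores <- function(X, k = 2, scale. = FALSE) {
  X <- as.matrix(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  r <- sum(pc$sdev > pc$sdev[1] * 1e-9)
  if (k > r) stop(sprintf("k = %d exceeds the rank (%d) of centered X", k, r),
                  call. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  attr(scores, "loadings") <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  attr(scores, "var_explained") <- pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  scores
}

#' Select samples equally spread across the main variation
#'
#' Partitions the PC1 score range into `m` equal-width bins and picks, per
#' bin, the sample nearest the bin center. The extreme-score samples are
#' always included (they anchor the first and last bins); an empty bin
#' contributes the unselected sample globally nearest its center. Used to
#' pick a representative calibration subset from a larger pool.
#'
#' @param scores PCA scores (first column is used) or a numeric vector.
#' @param m number of samples to select (>= 2).
#' @return Sorted integer vector of `m` distinct sample indices.
#' @export
select_representative <- function(scores, m) {
  s <- if (is.matrix(scores)) scores[, 1] else as.numeric(scores)
  n <- length(s)
  stopifnot_scalar_count(m, "m", 2L)
  if (m > n) stop("m exceeds the number of samples", call. = FALSE)
  if (m == n) return(seq_len(n))
  imin <- which.min(s); imax <- which.max(s)
  if (s[imin] == s[imax]) return(seq_len(m))  # degenerate: all scores equal
  edges <- seq(s[imin], s[imax], length.out = m + 1)
  centers <- (edges[-1] + edges[-(m + 1)]) / 2
  bin <- pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L), m)
  sel <- integer(0)
  reserved <- c(imin, imax)                 # extremes anchor the outer bins
  for (b in seq_len(m)) {
    if (b == 1L) { sel <- c(sel, imin); next }
    if (b == m) { sel <- c(sel, imax); next }
    cand <- setdiff(which(bin == b), c(sel, reserved))
    if (length(cand) == 0) cand <- setdiff(seq_len(n), c(sel, reserved))
    sel <- c(sel, cand[which.min(abs(s[cand] - centers[b]))])
  }
  sort(sel)
}

#' Hotelling-T2 outlier screen with subject escalation
#'
#' Flags samples whose Hotelling T2 on the first two score components
#' exceeds the 99% F-based control limit, then escalates to whole-subject
#' exclusion when more than half of a subject's samples are flagged (so a
#' systematically deviant subject is dropped entirely, as in repeated-visit
#' designs).
#'
#' @param scores score matrix with >= 2 columns (e.g. from [pca_scores()]).
#' @param subject_map subject id per row of `scores`.
#' @param level control-limit confidence level.
#' @return Character vector of excluded subject ids, with attribute
#'   `flagged_samples` (row indices over the T2 limit).
#' @export
detect_outliers <- function(scores, subject_map, level = 0.99) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  n <- nrow(scores)
  if (length(subject_map) != n) stop("subject_map length mismatch", call. = FALSE)
  if (length(unique(subject_map)) < 3) stop("need at least 3 subjects", call. = FALSE)
  v <- apply(scores, 2, stats::var)
  if (all(v < .Machine$double.eps)) {
    flagged <- integer(0)
  } else {
    v[v < .Machine$double.eps] <- Inf       # zero-variance axis carries no signal
    t2 <- rowSums(sweep(sweep(scores, 2, colMeans(scores))^2, 2, v, `/`))
    crit <- 2 * (n - 1) * (n + 1) / (n * (n - 2)) * stats::qf(level, 2, n - 2)
    flagged <- which(t2 > crit)
  }
  excl <- character(0)
  for (s in unique(subject_map)) {
    i <- which(subject_map == s)
    if (sum(i %in% flagged) > length(i) / 2) excl <- c(excl, as.character(s))
  }
  structure(excl, flagged_samples = flagged)
}

#' Kennard-Stone training/test split
#'
#' The classic deterministic max-min algorithm: the first two picks are the
#' pair at maximum Euclidean distance; each subsequent pick maximizes its
#' minimum distance to the already-selected set. Ties break to the lowest
#' index. The test set is the complement.
#'
#' @param X numeric matrix (samples x variables).
#' @param m_train number of training samples (2 <= m_train <= n).
#' @return List with sorted integer vectors `train` and `test`, plus
#'   `order` (the selection order).
#' @export
#' @examples
#' ks <- kennard_stone(matrix(rnorm(244 * 3), 122), 80)
#' lengths(ks[c("train", "test")]) # 80, 42
kennard_stone <- function(X, m_train) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot_scalar_count(m_train, "m_train", 2L)
  if (m_train > n) stop("m_train exceeds the number of samples", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  ## max-distance pair, lowest (i, j) on ties
  flat <- which(D == max(D), arr.ind = TRUE)
  flat <- flat[flat[, 1] < flat[, 2], , drop = FALSE]
  flat <- flat[order(flat[, 1], flat[, 2]), , drop = FALSE]
  sel <- as.integer(flat[1, ])
  mind <- unname(pmin(D[, sel[1]], D[, sel[2]]))
  while (length(sel) < m_train) {
    mind[sel] <- -Inf
    nxt <- as.integer(which.max(mind))      # which.max breaks ties low
    sel <- c(sel, nxt)
    mind <- pmin(mind, unname(D[, nxt]))
  }
  list(train = sort(sel), test = setdiff(seq_len(n), sel), order = sel)
}

#' Decide whether to square-root transform a response
#'
#' Returns `TRUE` when the sample skewness `|g1|` exceeds the threshold
#' (default 1.0), i.e. when the concentration distribution is clearly
#' asymmetric; constant vectors have skewness 0.
#'
#' @param y non-negative concentrations.
#' @param threshold absolute-skewness cutoff.
#' @return Logical flag, with the computed skewness as attribute
#'   `skewness`.
#' @export
decide_sqrt_transform <- function(y, threshold = 1.0) {
  y <- as.numeric(y)
  if (any(y < 0)) stop("concentrations must be non-negative", call. = FALSE)
  g1 <- sample_skewness(y)
  structure(abs(g1) > threshold, skewness = g1)
}
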