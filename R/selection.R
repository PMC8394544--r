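# Fast correlation-based filter (FCBF) feature selection with
# bootstrap voting.

#' Equal-frequency discretization
#'
#' Rank-based binning into (at most) `bins` classes, invariant to any
#' strictly monotone transform of the input.
#'
#' @param x Numeric vector.
#' @param bins Target number of bins (default 10).
#' @return Integer codes in `1..bins`.
#' @export
discretize_ef <- function(x, bins = 10L) {
  r <- rank(x, ties.method = "average")
  codes <- ceiling(r * bins / length(x))
  pmax(1L, pmin(as.integer(bins), as.integer(codes)))
}

entropy_counts <- function(tab) {
  p <- tab / sum(tab)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Symmetrical uncertainty between two discrete variables
#'
#' `SU(x, y) = 2 I(x; y) / (H(x) + H(y))`, in `[0, 1]`; the
#' relevance/redundancy measure FCBF ranks and prunes with. A constant
#' variable carries no information, so `SU = 0` (with a warning).
#'
#' @param x,y Discrete vectors (factors or integer codes) of equal
#'   length.
#' @return SU in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  hx <- entropy_counts(rowSums(tab))
  hy <- entropy_counts(colSums(tab))
  if (hx == 0 || hy == 0) {
    warning("constant variable: symmetrical uncertainty set to 0")
    return(0)
  }
  hxy <- entropy_counts(tab)
  mi <- hx + hy - hxy
  max(0, min(1, 2 * mi / (hx + hy)))
}

#' Fast correlation-based filter
#'
#' Ranks features by `SU(f; y)` (descending, ties broken by column
#' order) and keeps a feature unless some already-kept feature `g`
#' predominates it (`SU(f; g) >= SU(f; y)`), yielding a relevant,
#' non-redundant subset. The relevance threshold is zero: every
#' feature with positive SU enters the ranking.
#'
#' @param features Data frame of discretized features.
#' @param y Discrete label.
#' @return Character vector of selected feature names, in ranking
#'   order.
#' @export
fcbf <- function(features, y) {
  stopifnot(ncol(features) >= 1)
  su_y <- vapply(features, function(f)
    suppressWarnings(symmetrical_uncertainty(f, y)), numeric(1))
  ord <- order(-su_y, seq_along(su_y))
  ord <- ord[su_y[ord] > 0]
  kept <- integer(0)
  for (j in ord) {
    predominated <- FALSE
    for (g in kept) {
      su_fg <- suppressWarnings(symmetrical_uncertainty(features[[j]],
                                                        features[[g]]))
      if (su_fg >= su_y[j]) { predominated <- TRUE; break }
    }
    if (!predominated) kept <- c(kept, j)
  }
  names(features)[kept]
}

#' Bootstrap-voted FCBF feature selection
#'
#' Runs FCBF on `B` bootstrap replicates of the subjects (features
#' discretized within each replicate) and counts, for every feature,
#' how many replicates selected it. Features voted strictly more than
#' `threshold` times form the optimal subset. Deterministic given
#' `seed`.
#'
#' @param table Data frame of numeric features (columns) by subjects
#'   (rows); label columns must not be included.
#' @param y Label vector (factor or discrete), e.g. the four-group
#'   severity label.
#' @param B Number of bootstrap replicates (default 1000).
#' @param threshold Vote threshold; selection requires `votes >
#'   threshold` (default 500).
#' @param bins Discretization bins (default 10).
#' @param seed Integer RNG seed.
#' @return An object of class `selection_result`: `votes` (named
#'   integer), `selected` (character), `B`, `threshold`.
#' @export
bootstrap_select <- function(table, y, B = 1000L, threshold = 500L,
                             bins = 10L, seed = 1L) {
  stopifnot(nrow(table) > 0, ncol(table) > 0)
  if (B < 1) stop("B must be at least 1")
  y <- as.factor(y)
  set.seed(as.integer(seed))
  votes <- setNames(integer(ncol(table)), names(table))
  n <- nrow(table)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    disc <- as.data.frame(lapply(table[idx, , drop = FALSE],
                                 discretize_ef, bins = bins))
    names(disc) <- names(table)
    sel <- fcbf(disc, y[idx])
    votes[sel] <- votes[sel] + 1L
  }
  structure(list(votes = votes,
                 selected = names(votes)[votes > threshold],
                 B = as.integer(B), threshold = as.integer(threshold)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("FCBF bootstrap selection: %d replicates, votes > %d\n",
              x$B, x$threshold))
  v <- sort(x$votes, decreasing = TRUE)
  v <- v[v > 0]
  cat("top votes:\n")
  print(utils::head(v, 10))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
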