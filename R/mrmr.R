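#' Three-state feature discretization for mutual information
#'
#' States are assigned against the feature's mean and population standard
#' deviation: x <= mu - sigma -> 1, x >= mu + sigma -> 3, otherwise 2. The
#' inclusive boundaries with the population SD keep two-valued features
#' (e.g. an indicator) informative rather than collapsing them into the
#' middle state. Constant features map to state 2 everywhere.
#'
#' @param x Numeric vector.
#' @return Integer vector of states in 1..3.
#' @export
discretize_three_state <- function(x) {
  mu <- mean(x)
  sg <- sqrt(mean((x - mu)^2))
  if (sg == 0) return(rep(2L, length(x)))
  out <- rep(2L, length(x))
  out[x <= mu - sg] <- 1L
  out[x >= mu + sg] <- 3L
  out
}

#' Empirical mutual information of two discrete vectors
#'
#' Plug-in estimate in nats from the joint contingency table.
#'
#' @param a,b Vectors (coerced to factors) of equal length.
#' @return Non-negative scalar.
#' @export
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / (px[row(p)[pos]] * py[col(p)[pos]])))
}

#' Greedy minimum-redundancy maximum-relevance feature selection
#'
#' MID scheme: the first feature maximizes mutual information with the
#' outcome; every subsequent feature maximizes
#' I(f; y) - (1 / |S|) * sum over selected s of I(f; s), with features
#' ternarized by [discretize_three_state()] and the outcome used as is.
#' Ties are broken by the canonical feature (column) order.
#'
#' @param table Feature table.
#' @param features Candidate feature columns; default all non-id columns.
#' @param labels Outcome vector; default `table$outcome`.
#' @param k Number of features to select (default 10).
#' @return An object of class `mrmr_selection`: list with `selected` (ordered
#'   names), `relevance`, `redundancy` and `score` per selection step.
#' @export
mrmr_select <- function(table, features = NULL, labels = NULL, k = 10) {
  if (is.null(features)) features <- feature_columns(table)
  if (is.null(labels)) labels <- table$outcome
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  k <- min(k, length(features))
  disc <- lapply(features, function(fn) discretize_three_state(table[[fn]]))
  names(disc) <- features
  y <- as.factor(labels)
  relevance <- vapply(features, function(fn) mutual_information(disc[[fn]], y),
                      numeric(1))
  selected <- character(0)
  rel_out <- red_out <- score_out <- numeric(0)
  remaining <- features
  red_sum <- stats::setNames(numeric(length(features)), features)
  for (step in seq_len(k)) {
    red <- if (length(selected) == 0) stats::setNames(numeric(length(remaining)), remaining)
           else red_sum[remaining] / length(selected)
    score <- relevance[remaining] - red
    best <- remaining[which.max(score)] # which.max: first maximum = canonical order
    selected <- c(selected, best)
    rel_out <- c(rel_out, relevance[best])
    red_out <- c(red_out, unname(red[best]))
    score_out <- c(score_out, unname(score[best]))
    remaining <- setdiff(remaining, best)
    if (length(remaining)) {
      add <- vapply(remaining, function(fn) mutual_information(disc[[fn]], disc[[best]]),
                    numeric(1))
      red_sum[remaining] <- red_sum[remaining] + add
    }
  }
  structure(list(selected = selected, relevance = unname(rel_out),
                 redundancy = red_out, score = score_out,
                 discretization = "three-state at mu +/- population sigma (inclusive)"),
            class = "mrmr_selection")
}

#' @export
print.mrmr_selection <- function(x, ...) {
  cat(sprintf("<mrmr_selection> %d feature(s): %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @rdname mrmr_select
#' @param x An `mrmr_selection`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mrmr_selection <- function(x, ...) {
  tibble::tibble(step = seq_along(x$selected), feature = x$selected,
                 relevance = x$relevance, redundancy = x$redundancy,
                 score = x$score)
}
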