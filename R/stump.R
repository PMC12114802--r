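#' Fit a depth-1 classification tree (decision stump)
#'
#' Exhaustive CART-style search for the single best threshold test
#' separating the positive toxicity class: candidate splits are the
#' midpoints between consecutive distinct sorted values of each feature
#' (`css_mg_per_L`, then `auc_mg_h_per_L`), scored by the decrease in Gini
#' impurity \eqn{1 - \sum_k p_k^2}; the split with the largest decrease
#' wins. Ties are broken in favour of the concentration feature, then the
#' smaller threshold. Leaf probabilities are the positive-class frequencies
#' in each leaf. Minimum leaf size is 1. If only one class is present, a
#' degenerate no-split majority model is returned (not an error).
#'
#' @param rows an `fu_exposure` table (or data.frame with `css_mg_per_L`,
#'   `auc_mg_h_per_L` and `toxicity`).
#' @param positive predicate on the toxicity column defining the positive
#'   class; default: life-threatening toxicity.
#' @param criterion `"gini"` (CART default) or `"information"` (entropy
#'   decrease).
#' @return An object of class `fu_stump`: list with `feature` (`"css"`,
#'   `"auc"`, or `NA` for the degenerate model), `threshold`,
#'   `leaf_counts` (2x2: leaves x (negative, positive)),
#'   `leaf_probabilities` (P(positive) below/above), `impurity_gain`,
#'   `n`, `criterion`.
#' @examples
#' d <- data.frame(css_mg_per_L = c(1, 2, 5, 7, 8),
#'                 auc_mg_h_per_L = c(3, 1, 2, 2.5, 1.5),
#'                 toxicity = c("none", "none", "none",
#'                              "life_threatening", "life_threatening"))
#' fit_stump(d)  # splits css at 6
#' @export
fit_stump <- function(rows, positive = .fu_is_lt,
                      criterion = c("gini", "information")) {
  criterion <- match.arg(criterion)
  if (nrow(rows) < 1) stop("at least one row is required")
  y <- as.logical(positive(rows$toxicity))
  if (anyNA(y)) stop("positive() produced NA labels")
  feats <- list(css = rows$css_mg_per_L, auc = rows$auc_mg_h_per_L)
  n <- length(y)
  npos <- sum(y)

  impurity <- switch(criterion,
    gini = function(pos, tot) {
      p <- pos / tot
      1 - p^2 - (1 - p)^2
    },
    information = function(pos, tot) {
      p <- pos / tot
      h <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log2(q))
      h(p) + h(1 - p)
    })

  degenerate <- function() {
    structure(list(feature = NA_character_, threshold = NA_real_,
                   leaf_counts = matrix(c(n - npos, npos), nrow = 1,
                                        dimnames = list("all",
                                                        c("negative", "positive"))),
                   leaf_probabilities = c(all = npos / n),
                   impurity_gain = 0, n = n, criterion = criterion),
              class = "fu_stump")
  }
  if (npos == 0 || npos == n || n < 2) return(degenerate())

  parent <- impurity(npos, n)
  best <- list(gain = -Inf, feature = NA_character_, threshold = NA_real_)
  for (fname in names(feats)) {
    x <- feats[[fname]]
    ord <- order(x)
    xs <- x[ord]
    ys <- y[ord]
    cum_pos <- cumsum(ys)
    distinct <- which(diff(xs) > 0)  # split after position i
    for (i in distinct) {
      thr <- (xs[i] + xs[i + 1]) / 2
      nl <- i
      pl <- cum_pos[i]
      gain <- parent - (nl / n) * impurity(pl, nl) -
        ((n - nl) / n) * impurity(npos - pl, n - nl)
      better <- gain > best$gain + 1e-12 ||
        (abs(gain - best$gain) <= 1e-12 && is.finite(best$threshold) &&
           fname == best$feature && thr < best$threshold)
      if (better) best <- list(gain = gain, feature = fname, threshold = thr)
    }
  }
  if (!is.finite(best$gain) || best$gain <= 0) return(degenerate())

  x <- feats[[best$feature]]
  below <- x < best$threshold
  counts <- rbind(below = c(sum(!y & below), sum(y & below)),
                  above = c(sum(!y & !below), sum(y & !below)))
  colnames(counts) <- c("negative", "positive")
  probs <- counts[, "positive"] / rowSums(counts)
  structure(list(feature = best$feature, threshold = best$threshold,
                 leaf_counts = counts, leaf_probabilities = probs,
                 impurity_gain = best$gain, n = n, criterion = criterion),
            class = "fu_stump")
}

#' Predict from a decision stump
#'
#' Applies the stump's threshold test and returns, per row, the leaf's
#' majority class and positive-class probability. The degenerate (no-split)
#' model returns its overall majority class for every input.
#'
#' @param object an `fu_stump` from [fit_stump()].
#' @param newdata a data.frame with `css_mg_per_L` / `auc_mg_h_per_L` as
#'   required by the fitted feature.
#' @param ... ignored.
#' @return A `data.frame` with columns `leaf`, `p_positive`, `class`
#'   (logical: predicted positive).
#' @export
predict.fu_stump <- function(object, newdata, ...) {
  if (is.na(object$feature)) {
    p <- unname(object$leaf_probabilities["all"])
    return(data.frame(leaf = "all", p_positive = p, class = p >= 0.5,
                      row.names = NULL)[rep(1, nrow(newdata)), , drop = FALSE])
  }
  col <- paste0(object$feature,
                switch(object$feature, css = "_mg_per_L", auc = "_mg_h_per_L"))
  x <- newdata[[col]]
  if (is.null(x) || anyNA(x))
    stop("newdata lacks values for feature column ", col)
  leaf <- ifelse(x < object$threshold, "below", "above")
  p <- unname(object$leaf_probabilities[leaf])
  data.frame(leaf = leaf, p_positive = p, class = p >= 0.5,
             row.names = NULL)
}

#' @export
print.fu_stump <- function(x, ...) {
  if (is.na(x$feature)) {
    cat(sprintf("decision stump (degenerate): single leaf, P(positive) = %.3f, n = %d\n",
                x$leaf_probabilities["all"], x$n))
  } else {
    cat(sprintf("decision stump: %s %s %.4g (%s gain %.4f, n = %d)\n",
                x$feature, "<", x$threshold, x$criterion, x$impurity_gain, x$n))
    cat(sprintf("  below: P(positive) = %.3f (%d/%d)\n",
                x$leaf_probabilities["below"], x$leaf_counts["below", "positive"],
                sum(x$leaf_counts["below", ])))
    cat(sprintf("  above: P(positive) = %.3f (%d/%d)\n",
                x$leaf_probabilities["above"], x$leaf_counts["above", "positive"],
                sum(x$leaf_counts["above", ])))
  }
  invisible(x)
}

#' Serialize a stump to a JSON report
#'
#' @param model an `fu_stump`.
#' @param path output path; `NULL` returns the JSON string.
#' @param stamp optional named list merged into the report (seed, config
#'   hash, ...).
#' @return `path` (invisibly) or the JSON string.
#' @export
write_stump_json <- function(model, path = NULL, stamp = NULL) {
  rep <- list(feature = model$feature, threshold = model$threshold,
              leaf_counts = as.data.frame(model$leaf_counts),
              leaf_probabilities = as.list(model$leaf_probabilities),
              impurity_gain = model$impurity_gain, n = model$n,
              criterion = model$criterion)
  rep <- c(rep, stamp)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
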