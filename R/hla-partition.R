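# HLA-DQ genotype classification and the conditional-inference
# recursive-partitioning tree that turns the DQ genotype into a five-level
# risk-stratum covariate.
#
# The tree follows the two-stage conditional-inference scheme: at each node a
# per-predictor independence test is run against case/control status
# (chi-square for nominal predictors, a 1-df trend form for ordinal ones),
# the minimum p-value is Bonferroni-adjusted over the predictors tested, and
# splitting stops when the adjusted global test can no longer be rejected at
# alpha. The selected predictor is then split at the binary partition that
# maximizes the two-sample chi-square statistic (cutpoint search for ordinal,
# exhaustive two-set search for nominal predictors).

#' Effective HLA-DQ copy-count profile
#'
#' Converts an unordered DQ haplotype-class pair into effective per-class
#' copy counts. The pair {DQ2.2, DQ7} encodes the DQ2.5 heterodimer in trans
#' and is therefore counted as one effective DQ2.5 copy (and zero DQ2.2/DQ7
#' copies).
#'
#' @param hap1,hap2 Character vectors of haplotype-class labels
#'   (DQ2.5, DQ2.2, DQ7, DQ8, X); recycled to common length.
#' @return Data frame with integer columns `n_dq25`, `n_dq8`, `n_dq22`,
#'   `n_dq7`.
#' @export
dq_profile <- function(hap1, hap2) {
  n <- max(length(hap1), length(hap2))
  hap1 <- rep_len(as.character(hap1), n)
  hap2 <- rep_len(as.character(hap2), n)
  bad <- !(hap1 %in% .HLA_CLASSES) | !(hap2 %in% .HLA_CLASSES)
  if (any(bad)) {
    stop("unknown haplotype label: ",
         paste(unique(c(hap1, hap2)[c(bad, bad)]), collapse = ", "))
  }
  cnt <- function(cl) (hap1 == cl) + (hap2 == cl)
  n25 <- cnt("DQ2.5"); n22 <- cnt("DQ2.2"); n7 <- cnt("DQ7"); n8 <- cnt("DQ8")
  trans <- n22 == 1L & n7 == 1L         # DQ2.2/DQ7 -> one in-trans DQ2.5
  n25[trans] <- 1L
  n22[trans] <- 0L
  n7[trans] <- 0L
  data.frame(n_dq25 = as.integer(n25), n_dq8 = as.integer(n8),
             n_dq22 = as.integer(n22), n_dq7 = as.integer(n7))
}

#' Independence test of one predictor against a binary outcome
#'
#' Quadratic-form test of the node-wise null of independence. For a nominal
#' predictor this is the Pearson chi-square statistic on the predictor-by-
#' outcome table with `levels - 1` degrees of freedom; for an ordinal
#' (numeric or ordered) predictor the 1-df trend form `N * cor(x, y)^2` is
#' used. Degenerate inputs (single observed level, single outcome class)
#' return p = 1 by convention.
#'
#' @param x Predictor: numeric/ordered (ordinal) or factor/character
#'   (nominal).
#' @param y Binary outcome: logical, 0/1 numeric, or a 2-level factor.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
independence_test <- function(x, y) {
  y <- .as_binary(y)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  degenerate <- list(statistic = 0, p_value = 1, df = NA_integer_)
  if (length(y) == 0 || length(unique(y)) < 2) return(degenerate)
  if (is.numeric(x) || is.ordered(x)) {
    xs <- as.numeric(x)
    if (stats::var(xs) == 0) return(degenerate)
    r <- stats::cor(xs, y)
    stat <- length(y) * r^2
    return(list(statistic = stat,
                p_value = stats::pchisq(stat, 1, lower.tail = FALSE), df = 1L))
  }
  x <- factor(x)
  x <- droplevels(x)
  k <- nlevels(x)
  if (k < 2) return(degenerate)
  tab <- table(x, y)
  stat <- .pearson_chisq(tab)
  df <- k - 1L
  list(statistic = stat,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), df = df)
}

.pearson_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

.as_binary <- function(y) {
  if (is.factor(y)) return(as.integer(y == levels(y)[2]))
  if (is.character(y)) {
    u <- sort(unique(y))
    if (length(u) > 2) stop("outcome must be binary")
    return(as.integer(y == u[length(u)]))
  }
  if (is.logical(y)) return(as.integer(y))
  if (!all(y %in% c(0, 1) | is.na(y))) stop("outcome must be binary 0/1")
  as.integer(y)
}

#' Best binary split of a predictor on a binary outcome
#'
#' Searches admissible binary partitions of the observed predictor values
#' and returns the one maximizing the two-sample Pearson chi-square
#' statistic. Ordinal predictors are searched over the `k - 1` cutpoints;
#' nominal predictors over all `2^(k-1) - 1` two-set partitions. Partitions
#' leaving a child smaller than `min_node` are excluded; if none remains, a
#' no-split signal (`NULL`) is returned.
#'
#' @param x Predictor (see [independence_test()]).
#' @param y Binary outcome.
#' @param min_node Minimum admissible child size.
#' @return `NULL`, or a list with `left_values` (observed values routed
#'   left), `statistic`, `p_value`, and for ordinal predictors `cut` (left
#'   means `x <= cut`).
#' @export
best_binary_split <- function(x, y, min_node = 7L) {
  y <- .as_binary(y)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  ordinal <- is.numeric(x) || is.ordered(x)
  vals <- if (ordinal) sort(unique(as.numeric(x))) else sort(unique(as.character(x)))
  k <- length(vals)
  if (k < 2) return(NULL)

  candidates <- if (ordinal) {
    lapply(seq_len(k - 1), function(i) vals[seq_len(i)])
  } else {
    # all 2^(k-1)-1 two-set partitions: bit patterns over vals[-1], with
    # vals[1] always kept on the left to avoid mirror duplicates
    subs <- lapply(0:(2^(k - 1) - 1), function(m) {
      c(vals[1], vals[-1][bitwAnd(m, 2^(seq_len(k - 1) - 1)) > 0])
    })
    subs[vapply(subs, length, 0L) < k]    # drop the full set
  }

  xv <- if (ordinal) as.numeric(x) else as.character(x)
  best <- NULL
  for (lv in candidates) {
    left <- xv %in% lv
    n_l <- sum(left); n_r <- sum(!left)
    if (n_l < min_node || n_r < min_node) next
    tab <- rbind(c(sum(y[left]), n_l - sum(y[left])),
                 c(sum(y[!left]), n_r - sum(y[!left])))
    if (any(colSums(tab) == 0)) next
    stat <- .pearson_chisq(tab)
    if (is.null(best) || stat > best$statistic + 1e-12) {
      best <- list(left_values = lv, statistic = stat,
                   p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
      if (ordinal) best$cut <- max(lv)
    }
  }
  if (!is.null(best) && best$statistic <= 1e-12) return(NULL)
  best
}

#' Tree parameters
#'
#' @param alpha Significance threshold for the Bonferroni-adjusted global
#'   independence test at each node (default 0.05).
#' @param min_node Minimum terminal-node size.
#' @param min_split Minimum node size for a split to be attempted.
#' @return An object of class `tree_params`.
#' @export
tree_params <- function(alpha = 0.05, min_node = 7L, min_split = 20L) {
  stopifnot(alpha > 0, alpha < 1, min_node >= 1, min_split >= 2)
  structure(list(alpha = alpha, min_node = as.integer(min_node),
                 min_split = as.integer(min_split)), class = "tree_params")
}

#' Fit the conditional-inference risk-stratum tree
#'
#' Recursively partitions samples on the supplied predictors: at each node
#' the predictor with the smallest independence-test p-value is selected; if
#' its Bonferroni-adjusted p-value (over the predictors testable at the
#' node) is below `alpha` and an admissible binary partition exists, the
#' node is split; otherwise it becomes a terminal node. Terminal nodes are
#' numbered 1..K in left-to-right order and define the risk strata.
#'
#' @param profiles Data frame of predictors; numeric/ordered columns are
#'   treated as ordinal, factor/character columns as nominal. For the
#'   HLA-DQ application pass the `n_dq25` and `n_dq8` columns of
#'   [dq_profile()].
#' @param y Binary outcome (case/control status).
#' @param params A [tree_params()].
#' @return An object of class `hla_tree` with the nested node structure in
#'   `$root`, terminal-node count in `$n_terminal` and per-terminal labels
#'   in `$labels`.
#' @export
fit_ctree <- function(profiles, y, params = tree_params()) {
  stopifnot(inherits(params, "tree_params"))
  profiles <- as.data.frame(profiles)
  if (nrow(profiles) == 0) stop("empty input")
  y <- .as_binary(y)
  if (length(y) != nrow(profiles)) stop("profiles and outcome lengths differ")

  counter <- new.env()
  counter$next_id <- 1L
  counter$labels <- character()
  root <- .grow_node(profiles, y, params, counter, path = character())
  structure(list(root = root, n_terminal = counter$next_id - 1L,
                 labels = counter$labels,
                 predictors = names(profiles), params = params),
            class = "hla_tree")
}

.grow_node <- function(X, y, params, counter, path) {
  node <- list(n = length(y), cases = sum(y), controls = sum(y == 0))
  make_terminal <- function(node) {
    node$stratum_id <- counter$next_id
    counter$labels[counter$next_id] <-
      if (length(path)) paste(path, collapse = " & ") else "all samples"
    counter$next_id <- counter$next_id + 1L
    node
  }
  if (length(y) < params$min_split) return(make_terminal(node))

  tests <- lapply(X, independence_test, y = y)
  testable <- vapply(seq_along(tests), function(j) {
    xj <- X[[j]]
    length(unique(xj[!is.na(xj)])) >= 2
  }, TRUE) & length(unique(y)) >= 2
  if (!any(testable)) return(make_terminal(node))
  p_raw <- vapply(tests, `[[`, 0, "p_value")
  p_raw[!testable] <- 1
  j_best <- which.min(p_raw)
  p_adj <- min(1, p_raw[j_best] * sum(testable))
  node$selection_p <- p_adj
  if (p_adj >= params$alpha) return(make_terminal(node))

  sp <- best_binary_split(X[[j_best]], y, min_node = params$min_node)
  if (is.null(sp)) return(make_terminal(node))

  var <- names(X)[j_best]
  ordinal <- is.numeric(X[[j_best]]) || is.ordered(X[[j_best]])
  left <- if (ordinal) {
    as.numeric(X[[j_best]]) <= sp$cut
  } else {
    as.character(X[[j_best]]) %in% sp$left_values
  }
  node$split_predictor <- var
  node$split_left_values <- sp$left_values
  node$split_ordinal <- ordinal
  if (ordinal) node$split_cut <- sp$cut
  node$split_statistic <- sp$statistic
  node$split_p <- sp$p_value
  desc <- if (ordinal) {
    c(sprintf("%s<=%g", var, sp$cut), sprintf("%s>=%g", var, sp$cut + 1))
  } else {
    c(sprintf("%s in {%s}", var, paste(sp$left_values, collapse = ",")),
      sprintf("%s in {%s}", var,
              paste(setdiff(unique(as.character(X[[j_best]])), sp$left_values),
                    collapse = ",")))
  }
  node$children <- list(
    .grow_node(X[left, , drop = FALSE], y[left], params, counter,
               c(path, desc[1])),
    .grow_node(X[!left, , drop = FALSE], y[!left], params, counter,
               c(path, desc[2])))
  node
}

#' Assign samples to tree strata
#'
#' Routes each sample through the fitted tree's splits and returns its
#' terminal-node (stratum) id.
#'
#' @param tree An [fit_ctree()] result.
#' @param profiles Data frame with the predictor columns the tree was fitted
#'   on.
#' @return Integer vector of stratum ids (1..K, left-to-right terminal
#'   order), with per-stratum labels in `attr(, "labels")`.
#' @export
assign_strata <- function(tree, profiles) {
  stopifnot(inherits(tree, "hla_tree"))
  profiles <- as.data.frame(profiles)
  miss <- setdiff(tree$predictors, names(profiles))
  if (length(miss)) stop("profiles lack predictor columns: ",
                         paste(miss, collapse = ", "))
  out <- integer(nrow(profiles))
  route <- function(node, idx) {
    if (!is.null(node$stratum_id)) {
      out[idx] <<- node$stratum_id
      return(invisible())
    }
    x <- profiles[[node$split_predictor]][idx]
    left <- if (node$split_ordinal) {
      as.numeric(x) <= node$split_cut
    } else {
      as.character(x) %in% node$split_left_values
    }
    if (anyNA(left)) stop("cannot route sample with missing predictor value")
    route(node$children[[1]], idx[left])
    route(node$children[[2]], idx[!left])
  }
  if (nrow(profiles)) route(tree$root, seq_len(nrow(profiles)))
  attr(out, "labels") <- tree$labels
  out
}

#' Split p-values of a fitted tree
#'
#' @param tree An [fit_ctree()] result.
#' @return Numeric vector with the chi-square p-value of every accepted
#'   binary split, in depth-first order.
#' @export
tree_split_pvalues <- function(tree) {
  stopifnot(inherits(tree, "hla_tree"))
  collect <- function(node) {
    if (is.null(node$children)) return(numeric())
    c(node$split_p, collect(node$children[[1]]), collect(node$children[[2]]))
  }
  collect(tree$root)
}

#' @export
print.hla_tree <- function(x, ...) {
  cat(sprintf("conditional-inference risk-stratum tree: %d terminal nodes\n",
              x$n_terminal))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (!is.null(node$stratum_id)) {
      cat(sprintf("%s* stratum %d [%s]: n=%d (%d cases / %d controls)\n",
                  pad, node$stratum_id, x$labels[node$stratum_id],
                  node$n, node$cases, node$controls))
    } else {
      lv <- if (node$split_ordinal) sprintf("<= %g", node$split_cut) else
        sprintf("in {%s}", paste(node$split_left_values, collapse = ","))
      cat(sprintf("%ssplit %s %s  (chi2 = %.2f, p = %.3g)\n",
                  pad, node$split_predictor, lv, node$split_statistic,
                  node$split_p))
      show(node$children[[1]], indent + 1)
      show(node$children[[2]], indent + 1)
    }
  }
  show(x$root, 0)
  invisible(x)
}
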