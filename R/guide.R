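#' GUIDE-style regression tree
#'
#' Fits a piecewise least-squares regression tree in the GUIDE spirit:
#' at each node the split *variable* is chosen by unbiased chi-square
#' tests — a curvature test (independence of the sign of the node-model
#' residuals and the predictor discretized into quartile bins) and
#' pairwise interaction tests (residual sign against the 2x2 grid of
#' median halves of a predictor pair) — and only the chosen variable's
#' split *point* is then found by exhaustive search minimizing the summed
#' children sum-of-squares.  Leaves carry least-squares linear models on
#' all predictors.  Optionally the grown tree is pruned by
#' cost-complexity with k-fold cross-validation, keeping the smallest
#' tree whose prediction error is within one standard error of the
#' minimum (the 1-SE rule).
#'
#' @param formula model formula, e.g. `intensity ~ dG + Tm + mfe + length`.
#'   All predictors must be numeric; no missing values.
#' @param data data frame containing the variables.
#' @param min_node_size smallest node that may still be split.
#' @param min_bucket smallest allowed child node.
#' @param max_depth depth cap on the grown tree (root = depth 0).
#' @param prune logical: cost-complexity pruning with cross-validation.
#' @param cv_folds number of cross-validation folds for pruning.
#' @param se_factor multiple of the standard error for the pruning rule
#'   (1 = the 1-SE rule).
#' @param node_model `"linear"` (least-squares fit on all predictors,
#'   the default) or `"constant"` (node mean) — the model whose residual
#'   signs feed the selection tests.
#' @param credit importance attribution: `"winner"` (only the selected
#'   variable accrues its chi-square at a split node) or `"all"` (every
#'   predictor accrues its curvature chi-square at every split node).
#' @return an object of class `guide_tree` with `print`, `summary`,
#'   `predict`, `residuals`, `plot` and [importance()] methods.
#'   A constant response yields a root-only tree with
#'   `constant_response = TRUE`.
#' @seealso [importance()], [bootstrap_importance()], [spearman_cor()]
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = runif(400), x2 = runif(400))
#' d$y <- ifelse(d$x1 > 0.5, 3, 0) + rnorm(400, sd = 0.3)
#' fit <- guide_tree(y ~ x1 + x2, d, min_node_size = 40, prune = FALSE)
#' fit
#' importance(fit)
#' @export
guide_tree <- function(formula, data,
                       min_node_size = 50L,
                       min_bucket = max(5L, min_node_size %/% 3L),
                       max_depth = 10L,
                       prune = TRUE, cv_folds = 10L, se_factor = 1,
                       node_model = c("linear", "constant"),
                       credit = c("winner", "all")) {
  node_model <- match.arg(node_model)
  credit <- match.arg(credit)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- as.matrix(mf[, -1L, drop = FALSE])
  if (!is.numeric(y) || !is.numeric(X))
    stop("response and predictors must be numeric", call. = FALSE)
  n <- length(y)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  cfg <- list(min_node_size = as.integer(min_node_size),
              min_bucket = as.integer(min_bucket),
              max_depth = as.integer(max_depth),
              node_model = node_model, credit = credit)
  constant_response <- length(unique(y)) < 2L

  tree <- grow_guide(X, y, cfg,
                     root_only = constant_response)
  obj <- structure(list(nodes = tree,
                        predictors = colnames(X),
                        terms = stats::terms(mf),
                        call = match.call(),
                        config = cfg,
                        n = n,
                        constant_response = constant_response,
                        pruning = NULL),
                   class = "guide_tree")
  if (prune && !constant_response && n_splits(obj$nodes) > 0L) {
    pr <- prune_guide(obj, X, y, cv_folds = cv_folds,
                      se_factor = se_factor)
    obj$nodes <- pr$nodes
    obj$pruning <- pr$trace
  }
  obj
}

# -- growing ---------------------------------------------------------------

node_fit <- function(X, y, node_model) {
  if (node_model == "linear" && nrow(X) > ncol(X) + 1L) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    list(coef = coefs, resid = fit$residuals,
         sse = sum(fit$residuals^2))
  } else {
    m <- mean(y)
    list(coef = c(`(Intercept)` = m, stats::setNames(rep(0, ncol(X)),
                                                     colnames(X))),
         resid = y - m, sse = sum((y - m)^2))
  }
}

chisq_stat <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(0)
  E <- outer(rowSums(counts), colSums(counts)) / tot
  ok <- E > 0
  sum((counts[ok] - E[ok])^2 / E[ok])
}

# curvature test: residual sign x quartile bins of x
curvature_stat <- function(x, pos) {
  br <- unique(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE,
                               type = 7))
  br <- br[br > min(x) & br < max(x)]
  if (!length(br)) return(0)
  bin <- findInterval(x, br, left.open = TRUE) + 1L
  nb <- length(br) + 1L
  counts <- rbind(tabulate(bin[pos], nb), tabulate(bin[!pos], nb))
  chisq_stat(counts)
}

# interaction test: residual sign x quadrants of the (xa, xb) median grid
interaction_stat <- function(xa, xb, pos) {
  qa <- xa > stats::median(xa)
  qb <- xb > stats::median(xb)
  cell <- 1L + qa + 2L * qb
  counts <- rbind(tabulate(cell[pos], 4L), tabulate(cell[!pos], 4L))
  chisq_stat(counts)
}

# exhaustive split-point search: minimize child SSEs of constant models
best_split_point <- function(x, y, min_bucket) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(ys)
  cy <- cumsum(ys); cy2 <- cumsum(ys^2)
  k <- seq_len(n - 1L)
  valid <- xs[k] < xs[k + 1L] & k >= min_bucket & (n - k) >= min_bucket
  if (!any(valid)) return(NULL)
  k <- k[valid]
  sseL <- cy2[k] - cy[k]^2 / k
  sseR <- (cy2[n] - cy2[k]) - (cy[n] - cy[k])^2 / (n - k)
  tot <- sseL + sseR
  best <- k[which.min(tot)]   # ties resolve toward the smaller threshold
  list(point = (xs[best] + xs[best + 1L]) / 2, sse = min(tot))
}

grow_guide <- function(X, y, cfg, root_only = FALSE) {
  p <- ncol(X)
  nodes <- list()
  new_node <- function() length(nodes) + 1L

  grow <- function(idx, depth) {
    id <- new_node()
    Xi <- X[idx, , drop = FALSE]
    yi <- y[idx]
    fit <- node_fit(Xi, yi, cfg$node_model)
    nd <- list(id = id, n = length(idx), depth = depth,
               coef = fit$coef, sse = fit$sse,
               mean = mean(yi),
               leaf = TRUE, split_var = NA_character_,
               split_point = NA_real_, chi_sq = NA_real_,
               curv_stats = NULL, left = NA_integer_, right = NA_integer_)
    nodes[[id]] <<- nd
    if (root_only || length(idx) < cfg$min_node_size ||
        depth >= cfg$max_depth || fit$sse <= 1e-12 ||
        length(unique(yi)) < 2L)
      return(id)
    pos <- fit$resid >= 0
    curv <- vapply(seq_len(p), function(j) curvature_stat(Xi[, j], pos),
                   numeric(1))
    best_int <- 0; int_pair <- NULL
    if (p > 1L) {
      for (a in seq_len(p - 1L)) for (b in seq.int(a + 1L, p)) {
        s <- interaction_stat(Xi[, a], Xi[, b], pos)
        if (s > best_int) { best_int <- s; int_pair <- c(a, b) }
      }
    }
    if (!is.null(int_pair) && best_int > max(curv)) {
      # an interaction won: split on the pair member with more curvature
      win <- int_pair[which.max(curv[int_pair])]
      chi <- best_int
    } else {
      win <- which.max(curv)   # ties resolve toward column order
      chi <- curv[win]
    }
    if (chi <= 0) return(id)
    sp <- best_split_point(Xi[, win], yi, cfg$min_bucket)
    if (is.null(sp)) return(id)
    go_left <- Xi[, win] <= sp$point
    nd$leaf <- FALSE
    nd$split_var <- colnames(X)[win]
    nd$split_point <- sp$point
    nd$chi_sq <- chi
    nd$curv_stats <- stats::setNames(curv, colnames(X))
    nodes[[id]] <<- nd
    left <- grow(idx[go_left], depth + 1L)
    right <- grow(idx[!go_left], depth + 1L)
    nodes[[id]]$left <<- left
    nodes[[id]]$right <<- right
    id
  }
  grow(seq_along(y), 0L)
  nodes
}

n_splits <- function(nodes)
  sum(!vapply(nodes, `[[`, logical(1), "leaf"))

n_leaves <- function(nodes)
  sum(vapply(nodes, `[[`, logical(1), "leaf"))

# leaf ids (in the currently active tree rooted at 1)
active_ids <- function(nodes, id = 1L) {
  nd <- nodes[[id]]
  if (nd$leaf) return(id)
  c(id, active_ids(nodes, nd$left), active_ids(nodes, nd$right))
}

# -- prediction ------------------------------------------------------------

route_predict <- function(nodes, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(id, rows) {
    if (!length(rows)) return()
    nd <- nodes[[id]]
    if (nd$leaf) {
      cf <- nd$coef
      out[rows] <<- drop(cbind(1, X[rows, names(cf)[-1L],
                                    drop = FALSE]) %*% cf)
      return()
    }
    go_left <- X[rows, nd$split_var] <= nd$split_point
    rec(nd$left, rows[go_left])
    rec(nd$right, rows[!go_left])
  }
  rec(1L, seq_len(n))
  out
}

#' @export
predict.guide_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  route_predict(object$nodes, X)
}

#' @export
residuals.guide_tree <- function(object, data, ...) {
  mf <- stats::model.frame(object$terms, data)
  unname(stats::model.response(mf)) - predict(object, data)
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("GUIDE-style regression tree\n")
  cat("  n =", x$n, "|", n_splits(x$nodes), "splits,",
      n_leaves(x$nodes), "leaves\n")
  if (x$constant_response)
    cat("  (constant response: root-only tree)\n")
  if (!is.null(x$pruning))
    cat("  pruned by", nrow(x$pruning), "-step cost-complexity CV\n")
  invisible(x)
}

#' @export
summary.guide_tree <- function(object, ...) {
  print(object)
  cat("\nSplits:\n")
  rec <- function(id, indent) {
    nd <- object$nodes[[id]]
    pad <- strrep("  ", indent)
    if (nd$leaf) {
      cat(sprintf("%s* leaf (n=%d, mean=%.3g)\n", pad, nd$n, nd$mean))
    } else {
      cat(sprintf("%s%s <= %.4g  (n=%d, chi-sq=%.1f)\n", pad,
                  nd$split_var, nd$split_point, nd$n, nd$chi_sq))
      rec(nd$left, indent + 1L)
      rec(nd$right, indent + 1L)
    }
  }
  rec(1L, 0L)
  invisible(object)
}

#' @export
plot.guide_tree <- function(x, ...) {
  # simple dendrogram of split structure
  nodes <- x$nodes
  depth_max <- max(vapply(active_ids(nodes), function(i) nodes[[i]]$depth,
                          numeric(1)))
  pos <- new.env()
  counter <- new.env(); counter$x <- 0
  layout_node <- function(id) {
    nd <- nodes[[id]]
    if (nd$leaf) {
      counter$x <- counter$x + 1
      assign(as.character(id), counter$x, envir = pos)
      return(counter$x)
    }
    xl <- layout_node(nd$left); xr <- layout_node(nd$right)
    xx <- (xl + xr) / 2
    assign(as.character(id), xx, envir = pos)
    xx
  }
  layout_node(1L)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, counter$x + 0.5),
                        ylim = c(-depth_max - 0.5, 0.5))
  draw <- function(id) {
    nd <- nodes[[id]]
    xx <- get(as.character(id), envir = pos)
    yy <- -nd$depth
    if (!nd$leaf) {
      for (ch in c(nd$left, nd$right)) {
        xc <- get(as.character(ch), envir = pos)
        graphics::segments(xx, yy, xc, yy - 1)
        draw(ch)
      }
      graphics::text(xx, yy,
                     sprintf("%s<=%.3g", nd$split_var, nd$split_point),
                     cex = 0.7, pos = 3)
    } else {
      graphics::text(xx, yy, sprintf("n=%d", nd$n), cex = 0.6, pos = 1)
    }
  }
  draw(1L)
  invisible(x)
}

# -- pruning ---------------------------------------------------------------

# weakest-link cost-complexity sequence on a grown tree.
# Returns list(alphas, keep): keep[[k]] = logical over nodes marking
# collapsed (made-leaf) internal nodes for pruning level k.
cc_sequence <- function(nodes) {
  nn <- length(nodes)
  collapsed <- rep(FALSE, nn)
  is_active_leaf <- function(id)
    nodes[[id]]$leaf || collapsed[id]
  subtree_stats <- function(id) {
    if (is_active_leaf(id))
      return(c(sse = nodes[[id]]$sse, leaves = 1))
    l <- subtree_stats(nodes[[id]]$left)
    r <- subtree_stats(nodes[[id]]$right)
    c(sse = l[["sse"]] + r[["sse"]], leaves = l[["leaves"]] + r[["leaves"]])
  }
  alphas <- 0
  keeps <- list(collapsed)
  repeat {
    internal <- which(!vapply(nodes, `[[`, logical(1), "leaf") & !collapsed)
    # only nodes still in the active tree
    act <- active_set(nodes, collapsed)
    internal <- intersect(internal, act)
    if (!length(internal)) break
    g <- vapply(internal, function(id) {
      st <- subtree_stats(id)
      if (st[["leaves"]] <= 1) return(Inf)
      (nodes[[id]]$sse - st[["sse"]]) / (st[["leaves"]] - 1)
    }, numeric(1))
    gmin <- min(g)
    collapsed[internal[g <= gmin + 1e-12]] <- TRUE
    alphas <- c(alphas, max(gmin, 0))
    keeps[[length(keeps) + 1L]] <- collapsed
  }
  list(alphas = alphas, keeps = keeps)
}

active_set <- function(nodes, collapsed, id = 1L) {
  nd <- nodes[[id]]
  if (nd$leaf || collapsed[id]) return(id)
  c(id, active_set(nodes, collapsed, nd$left),
    active_set(nodes, collapsed, nd$right))
}

# apply a collapse mask: collapsed internal nodes become leaves
apply_collapse <- function(nodes, collapsed) {
  for (id in seq_along(nodes)) {
    if (collapsed[id] && !nodes[[id]]$leaf) {
      nodes[[id]]$leaf <- TRUE
      nodes[[id]]$split_var <- NA_character_
      nodes[[id]]$split_point <- NA_real_
      nodes[[id]]$chi_sq <- NA_real_
    }
  }
  nodes
}

# prune a node set to complexity alpha (collapse while weakest link <= alpha)
prune_to_alpha <- function(nodes, alpha) {
  seqc <- cc_sequence(nodes)
  k <- max(which(seqc$alphas <= alpha + 1e-12))
  apply_collapse(nodes, seqc$keeps[[k]])
}

prune_guide <- function(obj, X, y, cv_folds = 10L, se_factor = 1) {
  nodes <- obj$nodes
  cfg <- obj$config
  n <- length(y)
  seqc <- cc_sequence(nodes)
  alphas <- seqc$alphas
  # geometric-mean evaluation points between successive alphas
  eval_a <- sqrt(pmax(alphas, 0) * c(pmax(alphas[-1L], 0), Inf))
  eval_a[length(eval_a)] <- Inf
  eval_a[1L] <- 0
  folds <- sample(rep_len(seq_len(cv_folds), n))
  sqerr <- matrix(NA_real_, n, length(eval_a))
  for (f in seq_len(cv_folds)) {
    test <- folds == f
    sub <- grow_guide(X[!test, , drop = FALSE], y[!test], cfg)
    for (k in seq_along(eval_a)) {
      pk <- if (is.infinite(eval_a[k]))
        apply_collapse(sub, rep(TRUE, length(sub)))
      else prune_to_alpha(sub, eval_a[k])
      pred <- route_predict(pk, X[test, , drop = FALSE])
      sqerr[test, k] <- (y[test] - pred)^2
    }
  }
  cv <- colMeans(sqerr)
  cv_se <- apply(sqerr, 2, stats::sd) / sqrt(n)
  best <- which.min(cv)
  cutoff <- cv[best] + se_factor * cv_se[best]
  chosen <- max(which(cv <= cutoff))   # smallest tree within 1 SE
  pruned <- if (is.infinite(eval_a[chosen]))
    apply_collapse(nodes, rep(TRUE, length(nodes)))
  else prune_to_alpha(nodes, eval_a[chosen])
  trace <- data.frame(alpha = eval_a,
                      n_leaves = vapply(seq_along(eval_a), function(k) {
                        pk <- if (is.infinite(eval_a[k]))
                          apply_collapse(nodes, rep(TRUE, length(nodes)))
                        else prune_to_alpha(nodes, eval_a[k])
                        n_leaves_active(pk)
                      }, numeric(1)),
                      cv_error = cv, cv_se = cv_se)
  attr(trace, "chosen") <- chosen
  list(nodes = pruned, trace = trace)
}

n_leaves_active <- function(nodes) {
  ids <- active_ids(nodes)
  sum(vapply(ids, function(i) nodes[[i]]$leaf, logical(1)))
}

# -- importance ------------------------------------------------------------

#' Predictor importance scores
#'
#' Per-predictor importance of a fitted [guide_tree()]: the chi-square
#' statistic of the variable-selection test at each split node, weighted
#' by the square root of the node size, summed over all split nodes.
#' With `credit = "winner"` (the fit's default) only the variable chosen
#' at a node accrues score there.
#'
#' @param object a fitted model.
#' @param ... passed to methods.
#' @return object of class `importance_table` (a data frame): columns
#'   `predictor`, `score`, `relative` (scaled by the top score; top = 1).
#' @export
importance <- function(object, ...) UseMethod("importance")

#' @rdname importance
#' @export
importance.guide_tree <- function(object, ...) {
  score <- stats::setNames(rep(0, length(object$predictors)),
                           object$predictors)
  ids <- active_ids(object$nodes)
  for (id in ids) {
    nd <- object$nodes[[id]]
    if (nd$leaf) next
    w <- sqrt(nd$n)
    if (object$config$credit == "winner") {
      score[nd$split_var] <- score[nd$split_var] + nd$chi_sq * w
    } else {
      score <- score + nd$curv_stats[names(score)] * w
    }
  }
  out <- data.frame(predictor = names(score), score = unname(score),
                    relative = if (max(score) > 0) unname(score) / max(score)
                               else rep(0, length(score)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Bootstrap importance ranking
#'
#' Robustness protocol for the importance scores: the tree is refitted on
#' `n_rep` random replicates — either subsets of a fixed `fraction`
#' (default 90 %) drawn without replacement, or `size` rows resampled
#' with replacement — and raw importance scores are summarized as means
#' and standard deviations across replicates, finally scaled by the mean
#' of the most important predictor (relative scores; top = 1).
#'
#' @inheritParams guide_tree
#' @param protocol `"subsample"` (90 % without replacement) or
#'   `"resample"` (with replacement; set `size`).
#' @param fraction subset fraction for `"subsample"`.
#' @param size replicate size for `"resample"` (defaults to `nrow(data)`).
#' @param n_rep number of replicates (>= 2).
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @param prune prune each replicate's tree (off by default: the ranking
#'   does not use predicted error, and cross-validated pruning would
#'   dominate the cost of 100 replicates).
#' @param ... further arguments to [guide_tree()].
#' @return an `importance_table` with columns `predictor`, `mean`, `sd`,
#'   `relative`, plus the per-replicate score matrix in attribute
#'   `"replicates"`.
#' @export
bootstrap_importance <- function(formula, data,
                                 protocol = c("subsample", "resample"),
                                 fraction = 0.9, size = NULL,
                                 n_rep = 100L, seed = 1L,
                                 prune = FALSE, ...) {
  protocol <- match.arg(protocol)
  if (n_rep < 2L) stop("n_rep must be >= 2", call. = FALSE)
  n <- nrow(data)
  if (is.null(size)) size <- n
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  scores <- NULL
  for (r in seq_len(n_rep)) {
    idx <- if (protocol == "subsample")
      sample.int(n, max(2L, floor(fraction * n)))
    else sample.int(n, size, replace = TRUE)
    fit <- guide_tree(formula, data[idx, , drop = FALSE], prune = prune, ...)
    imp <- importance(fit)
    v <- stats::setNames(imp$score, imp$predictor)
    if (is.null(scores))
      scores <- matrix(NA_real_, n_rep, length(v),
                       dimnames = list(NULL, sort(names(v))))
    scores[r, ] <- v[colnames(scores)]
  }
  m <- colMeans(scores)
  s <- apply(scores, 2, stats::sd)
  top <- max(m)
  out <- data.frame(predictor = names(m), mean = unname(m), sd = unname(s),
                    relative = if (top > 0) unname(m) / top
                               else rep(0, length(m)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  attr(out, "replicates") <- scores
  attr(out, "protocol") <- protocol
  out
}

#' @export
print.importance_table <- function(x, ...) {
  cat("Predictor importance (relative to top):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.importance_table <- function(x, main = "Relative importance", ...) {
  rel <- x$relative
  bp <- graphics::barplot(rel, names.arg = x$predictor, ylab = "relative score",
                          main = main, ylim = c(0, max(rel) * 1.2), ...)
  if ("sd" %in% names(x) && "mean" %in% names(x) && max(x$mean) > 0) {
    se <- x$sd / max(x$mean)
    graphics::arrows(bp, pmax(0, rel - se), bp, rel + se,
                     angle = 90, code = 3, length = 0.05)
  }
  invisible(x)
}

# -- Spearman --------------------------------------------------------------

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.  The two-sided p-value
#' uses exact permutation enumeration for `n <= 8` and the
#' t-approximation otherwise.
#'
#' @param x,y numeric vectors of equal length (>= 3), non-constant.
#' @return list with `rho` and `p.value`.
#' @examples
#' spearman_cor(1:10, (1:10)^2)$rho  # 1: monotone
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("correlation undefined for a constant vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p.value = min(1, p))
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}
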