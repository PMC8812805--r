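# The eight classifier families behind train_classifier(). Each fit_* takes a
# numeric matrix X and 0/1 labels y and returns a list with everything its
# score_* needs; scores are continuous in [0, 1] (probability-like where the
# family allows) and oriented so larger = more likely positive.

CLASSIFIER_METHODS <- c("RF", "LR", "SVM", "KNN", "DT", "NB", "Adaboost", "ANN")

# ---- CART-style binary trees (shared by DT, RF, Adaboost) ------------------

# Greedy Gini tree on weighted samples. Nodes stored in parallel vectors.
fit_tree <- function(X, y, w = NULL, max_depth = 10L, min_node = 5L,
                     mtry = ncol(X)) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1 / n, n)
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0)
  prob <- numeric(0); leaf <- logical(0)
  new_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- NA_integer_
    right[length(right) + 1L] <<- NA_integer_
    prob[length(prob) + 1L] <<- NA_real_
    leaf[length(leaf) + 1L] <<- TRUE
    length(leaf)
  }
  grow <- function(rows, depth) {
    id <- new_node()
    W <- sum(w[rows])
    p1 <- sum(w[rows] * y[rows]) / W
    prob[id] <<- p1
    if (depth >= max_depth || length(rows) < 2L * min_node ||
        p1 <= 0 || p1 >= 1) {
      return(id)
    }
    feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
    best <- best_split(X, y, w, rows, feats, min_node)
    if (is.null(best)) return(id)
    lrows <- rows[X[rows, best$feature] <= best$threshold]
    rrows <- rows[X[rows, best$feature] > best$threshold]
    lid <- grow(lrows, depth + 1L)
    rid <- grow(rrows, depth + 1L)
    feature[id] <<- best$feature
    threshold[id] <<- best$threshold
    left[id] <<- lid
    right[id] <<- rid
    leaf[id] <<- FALSE
    id
  }
  root <- grow(seq_len(n), 0L)
  list(feature = feature, threshold = threshold, left = left, right = right,
       prob = prob, leaf = leaf, root = root)
}

# Best weighted-Gini split over candidate features; NULL when no split
# improves impurity or respects min_node.
best_split <- function(X, y, w, rows, feats, min_node) {
  W <- sum(w[rows]); W1 <- sum(w[rows] * y[rows])
  gini <- function(w1, wt) 1 - (w1 / wt)^2 - (1 - w1 / wt)^2
  parent <- gini(W1, W) * W
  best <- NULL; best_gain <- 1e-12
  for (f in feats) {
    xf <- X[rows, f]
    o <- order(xf)
    xs <- xf[o]; ws <- w[rows][o]; ys <- y[rows][o]
    cw <- cumsum(ws); cwy <- cumsum(ws * ys)
    m <- length(xs)
    i <- which(xs[-m] < xs[-1])
    counts <- seq_len(m)
    i <- i[counts[i] >= min_node & (m - counts[i]) >= min_node]
    if (!length(i)) next
    wl <- cw[i]; wl1 <- cwy[i]
    wr <- W - wl; wr1 <- W1 - wl1
    child <- gini(wl1, wl) * wl + gini(wr1, wr) * wr
    gain <- parent - child
    k <- which.max(gain)
    if (gain[k] > best_gain) {
      best_gain <- gain[k]
      best <- list(feature = f, threshold = (xs[i[k]] + xs[i[k] + 1L]) / 2)
    }
  }
  best
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  node <- rep(tree$root, n)
  repeat {
    internal <- !tree$leaf[node]
    if (!any(internal)) break
    idx <- which(internal)
    f <- tree$feature[node[idx]]
    th <- tree$threshold[node[idx]]
    goes_left <- X[cbind(idx, f)] <= th
    node[idx] <- ifelse(goes_left, tree$left[node[idx]],
                        tree$right[node[idx]])
  }
  tree$prob[node]
}

# ---- individual families ---------------------------------------------------

fit_lr <- function(X, y, hyper) {
  lambda <- hyper$lambda %||% 0
  Xd <- cbind(1, X)
  if (lambda == 0) {
    df <- data.frame(y = y, X)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    beta <- stats::coef(fit)
    beta[is.na(beta)] <- 0
  } else {
    # ridge-penalised IRLS; intercept unpenalised
    p <- ncol(Xd)
    beta <- rep(0, p)
    pen <- diag(c(0, rep(lambda, p - 1L)))
    for (it in 1:100) {
      eta <- drop(Xd %*% beta)
      mu <- stats::plogis(eta)
      wv <- pmax(mu * (1 - mu), 1e-8)
      z <- eta + (y - mu) / wv
      new_beta <- solve(crossprod(Xd, Xd * wv) + pen, crossprod(Xd, wv * z))
      if (max(abs(new_beta - beta)) < 1e-9) { beta <- new_beta; break }
      beta <- new_beta
    }
    beta <- drop(beta)
  }
  list(beta = unname(beta))
}
score_lr <- function(fit, X) stats::plogis(drop(cbind(1, X) %*% fit$beta))

fit_nb <- function(X, y, hyper) {
  stats_by <- function(cls) {
    Xc <- X[y == cls, , drop = FALSE]
    list(mean = colMeans(Xc), sd = pmax(apply(Xc, 2, stats::sd), 1e-6))
  }
  list(pos = stats_by(1L), neg = stats_by(0L),
       prior_pos = mean(y))
}
score_nb <- function(fit, X) {
  ll <- function(s) rowSums(sapply(seq_len(ncol(X)), function(j) {
    stats::dnorm(X[, j], s$mean[j], s$sd[j], log = TRUE)
  }))
  lp <- ll(fit$pos) + log(fit$prior_pos)
  ln <- ll(fit$neg) + log(1 - fit$prior_pos)
  1 / (1 + exp(ln - lp))
}

fit_knn <- function(X, y, hyper) {
  list(X = X, y = y, k = hyper$k %||% 7L)
}
score_knn <- function(fit, X) {
  k <- min(fit$k, nrow(fit$X))
  nn <- FNN::get.knnx(fit$X, X, k = k)
  rowMeans(matrix(fit$y[nn$nn.index], ncol = k))
}

fit_dt <- function(X, y, hyper) {
  list(tree = fit_tree(X, y,
                       max_depth = hyper$max_depth %||% 10L,
                       min_node = hyper$min_node %||% 5L))
}
score_dt <- function(fit, X) predict_tree(fit$tree, X)

fit_rf <- function(X, y, hyper) {
  ntree <- hyper$ntree %||% 500L
  mtry <- hyper$mtry %||% max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  trees <- lapply(seq_len(ntree), function(b) {
    rows <- sample.int(n, n, replace = TRUE)
    fit_tree(X[rows, , drop = FALSE], y[rows],
             max_depth = hyper$max_depth %||% 12L,
             min_node = hyper$min_node %||% 5L, mtry = mtry)
  })
  list(trees = trees)
}
score_rf <- function(fit, X) {
  votes <- vapply(fit$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X)))
  rowMeans(matrix(votes, nrow = nrow(X)))
}

fit_adaboost <- function(X, y, hyper) {
  rounds <- hyper$rounds %||% 100L
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ysgn <- 2 * y - 1
  for (t in seq_len(rounds)) {
    stump <- fit_tree(X, y, w, max_depth = 1L, min_node = 1L)
    pred <- as.integer(predict_tree(stump, X) >= 0.5)
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ysgn * (2 * pred - 1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}
score_adaboost <- function(fit, X) {
  if (!length(fit$stumps)) return(rep(0.5, nrow(X)))
  F <- numeric(nrow(X))
  for (t in seq_along(fit$stumps)) {
    pred <- 2 * as.integer(predict_tree(fit$stumps[[t]], X) >= 0.5) - 1
    F <- F + fit$alphas[t] * pred
  }
  stats::plogis(2 * F)
}

fit_svm <- function(X, y, hyper) {
  C <- hyper$cost %||% 1
  gamma <- hyper$gamma %||% (1 / ncol(X))
  n <- nrow(X)
  ysgn <- 2 * y - 1
  K <- rbf_kernel(X, X, gamma)
  D <- (ysgn %o% ysgn) * K + diag(1e-6, n)
  Amat <- cbind(ysgn, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(D, rep(1, n), Amat, bvec, meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  sv <- which(a > 1e-6)
  coef <- a[sv] * ysgn[sv]
  free <- which(a > 1e-6 & a < C - 1e-6)
  if (!length(free)) free <- sv
  b <- mean(ysgn[free] - K[free, sv, drop = FALSE] %*% coef)
  list(sv_x = X[sv, , drop = FALSE], coef = coef, b = b, gamma = gamma)
}
score_svm <- function(fit, X) {
  f <- drop(rbf_kernel(X, fit$sv_x, fit$gamma) %*% fit$coef) + fit$b
  stats::plogis(f)
}
rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

fit_ann <- function(X, y, hyper) {
  h <- hyper$hidden %||% 5L
  decay <- hyper$decay %||% 1e-3
  p <- ncol(X); n <- nrow(X)
  npar <- p * h + h + h + 1L
  unpack <- function(theta) {
    W1 <- matrix(theta[1:(p * h)], p, h)
    b1 <- theta[(p * h + 1):(p * h + h)]
    w2 <- theta[(p * h + h + 1):(p * h + 2 * h)]
    b2 <- theta[npar]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  forward <- function(par) {
    A1 <- tanh(sweep(X %*% par$W1, 2, par$b1, `+`))
    f <- drop(A1 %*% par$w2) + par$b2
    list(A1 = A1, p = stats::plogis(f))
  }
  nll <- function(theta) {
    par <- unpack(theta)
    pr <- pmin(pmax(forward(par)$p, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr)) +
      decay * (sum(par$W1^2) + sum(par$w2^2))
  }
  grad <- function(theta) {
    par <- unpack(theta)
    fw <- forward(par)
    dfv <- (fw$p - y) / n
    gw2 <- drop(crossprod(fw$A1, dfv)) + 2 * decay * par$w2
    gb2 <- sum(dfv)
    dZ1 <- (dfv %o% par$w2) * (1 - fw$A1^2)
    gW1 <- crossprod(X, dZ1) + 2 * decay * par$W1
    gb1 <- colSums(dZ1)
    c(as.numeric(gW1), gb1, gw2, gb2)
  }
  theta0 <- stats::rnorm(npar, 0, 0.5)
  opt <- stats::optim(theta0, nll, grad, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10))
  list(par = unpack(opt$par))
}
score_ann <- function(fit, X) {
  A1 <- tanh(sweep(X %*% fit$par$W1, 2, fit$par$b1, `+`))
  stats::plogis(drop(A1 %*% fit$par$w2) + fit$par$b2)
}

# methods whose geometry needs standardised inputs
NEEDS_SCALING <- c("SVM", "KNN", "ANN")

#' Train one screening classifier
#'
#' Fits one of the eight families (random forest, logistic regression, RBF
#' support vector machine, k-nearest neighbours, decision tree, Gaussian
#' naive Bayes, AdaBoost on stumps, one-hidden-layer neural network) on the
#' selected feature columns of a feature table. All randomness is seeded;
#' distance-based families (SVM, KNN, ANN) standardise features using
#' training statistics only.
#'
#' Fixed documented defaults: RF 500 trees with `mtry = floor(sqrt(p))`;
#' KNN k = 7; SVM RBF with `gamma = 1/p`, cost 1; DT depth 10; AdaBoost 100
#' stump rounds; ANN 5 tanh hidden units with weight decay 1e-3; LR is plain
#' maximum likelihood (set `hyper$lambda` for ridge).
#'
#' @param method One of `r paste(CLASSIFIER_METHODS, collapse = ", ")`.
#' @param train_table Feature table with the selected columns and a label
#'   column.
#' @param selected_features Character vector of feature column names.
#' @param hyper Named list of hyperparameter overrides.
#' @param label_column Column holding the class labels.
#' @param positive Positive class value.
#' @param seed Seed applied to all stochastic fitting.
#' @return An object of class `thal_model`; use [predict()] to obtain
#'   continuous scores in `[0, 1]`.
#' @export
train_classifier <- function(method, train_table, selected_features,
                             hyper = list(), label_column = "class_label",
                             positive = POSITIVE_CLASS, seed = 1L) {
  if (!method %in% CLASSIFIER_METHODS) {
    stopf("unknown method '%s'; choose one of %s", method,
          paste(CLASSIFIER_METHODS, collapse = ", "))
  }
  missing <- setdiff(selected_features, names(train_table))
  if (length(missing)) {
    stopf("selected feature(s) absent from table: %s",
          paste(missing, collapse = ", "))
  }
  X <- as.matrix(train_table[, selected_features, drop = FALSE])
  if (anyNA(X)) {
    stopf("masked (NA) feature values in training data; apply the missing-data policy first")
  }
  y <- as_binary_labels(train_table[[label_column]], positive)
  if (length(unique(y)) < 2L) stopf("training data must contain both classes")
  scaling <- NULL
  if (method %in% NEEDS_SCALING) {
    mu <- colMeans(X)
    sdv <- pmax(apply(X, 2, stats::sd), 1e-12)
    X <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
    scaling <- list(mean = mu, sd = sdv)
  }
  fit <- with_seed(seed, switch(method,
    RF = fit_rf(X, y, hyper),
    LR = fit_lr(X, y, hyper),
    SVM = fit_svm(X, y, hyper),
    KNN = fit_knn(X, y, hyper),
    DT = fit_dt(X, y, hyper),
    NB = fit_nb(X, y, hyper),
    Adaboost = fit_adaboost(X, y, hyper),
    ANN = fit_ann(X, y, hyper)
  ))
  structure(list(method = method, fit = fit, features = selected_features,
                 scaling = scaling, positive = positive,
                 label_column = label_column, seed = seed),
            class = "thal_model")
}

#' Score new samples with a trained classifier
#'
#' @param object A `thal_model` from [train_classifier()].
#' @param newdata Feature table containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`, larger = more positive-like.
#' @export
predict.thal_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  if (anyNA(X)) stopf("masked (NA) feature values in prediction data")
  if (!is.null(object$scaling)) {
    X <- sweep(sweep(X, 2, object$scaling$mean), 2, object$scaling$sd, `/`)
  }
  scorer <- switch(object$method,
    RF = score_rf, LR = score_lr, SVM = score_svm, KNN = score_knn,
    DT = score_dt, NB = score_nb, Adaboost = score_adaboost, ANN = score_ann)
  as.numeric(scorer(object$fit, X))
}

#' @export
print.thal_model <- function(x, ...) {
  cat(sprintf("thal_model: %s on %d feature(s) [%s]\n", x$method,
              length(x$features), paste(x$features, collapse = ", ")))
  invisible(x)
}
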