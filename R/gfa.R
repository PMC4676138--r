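#' Genetic function approximation (GFA) QSAR engine
#'
#' Rebuilds linear-plus-spline QSAR models of the kind used for the shipped
#' logBB equation: a genetic algorithm evolves sets of regression terms
#' (plain descriptors and truncated-power splines max(0, knot - x) /
#' max(0, x - knot)), coefficients are fitted by least squares, and fitness
#' is Friedman's lack-of-fit (LOF) score.  Preprocessing includes a
#' k-nearest-neighbour outlier filter and random or diversity-based
#' train/test splitting; validation includes Y-scrambling.
#'
#' @name gfa_qsar
NULL

#' Construct a regression dataset
#'
#' @param x numeric matrix or data frame of descriptors (named columns).
#' @param y numeric response, length nrow(x).
#' @return object of class `regression_dataset`.
#' @export
regression_dataset <- function(x, y) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), !is.null(colnames(x)))
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("missing/non-finite values")
  structure(list(x = x, y = as.numeric(y)), class = "regression_dataset")
}

#' k-nearest-neighbour outlier filter
#'
#' Scores each compound by its mean Euclidean distance (on standardized
#' descriptors) to its k nearest neighbours and removes compounds whose
#' score exceeds mean + z_threshold * sd of all scores.
#'
#' @param data a `regression_dataset`.
#' @param k number of neighbours (1 <= k < n).
#' @param z_threshold z-score cutoff (default 3).
#' @return integer vector of kept row indices.
#' @export
knn_outlier_filter <- function(data, k = 5L, z_threshold = 3) {
  n <- nrow(data$x)
  if (k <= 0L) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of compounds")
  xs <- scale(data$x)
  xs[is.nan(xs)] <- 0  # constant columns
  D <- as.matrix(stats::dist(xs))
  score <- vapply(seq_len(n), function(i) {
    mean(sort(D[i, -i])[seq_len(k)])
  }, 0)
  cutoff <- mean(score) + z_threshold * stats::sd(score)
  which(score <= cutoff | !is.finite(cutoff))
}

#' Train/test split
#'
#' @param data a `regression_dataset`.
#' @param fraction training fraction in (0, 1).
#' @param mode `"random"` or `"diversity"` (greedy MaxMin in standardized
#'   descriptor space selects the training side).
#' @param seed RNG seed (used by the random mode).
#' @return list with `train` and `test` `regression_dataset`s and the
#'   `train_idx` used.
#' @export
split_train_test <- function(data, fraction = 0.8,
                             mode = c("random", "diversity"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(data$x)
  n_train <- round(fraction * n)
  if (mode == "random") {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    idx <- sort(sample(n, n_train))
  } else {
    xs <- scale(data$x)
    xs[is.nan(xs)] <- 0
    D <- as.matrix(stats::dist(xs))
    meand <- rowMeans(D)
    sel <- which.max(meand)
    mind <- D[sel, ]
    mind[sel] <- -Inf
    while (length(sel) < n_train) {
      nxt <- which.max(mind)
      sel <- c(sel, nxt)
      mind <- pmin(mind, D[nxt, ])
      mind[nxt] <- -Inf
    }
    idx <- sort(sel)
  }
  list(
    train = regression_dataset(data$x[idx, , drop = FALSE], data$y[idx]),
    test = regression_dataset(data$x[-idx, , drop = FALSE], data$y[-idx]),
    train_idx = idx
  )
}

#' Friedman lack-of-fit score
#'
#' LOF = (SSE / m) / (1 - (c + d * p) / m)^2 with m samples, c basis
#' functions, p parameters and smoothness factor d.
#'
#' @param sse residual sum of squares.
#' @param n_samples m.
#' @param n_basis c.
#' @param n_params p.
#' @param d smoothness factor (default 1).
#' @export
lof_score <- function(sse, n_samples, n_basis, n_params, d = 1) {
  denom <- 1 - (n_basis + d * n_params) / n_samples
  if (denom <= 0) stop("model too complex for sample size (LOF denominator <= 0)")
  (sse / n_samples) / denom^2
}

# ---- term representation ------------------------------------------------

new_term <- function(desc, kind = "linear", knot = NA_real_) {
  list(desc = desc, kind = kind, knot = knot)
}

term_key <- function(t) paste(t$desc, t$kind, signif(t$knot, 8), sep = "|")

term_label <- function(t) {
  switch(t$kind,
         linear = t$desc,
         spline_below = sprintf("<%.6g - %s>", t$knot, t$desc),
         spline_above = sprintf("<%s - %.6g>", t$desc, t$knot))
}

term_column <- function(t, x) {
  v <- x[, t$desc]
  switch(t$kind,
         linear = v,
         spline_below = pmax(0, t$knot - v),
         spline_above = pmax(0, v - t$knot))
}

design_matrix <- function(terms, x) {
  if (length(terms) == 0L) return(matrix(numeric(nrow(x)), nrow = nrow(x), ncol = 0))
  m <- vapply(terms, term_column, numeric(nrow(x)), x = x)
  matrix(m, nrow = nrow(x),
         dimnames = list(NULL, vapply(terms, term_label, "")))
}

fit_terms <- function(terms, data, d = 1) {
  X <- cbind(`(Intercept)` = 1, design_matrix(terms, data$x))
  fit <- stats::lm.fit(X, data$y)
  if (any(is.na(fit$coefficients))) return(list(lof = Inf, fit = NULL))
  sse <- sum(fit$residuals^2)
  p <- length(terms) + 1L
  lof <- tryCatch(lof_score(sse, length(data$y), length(terms), p, d),
                  error = function(e) Inf)
  list(lof = lof, fit = fit, sse = sse)
}

r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

random_term <- function(x, splines, quantiles) {
  desc <- sample(colnames(x), 1)
  if (splines && stats::runif(1) < 0.5) {
    kind <- sample(c("spline_below", "spline_above"), 1)
    knot <- stats::quantile(x[, desc], stats::runif(1, 0.05, 0.95), names = FALSE)
    new_term(desc, kind, knot)
  } else {
    new_term(desc)
  }
}

dedupe_terms <- function(terms) {
  terms[!duplicated(vapply(terms, term_key, ""))]
}

#' Evolve a GFA model
#'
#' Genetic search over regression term sets: individuals are term lists,
#' crossover exchanges term sublists, mutation adds/removes/replaces a term
#' or redraws a spline knot from the observed 5th-95th descriptor quantile
#' range, coefficients are fitted by least squares and fitness is the LOF
#' score.  Singular fits are penalized, not fatal.  Fully reproducible given
#' the seed.
#'
#' @param data training `regression_dataset`.
#' @param pop_size population size.
#' @param generations number of generations.
#' @param term_bounds c(min, max) number of terms per individual.
#' @param splines allow spline terms.
#' @param p_mutation,p_crossover operator probabilities.
#' @param d LOF smoothness factor.
#' @param seed RNG seed.
#' @return object of class `gfa_model`: terms, coefficients, intercept,
#'   `lof`, `r2_train`.
#' @export
gfa_evolve <- function(data, pop_size = 60L, generations = 40L,
                       term_bounds = c(1L, 6L), splines = TRUE,
                       p_mutation = 0.4, p_crossover = 0.7, d = 1, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  x <- data$x
  max_terms <- min(term_bounds[2], nrow(x) - 3L)
  rand_individual <- function() {
    k <- sample(seq(term_bounds[1], max_terms), 1)
    dedupe_terms(replicate(k, random_term(x, splines), simplify = FALSE))
  }
  pop <- replicate(pop_size, rand_individual(), simplify = FALSE)
  fits <- lapply(pop, fit_terms, data = data, d = d)
  lofs <- vapply(fits, `[[`, 0, "lof")
  mutate <- function(ind) {
    op <- sample(c("add", "remove", "replace", "knot"), 1)
    if (op == "add" && length(ind) < max_terms) {
      ind <- dedupe_terms(c(ind, list(random_term(x, splines))))
    } else if (op == "remove" && length(ind) > term_bounds[1]) {
      ind <- ind[-sample(length(ind), 1)]
    } else if (op == "replace") {
      ind[[sample(length(ind), 1)]] <- random_term(x, splines)
      ind <- dedupe_terms(ind)
    } else {
      k <- which(vapply(ind, function(t) t$kind != "linear", TRUE))
      if (length(k)) {
        i <- if (length(k) == 1L) k else sample(k, 1)
        ind[[i]]$knot <- stats::quantile(x[, ind[[i]]$desc],
                                         stats::runif(1, 0.05, 0.95), names = FALSE)
      }
    }
    ind
  }
  crossover <- function(a, b) {
    if (length(a) == 0L || length(b) == 0L) return(list(a, b))
    ca <- sample(length(a), 1)
    cb <- sample(length(b), 1)
    c1 <- dedupe_terms(c(a[seq_len(ca)], b[-seq_len(cb)]))
    c2 <- dedupe_terms(c(b[seq_len(cb)], a[-seq_len(ca)]))
    trim <- function(ind) {
      if (length(ind) > max_terms) ind[seq_len(max_terms)]
      else if (length(ind) == 0L) list(random_term(x, splines)) else ind
    }
    list(trim(c1), trim(c2))
  }
  tournament <- function() {
    i <- sample(pop_size, 2)
    if (lofs[i[1]] <= lofs[i[2]]) pop[[i[1]]] else pop[[i[2]]]
  }
  for (g in seq_len(generations)) {
    newpop <- list(pop[[which.min(lofs)]])  # elitism
    while (length(newpop) < pop_size) {
      a <- tournament(); b <- tournament()
      kids <- if (stats::runif(1) < p_crossover) crossover(a, b) else list(a, b)
      for (kid in kids) {
        if (stats::runif(1) < p_mutation) kid <- mutate(kid)
        if (length(newpop) < pop_size) newpop[[length(newpop) + 1L]] <- kid
      }
    }
    pop <- newpop
    fits <- lapply(pop, fit_terms, data = data, d = d)
    lofs <- vapply(fits, `[[`, 0, "lof")
  }
  best <- which.min(lofs)
  bf <- fits[[best]]
  coefs <- bf$fit$coefficients
  structure(list(
    terms = pop[[best]],
    intercept = unname(coefs[1]),
    coefficients = coefs[-1],
    lof = lofs[best],
    r2_train = r_squared(data$y, data$y - bf$fit$residuals),
    d = d
  ), class = "gfa_model")
}

#' @export
print.gfa_model <- function(x, ...) {
  cat("GFA model (LOF ", signif(x$lof, 5), ", R2_train ", signif(x$r2_train, 4),
      ")\n  intercept ", signif(x$intercept, 6), "\n", sep = "")
  for (i in seq_along(x$terms)) {
    cat("  ", signif(x$coefficients[i], 6), " * ", term_label(x$terms[[i]]), "\n", sep = "")
  }
  invisible(x)
}

#' Predict from a GFA model
#' @param object a `gfa_model`.
#' @param newdata descriptor matrix or `regression_dataset`.
#' @param ... unused.
#' @export
predict.gfa_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "regression_dataset")) newdata$x else as.matrix(newdata)
  X <- design_matrix(object$terms, x)
  as.numeric(object$intercept + X %*% object$coefficients)
}

#' Convert a GFA model to the logBB parameter representation
#'
#' The result can be written with [write_logbb_model()] and evaluated with
#' [predict_logbb()], so a freshly evolved model is directly usable wherever
#' the shipped equation is.
#'
#' @param model a `gfa_model`.
#' @export
as_logbb_model <- function(model) {
  linear <- data.frame(descriptor = character(), coefficient = numeric())
  spline <- data.frame(descriptor = character(), knot = numeric(),
                       coefficient = numeric(), orientation = character())
  for (i in seq_along(model$terms)) {
    t <- model$terms[[i]]
    co <- unname(model$coefficients[i])
    if (t$kind == "linear") {
      linear <- rbind(linear, data.frame(descriptor = t$desc, coefficient = co))
    } else {
      spline <- rbind(spline, data.frame(
        descriptor = t$desc, knot = t$knot, coefficient = co,
        orientation = if (t$kind == "spline_below") "below" else "above"))
    }
  }
  structure(list(intercept = model$intercept, linear = linear, spline = spline),
            class = "logbb_model")
}

#' Y-scrambling validation
#'
#' Repeats the GFA model build on randomly permuted training responses and
#' reports the distribution of train/test R-squared values; values near zero
#' indicate the unscrambled model is not a chance correlation.
#'
#' @param train,test `regression_dataset`s.
#' @param n_repeats number of scrambles (default 10).
#' @param seed RNG seed.
#' @param ... passed to [gfa_evolve()].
#' @return list with `runs` (data frame `r2_train`, `r2_test`), `mean_train`,
#'   `sd_train`, `mean_test`, `sd_test`, and `sd_defined` (FALSE when
#'   n_repeats = 1; sd reported as 0).
#' @export
y_scramble <- function(train, test, n_repeats = 10L, seed = 1L, ...) {
  stopifnot(n_repeats >= 1L)
  old <- local_seed(seed)
  perms <- replicate(n_repeats, sample(length(train$y)), simplify = FALSE)
  restore_seed(old)
  runs <- do.call(rbind, lapply(seq_len(n_repeats), function(r) {
    ytr <- train$y[perms[[r]]]
    dtr <- regression_dataset(train$x, ytr)
    m <- gfa_evolve(dtr, seed = seed + r, ...)
    data.frame(
      r2_train = m$r2_train,
      r2_test = r_squared(test$y, predict(m, test))
    )
  }))
  sd_defined <- n_repeats > 1L
  list(
    runs = runs,
    mean_train = mean(runs$r2_train),
    sd_train = if (sd_defined) stats::sd(runs$r2_train) else 0,
    mean_test = mean(runs$r2_test),
    sd_test = if (sd_defined) stats::sd(runs$r2_test) else 0,
    sd_defined = sd_defined
  )
}
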