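# Base classifiers with GA-wrapped feature selection.
#
# Six learner families (SVM with RBF kernel, random forest, neural network,
# decision tree, k-nearest neighbours, gradient-boosted trees) are trained on
# the balanced, mRMR-reduced descriptors of one cell line. Feature subsets are
# chosen by a bit-string genetic algorithm whose fitness is the mean balanced
# classification rate (BCR) over stratified bootstrap resamples, scored on the
# out-of-bag compounds. A trained model qualifies for ensemble assembly when
# its accuracy on the untouched external split exceeds 0.8 (strictly).

LEARNERS <- c("SVM", "RF", "NN", "DTREE", "KNN", "XGBoost")

# internal: canonical feature names so formula/data.frame learners accept
# arbitrary fragment labels
.fnames <- function(p) paste0("F", seq_len(p))

.fit_learner <- function(learner, x, y) {
  x <- as.matrix(x)
  colnames(x) <- .fnames(ncol(x))
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(
    learner,
    SVM = e1071::svm(x, yf, kernel = "radial", scale = FALSE),
    RF = randomForest::randomForest(x, yf, ntree = 200),
    NN = nnet::nnet(x, as.numeric(y), size = 3, decay = 0.5, maxit = 200,
                    entropy = TRUE, trace = FALSE, MaxNWts = 100000),
    DTREE = rpart::rpart(cls ~ ., data = data.frame(cls = yf, x,
                                                    check.names = FALSE),
                         method = "class"),
    KNN = list(train = x, y = yf, k = 5),
    XGBoost = xgboost::xgboost(x, yf, nrounds = 50, max_depth = 4,
                               learning_rate = 0.3, nthreads = 1,
                               verbosity = 0),
    stop2("unknown learner id: ", learner)
  )
  structure(list(learner = learner, fit = fit, p = ncol(x)), class = "deqsar_fit")
}

.predict_score <- function(object, x) {
  x <- as.matrix(x)
  colnames(x) <- .fnames(ncol(x))
  fit <- object$fit
  s <- switch(
    object$learner,
    SVM = {
      pr <- predict(fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      m <- if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
      1 / (1 + exp(-m))   # logistic map of the margin
    },
    RF = predict(fit, x, type = "prob")[, "1"],
    NN = as.numeric(predict(fit, x)),
    DTREE = predict(fit, data.frame(x, check.names = FALSE), type = "prob")[, "1"],
    KNN = {
      pr <- class::knn(fit$train, x, fit$y, k = fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    XGBoost = predict(fit, x, type = "response")
  )
  as.numeric(s)
}

.predict_class <- function(object, x) {
  x <- as.matrix(x)
  colnames(x) <- .fnames(ncol(x))
  fit <- object$fit
  cl <- switch(
    object$learner,
    SVM = as.integer(as.character(predict(fit, x))),
    RF = as.integer(as.character(predict(fit, x))),
    NN = as.integer(as.numeric(predict(fit, x)) > 0.5),
    DTREE = as.integer(as.character(
      predict(fit, data.frame(x, check.names = FALSE), type = "class"))),
    KNN = as.integer(as.character(class::knn(fit$train, x, fit$y, k = fit$k))),
    XGBoost = as.integer(as.character(predict(fit, x, type = "class")))
  )
  cl
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity, specificity and the balanced classification rate
#' BCR = ((SN + SP) / 2) * (1 - |SN - SP|), which penalizes models whose
#' sensitivity and specificity diverge.
#'
#' @param y_true,y_pred Binary vectors (0/1) of equal length; `y_true` must
#'   contain both classes.
#' @return An object of class `performance_metrics` with fields `AC`, `SN`,
#'   `SP`, `BCR`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop2("length mismatch")
  y_true <- as.integer(y_true != 0)
  y_pred <- as.integer(y_pred != 0)
  if (!any(y_true == 1)) stop2("SN undefined: no active compounds in y_true")
  if (!any(y_true == 0)) stop2("SP undefined: no inactive compounds in y_true")
  ac <- mean(y_true == y_pred)
  sn <- mean(y_pred[y_true == 1] == 1)
  sp <- mean(y_pred[y_true == 0] == 0)
  bcr <- ((sn + sp) / 2) * (1 - abs(sn - sp))
  structure(list(AC = ac, SN = sn, SP = sp, BCR = bcr),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("AC %.3f  SN %.3f  SP %.3f  BCR %.3f\n", x$AC, x$SN, x$SP, x$BCR))
  invisible(x)
}

#' Bootstrap BCR fitness of a feature mask
#'
#' Repeatedly draws a class-stratified bootstrap resample of the dataset,
#' fits the learner on the resample restricted to the masked features, scores
#' BCR on the out-of-bag compounds, and returns the mean BCR over all
#' resamples. Degenerate draws (out-of-bag set missing a class) are redrawn
#' with bounded retries.
#'
#' @param mask Logical feature mask (at least one `TRUE`).
#' @param dataset A [labeled_dataset()].
#' @param learner One of `r paste(LEARNERS, collapse=", ")`.
#' @param n_splits Number of bootstrap resamples (default 100).
#' @param seed RNG seed; fixed seed gives identical resamples for every mask.
#' @return Mean out-of-bag BCR.
#' @export
bootstrap_bcr_fitness <- function(mask, dataset, learner, n_splits = 100,
                                  seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  mask <- as.logical(mask)
  if (!any(mask)) stop2("mask selects no features")
  xs <- dataset$x[, mask, drop = FALSE]
  y <- dataset$y
  rows1 <- which(y == 1); rows0 <- which(y == 0)
  if (!length(rows1) || !length(rows0)) stop2("both classes required")
  n <- length(y)
  withr::with_seed(seed, {
    bcrs <- vapply(seq_len(n_splits), function(s) {
      for (try in 1:10) {
        b1 <- sample(rows1, length(rows1), replace = TRUE)
        b0 <- sample(rows0, length(rows0), replace = TRUE)
        oob <- setdiff(seq_len(n), unique(c(b1, b0)))
        if (length(oob) >= 2 && any(y[oob] == 1) && any(y[oob] == 0)) {
          tr <- c(b1, b0)
          fit <- .fit_learner(learner, xs[tr, , drop = FALSE], y[tr])
          pred <- .predict_class(fit, xs[oob, , drop = FALSE])
          return(compute_metrics(y[oob], pred)$BCR)
        }
      }
      stop2("could not draw a two-class out-of-bag set in 10 tries")
    }, numeric(1))
    mean(bcrs)
  })
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the reference protocol: a population of 50 bit-string
#' chromosomes evolved for 30 generations, fitness averaged over 100 bootstrap
#' resamples. Operators: tournament selection (size 3), uniform crossover
#' (rate 0.8), per-bit mutation (rate 1/L by default), elitism 1, initial bit
#' probability 0.1 (sparse starting masks).
#'
#' @param population,generations,bootstrap_splits,crossover_rate,mutation_rate,elitism,tournament,init_prob,seed
#'   See description.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 50, generations = 30, bootstrap_splits = 100,
                      crossover_rate = 0.8, mutation_rate = NULL, elitism = 1,
                      tournament = 3, init_prob = 0.1, seed = 1) {
  stopifnot(population >= 2, generations >= 1, bootstrap_splits >= 1)
  structure(list(population = population, generations = generations,
                 bootstrap_splits = bootstrap_splits,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 elitism = elitism, tournament = tournament,
                 init_prob = init_prob, seed = seed),
            class = "ga_config")
}

.mask_key <- function(mask) paste(which(mask), collapse = ",")

#' GA wrapper feature selection
#'
#' Evolves bit-string feature masks over the candidate descriptors of a
#' training dataset; the fitness of a mask is its [bootstrap_bcr_fitness()]
#' (computed with a fixed resampling seed, so all masks see the same splits,
#' and memoised per mask). Elitism guarantees a nondecreasing best-fitness
#' trace. Offspring with empty masks are repaired by switching one random bit
#' on.
#'
#' @param dataset Training [labeled_dataset()] (at least 2 features).
#' @param learner Learner id.
#' @param config A [ga_config()].
#' @return A `ga_result`: list with `mask` (named logical), `features`,
#'   `fitness` (best mean BCR), `trace` (best fitness per generation) and the
#'   configuration.
#' @export
ga_select_features <- function(dataset, learner, config = ga_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  L <- ncol(dataset$x)
  if (L < 2) stop2("dataset must have at least 2 candidate features")
  mut <- config$mutation_rate %||% (1 / L)
  cache <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    key <- .mask_key(mask)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- bootstrap_bcr_fitness(mask, dataset, learner,
                                 n_splits = config$bootstrap_splits,
                                 seed = config$seed)
    cache[[key]] <- val
    val
  }
  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(L, 1)] <- TRUE
    mask
  }
  withr::with_seed(config$seed, {
    pop <- lapply(seq_len(config$population), function(i) {
      repair(runif(L) < config$init_prob)
    })
    trace <- numeric(config$generations)
    best_mask <- NULL
    best_fit <- -Inf
    for (g in seq_len(config$generations)) {
      fits <- vapply(pop, fitness, numeric(1))
      gi <- which.max(fits)
      if (fits[gi] > best_fit) {
        best_fit <- fits[gi]
        best_mask <- pop[[gi]]
      }
      trace[g] <- best_fit
      if (g == config$generations) break
      ord <- order(-fits)
      elite <- pop[ord[seq_len(min(config$elitism, length(pop)))]]
      tourn <- function() {
        cand <- sample.int(length(pop), config$tournament, replace = TRUE)
        pop[[cand[which.max(fits[cand])]]]
      }
      children <- lapply(seq_len(config$population - length(elite)), function(i) {
        p1 <- tourn(); p2 <- tourn()
        child <- if (runif(1) < config$crossover_rate) {
          pickp2 <- runif(L) < 0.5
          ifelse(pickp2, p2, p1)
        } else p1
        flip <- runif(L) < mut
        repair(xor(child, flip))
      })
      pop <- c(elite, children)
    }
    names(best_mask) <- colnames(dataset$x)
    structure(list(mask = best_mask,
                   features = colnames(dataset$x)[best_mask],
                   fitness = best_fit, trace = trace, learner = learner,
                   config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %s: %d features, best BCR %.3f over %d generations\n",
              x$learner, sum(x$mask), x$fitness, length(x$trace)))
  invisible(x)
}

#' Train a base model
#'
#' Fits the learner on the training split restricted to the masked features
#' and evaluates it on the untouched external split. The model qualifies for
#' ensemble assembly iff its external accuracy is strictly greater than 0.8.
#'
#' @param split A `split_pair` from [split_train_external()].
#' @param learner Learner id.
#' @param mask Logical feature mask over the training columns (or a
#'   `ga_result`).
#' @param seed RNG seed for the fit.
#' @return An object of class `base_model` with fields `cell_line`, `learner`,
#'   `features`, `metrics` (external [compute_metrics()]), `qualified`.
#' @export
train_base_model <- function(split, learner, mask, seed = 1) {
  stopifnot(inherits(split, "split_pair"))
  if (inherits(mask, "ga_result")) mask <- mask$mask
  mask <- as.logical(mask)
  if (!any(mask)) stop2("mask selects no features")
  if (!learner %in% LEARNERS) stop2("unknown learner id: ", learner)
  feats <- colnames(split$train$x)[mask]
  fit <- withr::with_seed(seed, {
    .fit_learner(learner, split$train$x[, mask, drop = FALSE], split$train$y)
  })
  pred <- withr::with_seed(seed + 1L, {
    .predict_class(fit, split$external$x[, mask, drop = FALSE])
  })
  metrics <- compute_metrics(split$external$y, pred)
  structure(list(cell_line = split$train$cell_line, learner = learner,
                 features = feats, fit = fit, metrics = metrics,
                 qualified = metrics$AC > 0.8, seed = seed,
                 model_id = paste(split$train$cell_line, learner, sep = "-")),
            class = "base_model")
}

#' @export
print.base_model <- function(x, ...) {
  cat(sprintf("<base_model> %s  (%d features)  external AC %.3f  %s\n",
              x$model_id, length(x$features), x$metrics$AC,
              if (x$qualified) "QUALIFIED" else "not qualified"))
  invisible(x)
}

#' Score compounds with a base model
#'
#' Returns a probability-like activity score in [eps, 1] for every compound
#' in a descriptor table. Fragments absent from the table are imputed as zero
#' counts; learners that emit signed decision values are mapped through the
#' logistic function. Scores are clipped to `[1e-6, 1]` so downstream
#' geometric means stay defined.
#'
#' @param model A [train_base_model()] result.
#' @param table Descriptor matrix with fragment labels as column names.
#' @param seed RNG seed (nearest-neighbour vote ties).
#' @return Numeric score vector, one per row of `table`.
#' @export
score_compounds <- function(model, table, seed = 1) {
  stopifnot(inherits(model, "base_model"))
  n <- nrow(table)
  X <- matrix(0, n, length(model$features))
  hit <- match(model$features, colnames(table))
  ok <- !is.na(hit)
  if (any(ok)) X[, ok] <- as.matrix(table[, hit[ok], drop = FALSE])
  s <- withr::with_seed(seed, .predict_score(model$fit, X))
  pmin(pmax(s, 1e-6), 1)
}
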