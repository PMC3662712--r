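#' Fit a climate envelope model on presence/background data
#'
#' Fits a suitability model predicting the probability that a route is a
#' presence rather than a background point, from the seven climate
#' covariates. Two backends are available:
#'
#' * `"rf"` - a random forest classifier
#'   ([randomForest::randomForest()]), probability of the presence class.
#' * `"maxent"` - a maximum-entropy-style presence/background density-ratio
#'   estimator, implemented as ridge-penalized logistic regression
#'   ([glmnet::glmnet()]) on standardized linear and quadratic features.
#'   With Gaussian climate responses the log odds are exactly quadratic, so
#'   this feature set is well specified; the light ridge penalty
#'   (`lambda`, default 1e-3) keeps fits finite under complete separation.
#'   The background rows of the matrix are the environmental background.
#'
#' Hyperparameters are fixed and documented rather than tuned; fits are
#' deterministic under `seed` for fixed training data.
#'
#' @param matrix A `cem_matrix` from [build_model_matrix()] (or any data
#'   frame with a `label` factor and the seven covariates).
#' @param algorithm `"rf"` or `"maxent"`.
#' @param seed Integer seed controlling the backend's randomness.
#' @param ntree Trees for the random forest backend.
#' @param lambda Ridge penalty for the maxent backend.
#' @return An object of class `cem` with `print`, `summary` and `predict`
#'   methods.
#' @seealso [predict.cem()], [project_surface()]
#' @export
cem <- function(matrix, algorithm = c("rf", "maxent"), seed = 1L,
                ntree = 500L, lambda = 1e-3) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.data.frame(matrix), "label" %in% names(matrix))
  vars <- climate_variables()
  if (!all(vars %in% names(matrix)))
    stop("model matrix must contain the seven climate covariates")
  y <- factor(matrix$label, levels = c("background", "presence"))
  if (nlevels(droplevels(y)) < 2L)
    stop("single-class input: need both presence and background rows")
  if (any(table(y) < 2L))
    stop("need at least 2 rows per class")
  X <- as.matrix(matrix[, vars, drop = FALSE])
  if (anyNA(X)) stop("model matrix contains missing covariates")
  const <- apply(X, 2L, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant covariate(s): ", paste(vars[const], collapse = ", "))

  fit <- switch(algorithm,
    rf = with_seed(seed,
      randomForest::randomForest(x = X, y = y, ntree = ntree)),
    maxent = {
      ctr <- colMeans(X)
      scl <- apply(X, 2L, stats::sd)
      scl[scl == 0] <- 1
      Z <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
      F_ <- cbind(Z, Z^2)
      colnames(F_) <- c(vars, paste0(vars, "_sq"))
      g <- glmnet::glmnet(F_, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
      list(glmnet = g, center = ctr, scale = scl)
    })

  obj <- structure(
    list(algorithm = algorithm, fit = fit, variables = vars,
         n_presence = sum(y == "presence"),
         n_background = sum(y == "background"),
         seed = seed, ntree = ntree, lambda = lambda),
    class = "cem")
  obj$training_prob <- predict(obj, matrix)
  obj$training_label <- y
  obj
}

#' Predict suitability probabilities from a fitted envelope model
#'
#' @param object A [cem()] fit.
#' @param newdata Data frame containing the seven covariates (complete rows
#'   required; row order is preserved).
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict.cem <- function(object, newdata, ...) {
  vars <- object$variables
  if (!all(vars %in% names(newdata)))
    stop("newdata lacks covariate(s): ",
         paste(setdiff(vars, names(newdata)), collapse = ", "))
  X <- as.matrix(newdata[, vars, drop = FALSE])
  if (anyNA(X)) stop("missing covariate values in newdata")
  p <- switch(object$algorithm,
    rf = unname(predict(object$fit, X, type = "prob")[, "presence"]),
    maxent = {
      Z <- sweep(sweep(X, 2L, object$fit$center), 2L, object$fit$scale, `/`)
      F_ <- cbind(Z, Z^2)
      as.numeric(predict(object$fit$glmnet, F_, type = "response"))
    })
  pmin(pmax(p, 0), 1)
}

#' @export
print.cem <- function(x, ...) {
  cat(sprintf("<cem> %s envelope model: %d presences vs %d background, seed %d\n",
              x$algorithm, x$n_presence, x$n_background, x$seed))
  invisible(x)
}

#' @export
summary.cem <- function(object, ...) {
  tr_auc <- auc(object$training_prob[object$training_label == "presence"],
                object$training_prob[object$training_label == "background"])
  cat(sprintf(
    "Climate envelope model (%s)\n  presences: %d  background: %d\n  training AUC: %.3f\n",
    object$algorithm, object$n_presence, object$n_background, tr_auc))
  invisible(list(algorithm = object$algorithm, training_auc = tr_auc))
}

#' Project a fitted model onto a climate stack
#'
#' Predicts the suitability probability of every grid cell; cells with any
#' missing covariate stay missing.
#'
#' @param model A [cem()] fit.
#' @param stack A [climate_stack()].
#' @return An object of class `suitability_surface`: probability matrix on
#'   the stack's geometry plus `period` and `algorithm` tags.
#' @export
project_surface <- function(model, stack) {
  stopifnot(inherits(model, "cem"), inherits(stack, "climate_stack"))
  tab <- stack_cell_table(stack)
  p <- rep(NA_real_, nrow(tab))
  ok <- stats::complete.cases(tab)
  if (any(ok)) p[ok] <- predict(model, tab[ok, , drop = FALSE])
  ref <- stack$grids[[1L]]
  suitability_surface(matrix(p, nrow(ref$values), ncol(ref$values)),
                      ref, period = stack$period, algorithm = model$algorithm)
}

## cells x 7 covariate data.frame for a stack (column-major cell order)
stack_cell_table <- function(stack) {
  as.data.frame(lapply(stack$grids, function(g) as.vector(g$values)))
}

#' Construct a suitability surface
#'
#' @param values Probability matrix in `[0, 1]` (NA allowed).
#' @param geometry A [climate_grid()] supplying cell size and origin.
#' @param period,algorithm Provenance tags.
#' @return Object of class `suitability_surface`.
#' @export
suitability_surface <- function(values, geometry, period = "t1",
                                algorithm = "rf") {
  values <- as.matrix(values)
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  structure(list(values = values, cell_size = geometry$cell_size,
                 origin = geometry$origin, period = period,
                 algorithm = algorithm),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat(sprintf("<suitability_surface> %s @ %s: %d x %d cells, range [%.3f, %.3f]\n",
              x$algorithm, x$period, nrow(x$values), ncol(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}
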