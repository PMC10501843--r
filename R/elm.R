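#' Extreme learning machine with random hidden layer
#'
#' A single-hidden-layer feed-forward network whose hidden parameters
#' (input weights \eqn{c_i} and biases \eqn{e_i}) are drawn once at
#' random and never trained.  Only the output weight vector \eqn{w} is
#' fitted, here by solving the norm-constrained least-squares problem
#' \deqn{\min_{\omega \in C} \|H\omega - R\|_2^2}
#' posed as a split feasibility problem, where \eqn{H} is the hidden-layer
#' output matrix, \eqn{R} the target vector, and \eqn{C} an L1 or L2
#' norm ball limiting the weight magnitude against overfitting.
#'
#' Hidden weights and biases are drawn uniformly on \eqn{[-1, 1]} from
#' the stated seed, so a model is reproducible from `(n_features,
#' n_hidden, seed)`.
#'
#' @param n_features number of input features d.
#' @param n_hidden number of hidden nodes M (the study used M = 160).
#' @param activation hidden activation; only `"sigmoid"` is provided,
#'   whose outputs lie strictly in (0, 1).
#' @param seed integer seed for the hidden parameters.
#' @return an object of class `elm` (untrained: `out_weight` is `NULL`).
#' @export
elm_model <- function(n_features, n_hidden = 160L,
                      activation = c("sigmoid"), seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(n_features >= 1, n_hidden >= 1)
  rng <- with_seed(seed, list(
    W = matrix(stats::runif(n_hidden * n_features, -1, 1), nrow = n_hidden),
    b = stats::runif(n_hidden, -1, 1)))
  structure(
    list(hidden_weights = rng$W, hidden_bias = rng$b,
         n_hidden = as.integer(n_hidden), n_features = as.integer(n_features),
         activation = activation, seed = as.integer(seed),
         out_weight = NULL, scaling = NULL, run = NULL),
    class = "elm")
}

#' Hidden-layer output matrix
#'
#' The N x M matrix \eqn{H} with entry \eqn{(s, i) =
#' V(\langle c_i, \mu_s\rangle + e_i)} for activation \eqn{V}; the design
#' matrix of the output-weight least-squares problem.
#'
#' @param model an [elm_model()].
#' @param features numeric matrix, samples in rows.
#' @return numeric matrix N x M.
#' @export
hidden_matrix <- function(model, features) {
  stopifnot(inherits(model, "elm"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(features), model$n_features))
  Z <- features %*% t(model$hidden_weights)
  Z <- sweep(Z, 2L, model$hidden_bias, "+")
  stats::plogis(Z)
}

#' Train the output weights as a constrained least-squares SFP
#'
#' Encodes \eqn{\min_{\omega \in C} \|H\omega - R\|^2} as the split
#' feasibility problem with operator \eqn{A = H}, domain set
#' \eqn{C = \{\|\omega\|_1 \le \gamma\}} or
#' \eqn{\{\|\omega\|_2^2 \le \gamma\}}, and target set the singleton
#' \eqn{Q = \{R\}} described by \eqn{q(\omega) = \tfrac12\|\omega -
#' R\|^2}, then runs the chosen projection solver from the zero vector
#' (feasible for either ball).  The final iterate becomes the output
#' weight.
#'
#' @param model an [elm_model()].
#' @param features numeric matrix N x d of training inputs.
#' @param targets numeric vector of length N with values in \{0, 1\}
#'   (malignant/positive = 1).
#' @param constraint `"l2_ball"` (\eqn{\|\omega\|_2^2 \le \gamma}) or
#'   `"l1_ball"` (\eqn{\|\omega\|_1 \le \gamma}).
#' @param gamma positive norm budget (the study used \eqn{\gamma = 7}
#'   for L1 and \eqn{\gamma = 17} for L2).
#' @param method,config solver selection, see [sfp_solve()].
#' @param standardize center/scale features before the hidden layer
#'   (scaling is stored and re-applied at prediction).
#' @param store_iterates keep the solver's iterate history (needed for
#'   learning curves).
#' @return the trained `elm` (fields `out_weight`, `scaling`, `run`).
#' @export
elm_train <- function(model, features, targets,
                      constraint = c("l2_ball", "l1_ball"), gamma = 17,
                      method = "imrcqm", config = solver_config(),
                      standardize = TRUE, store_iterates = TRUE) {
  stopifnot(inherits(model, "elm"))
  constraint <- match.arg(constraint)
  features <- as.matrix(features)
  targets <- as.numeric(targets)
  stopifnot(nrow(features) == length(targets), !anyNA(features),
            !anyNA(targets), gamma > 0)

  scaling <- NULL
  if (standardize) {
    ctr <- colMeans(features)
    scl <- apply(features, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    features <- sweep(sweep(features, 2L, ctr, "-"), 2L, scl, "/")
    scaling <- list(center = ctr, scale = scl)
  }

  H <- hidden_matrix_raw(model, features)
  Cset <- if (constraint == "l2_ball") cc_l2_ball(gamma) else cc_l1_ball(gamma)
  prob <- sfp_instance(H, Cset, cc_singleton(targets))
  run <- sfp_solve(prob, method = method, config = config,
                   omega0 = numeric(ncol(H)), store_iterates = store_iterates)

  model$out_weight <- run$omega
  model$scaling <- scaling
  model$constraint <- list(kind = constraint, gamma = gamma)
  model$run <- run
  model
}

# hidden matrix without re-checking class/dims (features already scaled)
hidden_matrix_raw <- function(model, features) {
  Z <- features %*% t(model$hidden_weights)
  Z <- sweep(Z, 2L, model$hidden_bias, "+")
  stats::plogis(Z)
}

#' Predict from a trained ELM
#'
#' Raw outputs are \eqn{O = H w}; class labels use the threshold rule
#' `label 1 iff O >= threshold` (ties go to the positive class).
#'
#' @param object a trained `elm`.
#' @param newdata numeric matrix of features.
#' @param type `"class"` for 0/1 labels or `"response"` for raw outputs.
#' @param threshold decision threshold for `"class"` (default 0.5).
#' @param ... unused.
#' @return numeric vector of labels or raw outputs.
#' @export
predict.elm <- function(object, newdata, type = c("class", "response"),
                        threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.null(object$out_weight))
    stop("model is untrained: call elm_train() first")
  newdata <- as.matrix(newdata)
  if (!is.null(object$scaling))
    newdata <- sweep(sweep(newdata, 2L, object$scaling$center, "-"),
                     2L, object$scaling$scale, "/")
  O <- drop(hidden_matrix_raw(object, newdata) %*% object$out_weight)
  if (type == "response") O else as.numeric(O >= threshold)
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm> %d hidden nodes, %d features, %s activation, seed %d\n",
              x$n_hidden, x$n_features, x$activation, x$seed))
  if (is.null(x$out_weight)) {
    cat("  untrained\n")
  } else {
    cat(sprintf("  trained: %s gamma=%g via %s (%d iterations)\n",
                x$constraint$kind, x$constraint$gamma, x$run$method,
                x$run$n_iter))
  }
  invisible(x)
}

#' Serialize / restore an ELM as plain text (JSON)
#'
#' Stores the seed, architecture, constraint, scaling and output weight;
#' hidden parameters are regenerated from the seed on read.
#'
#' @param model a trained or untrained `elm`.
#' @param path file path.
#' @return `path` (write) or the restored `elm` (read).
#' @export
write_elm <- function(model, path) {
  stopifnot(inherits(model, "elm"))
  jsonlite::write_json(
    list(n_features = model$n_features, n_hidden = model$n_hidden,
         activation = model$activation, seed = model$seed,
         out_weight = model$out_weight, scaling = model$scaling,
         constraint = model$constraint),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- elm_model(s$n_features, s$n_hidden, s$activation, s$seed)
  if (!is.null(s$out_weight)) m$out_weight <- as.numeric(s$out_weight)
  if (!is.null(s$scaling))
    m$scaling <- list(center = as.numeric(s$scaling$center),
                      scale = as.numeric(s$scaling$scale))
  if (!is.null(s$constraint)) m$constraint <- s$constraint
  m
}
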