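# Classifier registry. A family is a contract: fit(x, y, params, seed) returns
# a fitted model handle, predict(model, x) returns integer 0/1 labels. LIG
# families run with default settings (empty params); FT families carry a
# default hyperparameter grid searched during training. The registry is
# deliberately open: any classifier honouring the contract can enlist.

the_registry <- new.env(parent = emptyenv())

#' Register a classifier family
#'
#' @param name Registry name.
#' @param phase `"lig"` (parameter-free) or `"ft"` (grid-tuned).
#' @param fit Function `(x, y, params, seed) -> model`; `x` is a numeric
#'   matrix (samples x features), `y` an integer 0/1 vector, `params` a named
#'   list (empty for LIG), `seed` an integer.
#' @param predict Function `(model, x) -> integer 0/1 vector`.
#' @param default_grid Named list of parameter value vectors (FT only);
#'   the search grid is their Cartesian product.
#' @return `name`, invisibly.
#' @export
register_classifier <- function(name, phase = c("lig", "ft"), fit, predict,
                                default_grid = NULL) {
  phase <- match.arg(phase)
  if (phase == "ft" && is.null(default_grid)) {
    abort("FT families must declare a default_grid.")
  }
  assign(name, list(name = name, phase = phase, fit = fit, predict = predict,
                    default_grid = default_grid),
         envir = the_registry)
  invisible(name)
}

#' List registered classifier families
#'
#' @return A tibble with columns `family`, `phase` and `grid_size` (NA for
#'   parameter-free families).
#' @export
classifier_families <- function() {
  nms <- sort(ls(the_registry))
  purrr::map_dfr(nms, function(nm) {
    f <- get(nm, envir = the_registry)
    tibble(family = nm, phase = f$phase,
           grid_size = if (is.null(f$default_grid)) NA_integer_ else
             as.integer(prod(lengths(f$default_grid))))
  })
}

get_family <- function(name, phase = NULL) {
  if (!exists(name, envir = the_registry)) {
    abort(sprintf("unknown classifier family '%s'.", name))
  }
  fam <- get(name, envir = the_registry)
  if (!is.null(phase) && fam$phase != phase) {
    abort(sprintf("family '%s' is registered for phase '%s', not '%s'.",
                  name, fam$phase, phase))
  }
  fam
}

as_factor_y <- function(y) factor(y, levels = c(0L, 1L))
from_factor_y <- function(p) as.integer(as.character(p))

safe_frame <- function(x) {
  df <- as.data.frame(x)
  names(df) <- paste0(".f", seq_len(ncol(df)))
  df
}

# ---- discrete AdaBoost.M1 over rpart stumps ---------------------------------
# Written in-package: boosting with depth-1 CART weak learners and the
# standard log-odds member weights; deterministic given its inputs.
fit_adaboost_stumps <- function(x, y, n_rounds = 50) {
  df <- safe_frame(x)
  df$.y <- as_factor_y(y)
  n <- length(y)
  w <- rep(1 / n, n)
  ys <- ifelse(y == 1L, 1, -1)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- from_factor_y(stats::predict(fit, df, type = "class"))
    hs <- ifelse(pred == 1L, 1, -1)
    err <- sum(w * (hs != ys))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ys * hs)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  structure(list(stumps = stumps, alphas = alphas), class = "adaboost_stumps")
}

predict_adaboost_stumps <- function(model, x) {
  df <- safe_frame(x)
  score <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- from_factor_y(stats::predict(model$stumps[[m]], df, type = "class"))
    score <- score + model$alphas[m] * ifelse(pred == 1L, 1, -1)
  }
  as.integer(score > 0)
}

# ranger resolves tied tree votes with R's global RNG at predict time; pin it
# so predictions are a pure function of (model, data).
predict_ranger_det <- function(model, x) {
  with_seed(190417L, {
    from_factor_y(stats::predict(model, data = x,
                                 num.threads = 1)$predictions)
  })
}

# ---- registry bootstrap -----------------------------------------------------
register_default_families <- function() {
  # LIG: parameter-free tree family trio
  register_classifier(
    "decision_tree", "lig",
    fit = function(x, y, params, seed) {
      df <- safe_frame(x); df$.y <- as_factor_y(y)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(xval = 0))
    },
    predict = function(model, x) {
      from_factor_y(stats::predict(model, safe_frame(x), type = "class"))
    }
  )
  register_classifier(
    "adaboost", "lig",
    fit = function(x, y, params, seed) fit_adaboost_stumps(x, y),
    predict = function(model, x) predict_adaboost_stumps(model, x)
  )
  register_classifier(
    "extra_trees", "lig",
    fit = function(x, y, params, seed) {
      ranger::ranger(x = x, y = as_factor_y(y), splitrule = "extratrees",
                     num.trees = 500, num.threads = 1, seed = seed)
    },
    predict = predict_ranger_det
  )
  # FT: grid-tuned families
  register_classifier(
    "random_forest", "ft",
    fit = function(x, y, params, seed) {
      ranger::ranger(x = x, y = as_factor_y(y),
                     num.trees = params$num_trees %||% 500,
                     splitrule = params$splitrule %||% "gini",
                     replace = params$bootstrap %||% TRUE,
                     sample.fraction = if (isTRUE(params$bootstrap %||% TRUE)) 1 else 0.632,
                     num.threads = 1, seed = seed)
    },
    predict = predict_ranger_det,
    default_grid = list(
      num_trees = c(100, 300, 500, 800, 1000),
      splitrule = c("gini", "hellinger"),
      bootstrap = c(TRUE, FALSE)
    )
  )
  register_classifier(
    "svm", "ft",
    fit = function(x, y, params, seed) {
      e1071::svm(x = x, y = as_factor_y(y),
                 cost = params$cost %||% 1,
                 gamma = params$gamma %||% (1 / ncol(x)),
                 kernel = params$kernel %||% "radial", scale = FALSE)
    },
    predict = function(model, x) {
      from_factor_y(stats::predict(model, x))
    },
    default_grid = list(
      cost = c(0.001, 0.01, 0.1, 1, 10),
      gamma = c(0.001, 0.01, 0.1, 1),
      kernel = c("radial", "linear")
    )
  )
  register_classifier(
    "mlp", "ft",
    fit = function(x, y, params, seed) {
      with_seed(seed, {
        nnet::nnet(x = x, y = cbind(neg = 1 - y, pos = y),
                   size = params$size %||% 25,
                   decay = params$decay %||% 1e-4,
                   softmax = TRUE, maxit = 150, trace = FALSE,
                   MaxNWts = 100000)
      })
    },
    predict = function(model, x) {
      as.integer(max.col(stats::predict(model, x),
                         ties.method = "first") == 2L)
    },
    default_grid = list(
      decay = c(1, 0.1, 0.001, 1e-4, 1e-5, 1e-6, 1e-7, 1e-8),
      size = c(5, 25, 100)
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.onLoad <- function(libname, pkgname) {
  register_default_families()
}
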