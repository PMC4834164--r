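# Model serialization: a single self-describing JSON file with a versioned
# header, config echo, and per-learner dual coefficients. Random Forest
# models (native C structures) fall back to RDS.

MODEL_FORMAT_VERSION <- 1L

#' Write / read a fitted screening model
#'
#' `adaboost_svm` and `plain_svm` models are written as self-describing JSON
#' (format header, package version, config echo, support vectors and dual
#' coefficients at full precision); `pharm_rf` models are written as RDS.
#'
#' @param model A fitted `adaboost_svm`, `plain_svm` or `pharm_rf`.
#' @param path Output file; `.json` or `.rds` is appended if absent.
#' @return `read_model()` returns the model; the writer returns the path
#'   invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "pharm_rf")) {
    if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
    saveRDS(model, path)
    return(invisible(path))
  }
  if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
  header <- list(format = "pharmboost_model", format_version = MODEL_FORMAT_VERSION,
                 package_version = as.character(utils::packageVersion("pharmboost")),
                 type = class(model)[1L])
  ser_svm <- function(m) {
    list(n_sv_rows = nrow(m$sv_x), n_sv_cols = ncol(m$sv_x),
         sv_x = as.numeric(m$sv_x), coef = as.numeric(m$coef), b = m$b,
         sigma = m$sigma, cost = m$cost)
  }
  body <- if (inherits(model, "adaboost_svm")) {
    list(config = unclass(model$config), mode = model$mode,
         n_features = model$n_features,
         feature_names = as.list(model$feature_names),
         train_error = model$train_error, error_bound = model$error_bound,
         layers = model$layers,
         learners = lapply(model$learners, function(lr) {
           list(alpha = lr$alpha, epsilon = lr$epsilon, sigma = lr$sigma,
                iteration = lr$iteration, n_train = lr$n_train,
                feature = lr$feature, svm = ser_svm(lr$model))
         }))
  } else if (inherits(model, "plain_svm")) {
    c(ser_svm(model), list(sign_to_active = model$sign_to_active,
                           cross_accuracy = model$cross_accuracy,
                           n_sv = model$n_sv))
  } else {
    stopf("cannot serialize model of class %s", class(model)[1L])
  }
  jsonlite::write_json(c(header, body), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "pharmboost_model")) {
    stopf("not a pharmboost model file: %s", path,
          class = "pharmboost_input_error")
  }
  num <- function(x) as.numeric(unlist(x))
  de_svm <- function(s) {
    structure(list(sv_x = matrix(num(s$sv_x), nrow = s$n_sv_rows,
                                 ncol = s$n_sv_cols),
                   coef = num(s$coef), b = s$b, sigma = s$sigma,
                   cost = s$cost),
              class = "weighted_svm")
  }
  if (obj$type == "plain_svm") {
    m <- de_svm(obj)
    return(structure(list(sv_x = m$sv_x, coef = m$coef, b = m$b,
                          sign_to_active = obj$sign_to_active,
                          sigma = obj$sigma, cost = obj$cost,
                          cross_accuracy = obj$cross_accuracy %||% NA_real_,
                          n_sv = obj$n_sv),
                     class = "plain_svm"))
  }
  if (obj$type == "adaboost_svm") {
    cfg <- obj$config
    cfg$signal_channels <- NULL
    cfg <- do.call(boost_config, cfg)
    learners <- lapply(obj$learners, function(lr) {
      list(model = de_svm(lr$svm), alpha = lr$alpha, epsilon = lr$epsilon,
           sigma = lr$sigma, iteration = lr$iteration, n_train = lr$n_train,
           feature = if (is.null(lr$feature) || is.na(lr$feature)) NA_integer_
                     else as.integer(lr$feature))
    })
    return(structure(list(learners = learners, config = cfg, mode = obj$mode,
                          layers = obj$layers,
                          n_features = obj$n_features,
                          feature_names = unlist(obj$feature_names),
                          train_error = obj$train_error,
                          error_bound = obj$error_bound),
                     class = "adaboost_svm"))
  }
  stopf("unknown model type '%s'", obj$type, class = "pharmboost_input_error")
}
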