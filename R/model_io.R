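MODEL_SCHEMA_VERSION <- 1L

#' Save a trained model to a text container
#'
#' Writes a self-describing JSON file holding the predictor gene list,
#' per-gene Fourier coefficients, the evaluated smoothed matrix, PCA
#' center and rotation, multinomial coefficients, class grid and all
#' hyperparameters, with an explicit schema-version field. Numbers are
#' written with 17 significant digits so that `load_model(save_model(m))`
#' reproduces predictions bit-identically.
#'
#' @param model A `taufisher_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "taufisher_model"))
  payload <- list(
    container = "taufisher_model",
    schema_version = MODEL_SCHEMA_VERSION,
    genes = model$genes,
    config = model$config,
    fits = lapply(model$fits, function(f)
      list(coefficients = f$coefficients, K = f$K, omega = f$omega,
           lambda = f$lambda, span = f$span, rss = f$rss)),
    smoothed = list(values = model$smoothed$values,
                    grid_times = model$smoothed$grid_times,
                    source_genes = model$smoothed$source_genes),
    classifier = model$classifier)
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' Refuses files whose schema version does not match the version this
#' package writes.
#'
#' @param path Path to the model file.
#' @return A `taufisher_model`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("cannot parse model file ", path, ": ",
                             conditionMessage(e)))
  if (!identical(payload$container, "taufisher_model"))
    stop("not a taufisher model file: ", path)
  if (!identical(as.integer(payload$schema_version), MODEL_SCHEMA_VERSION))
    stop("model schema version ", payload$schema_version,
         " does not match supported version ", MODEL_SCHEMA_VERSION)
  fits <- lapply(payload$fits, function(f)
    structure(list(coefficients = as.numeric(f$coefficients), K = f$K,
                   omega = f$omega, lambda = f$lambda,
                   span = as.numeric(f$span), rss = f$rss),
              class = "fourier_fit"))
  sm_values <- as.matrix(payload$smoothed$values)
  rownames(sm_values) <- payload$smoothed$source_genes
  clf <- payload$classifier
  structure(
    list(version = MODEL_SCHEMA_VERSION,
         genes = payload$genes,
         gene_set = NULL,
         fits = fits,
         smoothed = structure(
           list(values = sm_values,
                grid_times = as.numeric(payload$smoothed$grid_times),
                source_genes = payload$smoothed$source_genes),
           class = "smoothed_matrix"),
         classifier = list(center = as.numeric(clf$center),
                           rotation = as.matrix(clf$rotation),
                           beta = as.matrix(clf$beta),
                           beta_classes = as.integer(clf$beta_classes),
                           classes = as.integer(clf$classes)),
         config = payload$config),
    class = "taufisher_model")
}
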