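# Model state is serialized as a single JSON document: schema, architecture,
# preprocessor and every parameter matrix at full precision. JSON keeps the
# artifact diffable and language-neutral; no binary formats are written.

schema_to_list <- function(schema) {
  list(
    features = purrr::pmap(schema$features, function(name, role, levels, stage) {
      out <- list(name = name, role = role, stage = stage)
      if (!is.null(levels)) out$levels <- as.list(levels)
      out
    }),
    duration = schema$duration, event = schema$event
  )
}

schema_from_list <- function(doc) {
  feats <- dplyr::bind_rows(purrr::map(doc$features, function(f) {
    tibble(name = f$name, role = f$role,
           levels = list(if (is.null(f$levels)) NULL else as.character(unlist(f$levels))),
           stage = f$stage)
  }))
  feature_schema(feats, doc$duration, doc$event)
}

#' Serialize a trained model (and its preprocessor) to one JSON file
#'
#' @param model A trained `risk_model`.
#' @param preprocessor The [fit_preprocessor()] state used with it.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, preprocessor, path) {
  doc <- list(
    type = model$type,
    schema = schema_to_list(model$schema),
    time_mu = model$time_mu, time_sd = model$time_sd,
    preprocessor = list(location = as.list(preprocessor$location),
                        scale = as.list(preprocessor$scale)),
    theta = unname(unlist(model$params))
  )
  if (model$type == "ttsurv") {
    doc$config <- unclass(model$config)
    doc$dense_width <- model$dense_width
  } else {
    doc$code_center <- as.list(model$code_center)
    doc$code_scale <- as.list(model$code_scale)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model bundle written by [write_model()]
#'
#' @param path JSON path.
#' @return A list with `model` and `preprocessor`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- schema_from_list(
    jsonlite::read_json(path, simplifyVector = FALSE)$schema)
  if (doc$type == "ttsurv") {
    cfgl <- doc$config
    model <- risk_model(schema,
                        encoder_config(cfgl$d_embed, cfgl$n_layers,
                                       cfgl$n_heads, cfgl$mlp_hidden,
                                       cfgl$t_tokens),
                        dense_width = doc$dense_width, seed = 1)
  } else {
    model <- linear_risk_model(schema)
    model$code_center[] <- unlist(doc$code_center)
    model$code_scale[] <- unlist(doc$code_scale)
  }
  model$params <- utils::relist(doc$theta, model$params)
  model$time_mu <- doc$time_mu
  model$time_sd <- doc$time_sd
  model$trained <- TRUE
  pre <- structure(
    list(location = unlist(doc$preprocessor$location),
         scale = unlist(doc$preprocessor$scale),
         feature_names = names(unlist(doc$preprocessor$location)),
         schema_features = schema$features$name),
    class = "preprocessor"
  )
  list(model = model, preprocessor = pre)
}
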