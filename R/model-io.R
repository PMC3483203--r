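# Model serialization: plain JSON holding feature index, per-class mean
# and covariance, sample sizes and applied ridge.  Precision matrices
# and log-determinants are rebuilt deterministically on read from the
# stored covariance + ridge, so a round-tripped model predicts
# identically.

FORMAT_VERSION <- 1L

# lightweight fingerprint of the property table a model was built with
table_checksum <- function(table = dinuc_property_table()) {
  round(sum(as.vector(table) * seq_along(table)), 6)
}

#' Write a covariant discriminant model to JSON
#'
#' @param model A `"cd_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_cd_model()]
#' @export
write_cd_model <- function(model, path) {
  stopifnot(inherits(model, "cd_model"))
  pack <- function(cm) list(class_id = cm$class_id, n = cm$n,
                            ridge_used = cm$ridge_used, mean = cm$mean,
                            cov = cm$cov)
  rec <- list(format = "nucleoscan-cd-model", version = FORMAT_VERSION,
              levels = model$levels, input_dim = model$input_dim,
              features = model$features, prior = model$prior,
              table_checksum = table_checksum(),
              positive = pack(model$positive),
              negative = pack(model$negative))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a covariant discriminant model from JSON
#'
#' @param path Path written by [write_cd_model()].
#' @return A `"cd_model"`.
#' @export
read_cd_model <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(rec$format, "nucleoscan-cd-model"))
    stop("'", path, "' is not a covariant discriminant model file")
  if (!isTRUE(all.equal(rec$table_checksum, table_checksum(),
                        tolerance = 1e-6)))
    warning("model '", path, "' was built with a different property table")
  unpack <- function(cm) {
    p <- length(cm$mean)
    C <- matrix(as.numeric(cm$cov), p, p)
    out <- list(class_id = cm$class_id, mean = as.numeric(cm$mean),
                cov = (C + t(C)) / 2, n = cm$n)
    out <- finish_class_model(out, ridge = cm$ridge_used)
    # finish_class_model may only escalate; stored ridge is authoritative
    out$ridge_used <- max(out$ridge_used, cm$ridge_used)
    out
  }
  structure(list(positive = unpack(rec$positive),
                 negative = unpack(rec$negative),
                 features = as.integer(rec$features),
                 input_dim = as.integer(rec$input_dim),
                 levels = as.character(rec$levels),
                 prior = if (is.null(rec$prior)) NULL
                         else as.numeric(rec$prior)),
            class = "cd_model")
}
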