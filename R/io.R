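# Checkpoints, interaction tables and prediction output.

CHECKPOINT_FORMAT_VERSION <- 1L

#' Save model parameters to a JSON checkpoint
#'
#' Stores every parameter tensor with its dimensions, the configuration,
#' the frozen set and a format-version header.
#'
#' @param object a `pretrain_result` or `model_bundle`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  ps <- object$ps
  payload <- list(
    format_version = CHECKPOINT_FORMAT_VERSION,
    class = class(object)[1],
    package_version = as.character(utils::packageVersion("cpifuse")),
    config = .strip_classes(object[setdiff(names(object), "ps")]),
    frozen = ps$frozen,
    params = lapply(ps$values, function(v) {
      list(dim = dim(v), data = as.vector(v))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return object of the saved class with a rebuilt parameter store.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format_version) ||
      payload$format_version != CHECKPOINT_FORMAT_VERSION) {
    stop("unsupported checkpoint format version")
  }
  ps <- ps_new()
  for (nm in names(payload$params)) {
    p <- payload$params[[nm]]
    ps$values[[nm]] <- matrix(p$data, p$dim[1], p$dim[2])
  }
  ps$frozen <- as.character(payload$frozen %||% character(0))
  out <- payload$config
  out$ps <- ps
  # restore list-classes lost in JSON round trip
  if (payload$class == "pretrain_result") {
    out$cfg <- do.call(pna_config, out$cfg[names(formals(pna_config))])
  } else if (payload$class == "model_bundle") {
    out$cfg <- do.call(fusion_config,
                       out$cfg[intersect(names(out$cfg),
                                         names(formals(fusion_config)))])
    out$pna_cfg <- do.call(pna_config,
                           out$pna_cfg[names(formals(pna_config))])
  }
  class(out) <- payload$class
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_classes) else x
}

#' Read an interaction table
#'
#' @param path CSV or TSV with at least `compound_id`, `protein_id`, and
#'   typically `label` (plus `smiles` / `structure_path` columns).
#' @return data.frame.
#' @export
read_interactions <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("compound_id", "protein_id")
  if (!all(need %in% names(df))) {
    stop("interaction table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write predictions as TSV
#'
#' Columns: compound_id, protein_id, y_true (if known), y_pred.
#' @param predictions data.frame from [predict_interactions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  cols <- intersect(c("compound_id", "protein_id", "y_true", "y_pred"),
                    names(predictions))
  utils::write.table(predictions[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
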