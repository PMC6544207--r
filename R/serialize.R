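# JSON (text) serialization of trained models and session logs: versioned,
# self-describing containers carrying the feature subset, imputation
# constants and seed alongside the tree tables.

#' Save a trained fatigue model as JSON
#'
#' @param model a [train_ensemble()] result.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  core <- model$core
  payload <- list(
    container = "oculofatigue_model", version = 1L,
    spec = unclass(model$spec), features = model$features,
    impute = as.list(model$impute), threshold = model$threshold,
    seed = model$seed,
    core = list(kind = core$kind,
                alphas = core$alphas,
                trees = lapply(core$trees %||% list(core$tree),
                               function(tr) as.list(tr$nodes)),
                mu = core$mu, s = core$s, c_pos = core$c_pos,
                c_neg = core$c_neg))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a fatigue model saved by [save_model()]
#'
#' @param path JSON model path.
#' @return a `fatigue_model`.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(p$container, "oculofatigue_model"))
    abort("not an oculofatigue model file", "format_error")
  restore_tree <- function(tab) {
    tab <- as.data.frame(tab)
    tab$feature <- as.integer(tab$feature)
    tab$left <- as.integer(tab$left); tab$right <- as.integer(tab$right)
    structure(list(nodes = tab), class = "oculo_tree")
  }
  trees <- lapply(p$core$trees, restore_tree)
  core <- list(kind = p$core$kind)
  if (core$kind == "single_tree") core$tree <- trees[[1]]
  else core$trees <- trees
  if (!is.null(p$core$alphas)) core$alphas <- as.numeric(p$core$alphas)
  for (f in c("mu", "s", "c_pos", "c_neg"))
    if (!is.null(p$core[[f]])) core[[f]] <- as.numeric(p$core[[f]])
  spec <- p$spec
  structure(list(spec = structure(spec, class = "classifier_spec"),
                 core = core, features = as.character(p$features),
                 impute = unlist(p$impute), threshold = p$threshold,
                 seed = p$seed),
            class = "fatigue_model")
}
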