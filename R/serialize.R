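# Portable text serialization for fitted ensembles (JSON; full double
# precision), so models move between sessions without binary artifacts.

#' Write / read a bagged-tree model as JSON text
#'
#' @param model a \code{"bagged_trees"} fit.
#' @param path file path.
#' @return \code{read_bagged_trees} returns the model.
#' @export
write_bagged_trees <- function(model, path) {
  stopifnot(inherits(model, "bagged_trees"))
  payload <- list(
    format = "sleepwave-bagged-trees-v1",
    classes = model$classes,
    n_learners = model$n_learners,
    max_splits = model$max_splits,
    seed = model$seed,
    oob_error = model$oob_error,
    trees = lapply(model$trees, function(tr) {
      list(feature = tr$feature, threshold = tr$threshold,
           left = tr$left, right = tr$right,
           probs = tr$probs, n_splits = tr$n_splits)
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bagged_trees
#' @export
read_bagged_trees <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "sleepwave-bagged-trees-v1")) {
    stop("not a sleepwave bagged-trees file", call. = FALSE)
  }
  trees <- if (is.data.frame(p$trees)) {
    lapply(seq_len(nrow(p$trees)), function(i) as.list(p$trees[i, ]))
  } else p$trees
  trees <- lapply(trees, function(tr) {
    list(feature = as.integer(unlist(tr$feature)),
         threshold = as.numeric(unlist(tr$threshold)),
         left = as.integer(unlist(tr$left)),
         right = as.integer(unlist(tr$right)),
         probs = matrix(as.numeric(unlist(tr$probs)),
                        ncol = length(p$classes)),
         n_splits = as.integer(tr$n_splits))
  })
  structure(list(trees = trees, classes = p$classes,
                 n_learners = as.integer(p$n_learners),
                 max_splits = as.integer(p$max_splits),
                 seed = as.integer(p$seed),
                 oob_error = as.numeric(p$oob_error)),
            class = "bagged_trees")
}
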