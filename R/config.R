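#' Run configuration for the prediction pipeline
#'
#' Collects every tunable of the denoise-embed-score pipeline.  The
#' defaults are the published operating point of the model: embedding
#' dimension 64, three convolution layers, Adam learning rate 0.00725,
#' 600 training epochs, edge/feature dropout rates 0.6 and 0.4, graph
#' penalty factor 6 on the similarity blocks, and low-rank balance
#' parameter 0.1.
#'
#' @param lrr_alpha balance between the nuclear-norm and column-sparse
#'   terms of the low-rank decomposition (default 0.1).
#' @param embed_dim embedding dimension `k` of the graph convolution
#'   layers (default 64).
#' @param n_layers number of convolution layers `L` (default 3).
#' @param learning_rate initial Adam learning rate (default 0.00725).
#' @param epochs number of full-matrix gradient steps (default 600).
#' @param dropout_edge dropout rate applied to the normalized adjacency
#'   during training (default 0.6).
#' @param dropout_feature dropout rate applied to layer inputs during
#'   training (default 0.4).
#' @param graph_penalty penalty factor multiplying the (normalized)
#'   similarity blocks of the input graph (default 6).
#' @param seed integer seed for model-weight initialization and dropout.
#' @param cv_seed integer seed for cross-validation partitions, kept
#'   separate from the model seed so re-running CV does not disturb
#'   training reproducibility.
#' @param norm_style similarity normalization: `"sqrt"` divides by the
#'   square root of the row-sum/column-sum product (symmetric,
#'   scale-invariant; default) or `"product"` divides by the product.
#' @param loss `"weighted_bce"` (positives up-weighted by the
#'   negative/positive count ratio; default) or plain `"bce"`.
#' @param lrr_side which coefficient matrix the low-rank decomposition
#'   learns: `"mirna"` (miRNA-by-miRNA, default) or `"sm"`.
#'
#' @return a list of class `smma_config`.
#' @export
run_config <- function(lrr_alpha = 0.1, embed_dim = 64, n_layers = 3,
                       learning_rate = 0.00725, epochs = 600,
                       dropout_edge = 0.6, dropout_feature = 0.4,
                       graph_penalty = 6, seed = 1L, cv_seed = 1L,
                       norm_style = c("sqrt", "product"),
                       loss = c("weighted_bce", "bce"),
                       lrr_side = c("mirna", "sm")) {
  cfg <- list(
    lrr_alpha = as.numeric(lrr_alpha),
    embed_dim = as.integer(embed_dim),
    n_layers = as.integer(n_layers),
    learning_rate = as.numeric(learning_rate),
    epochs = as.integer(epochs),
    dropout_edge = as.numeric(dropout_edge),
    dropout_feature = as.numeric(dropout_feature),
    graph_penalty = as.numeric(graph_penalty),
    seed = as.integer(seed),
    cv_seed = as.integer(cv_seed),
    norm_style = match.arg(norm_style),
    loss = match.arg(loss),
    lrr_side = match.arg(lrr_side))
  validate_config(cfg)
  structure(cfg, class = "smma_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$lrr_alpha > 0, cfg$embed_dim >= 1, cfg$n_layers >= 1,
    cfg$learning_rate > 0, cfg$epochs >= 0,
    cfg$dropout_edge >= 0, cfg$dropout_edge < 1,
    cfg$dropout_feature >= 0, cfg$dropout_feature < 1,
    cfg$graph_penalty > 0)
  invisible(cfg)
}

#' Read / write a run configuration as a flat key-value file
#'
#' One `key = value` pair per line; numeric fields are serialized at
#' full double precision so a write/read round trip is lossless.
#'
#' @param path file path.
#' @param cfg an `smma_config` (for writing).
#' @return `read_run_config` returns an `smma_config`; unknown keys are
#'   an error.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, `[[`, "", 2)
  defaults <- run_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  args <- as.list(defaults)
  for (i in seq_along(keys)) {
    k <- keys[i]
    args[[k]] <- if (is.character(defaults[[k]])) vals[i] else
      if (is.integer(defaults[[k]])) as.integer(vals[i]) else as.numeric(vals[i])
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "smma_config"))
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.integer(v)) as.character(v)
    else format(v, digits = 17)
  }
  writeLines(paste0(names(cfg), " = ", vapply(cfg, fmt, "")), path)
  invisible(path)
}
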