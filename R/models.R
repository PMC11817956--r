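#' Run a forward pass and capture activation shapes
#'
#' @param model A `seg_model` from [build_unet()] or [build_swin_unetr()].
#' @param image A 3D numeric array matching the model's `input_shape` (a
#'   channel dimension of 1 is added), or a 4D (X, Y, Z, C) array.
#' @param cache Keep the intermediate activations needed for
#'   backpropagation (training only; memory-hungry).
#' @return A list with `y` (the (X, Y, Z, 2) logit array), `shapes` (named
#'   list of observed activation shapes, including `bottleneck`), and
#'   `cache`.
#' @export
model_forward <- function(model, image, cache = FALSE) {
  stopifnot(inherits(model, "seg_model"))
  x <- as_model_input(model, image)
  if (model$arch == "unet") unet_forward(model, x, cache)
  else swin_forward(model, x, cache)
}

as_model_input <- function(model, image) {
  if (length(dim(image)) == 3) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  tgt <- model$spec$input_shape
  if (!all(d[1:3] == tgt) || d[4] != model$spec$in_channels) {
    stop("input shape (", paste(d, collapse = "x"),
         ") does not match the model contract (",
         paste(c(tgt, model$spec$in_channels), collapse = "x"), ")")
  }
  image
}

#' @noRd
model_backward <- function(model, cache, dy) {
  if (model$arch == "unet") unet_backward(model, cache, dy)
  else swin_backward(model, cache, dy)$grads
}

#' Segment a volume
#'
#' Applies the model and takes the argmax over the two output channels.
#' Ties go to background, so the prediction is deterministic given the
#' weights and favors specificity.
#'
#' @param model A `seg_model`.
#' @param image A 3D volume matching the model input contract.
#' @return A binary (0/1) 3D array of the same spatial shape.
#' @export
segment <- function(model, image) {
  out <- model_forward(model, image, cache = FALSE)
  logits_to_mask(out$y)
}

logits_to_mask <- function(y) {
  d <- dim(y)
  m <- (y[, , , 2] > y[, , , 1]) * 1
  dim(m) <- d[1:3]
  m
}

#' Choose which parameter groups receive gradient updates
#'
#' `all` trains everything; `bottom_two_only` trains only the two decoder
#' blocks nearest the output plus the final head (the layer-freezing
#' transfer protocol); `decoder_only` freezes the encoder and trains the
#' full decoding path (the self-supervised downstream protocol).
#'
#' @param model A `seg_model`.
#' @param policy One of `"all"`, `"bottom_two_only"`, `"decoder_only"`.
#' @return The model with updated trainability flags.
#' @export
set_trainable <- function(model, policy = c("all", "bottom_two_only",
                                            "decoder_only")) {
  policy <- match.arg(policy)
  on <- switch(policy,
               all = c("encoder", "decoder", "bottom_two", "head"),
               bottom_two_only = c("bottom_two", "head"),
               decoder_only = c("decoder", "bottom_two", "head"))
  model$trainable <- stats::setNames(model$groups %in% on,
                                     names(model$params))
  model$policy <- policy
  model
}

#' Parameter group assignment
#'
#' @param model A `seg_model`.
#' @return A tibble with one row per parameter array: name, group, size,
#'   trainable flag.
#' @export
parameter_groups <- function(model) {
  tibble::tibble(
    parameter = names(model$params),
    group = unname(model$groups),
    size = vapply(model$params, length, integer(1), USE.NAMES = FALSE),
    trainable = unname(model$trainable[names(model$params)])
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the spec so shapes are validated on load.
#'
#' @param model A `seg_model`.
#' @param path File path.
#' @return `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(arch = model$arch, spec = model$spec, params = model$params,
               groups = model$groups), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- if (ck$arch == "unet") build_unet(ck$spec) else
    build_swin_unetr(ck$spec)
  stopifnot(identical(names(model$params), names(ck$params)))
  model$params <- ck$params
  model
}

#' @export
print.seg_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<%s segmentation model>\n", x$arch))
  cat("  input: ", paste(x$spec$input_shape, collapse = "x"), "\n", sep = "")
  cat("  parameters:", npar, "in", length(x$params), "arrays\n")
  gr <- table(x$groups)
  cat("  groups:", paste(names(gr), gr, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.seg_model <- function(x, ...) parameter_groups(x)

#' @export
glance.seg_model <- function(x, ...) {
  tibble::tibble(
    architecture = x$arch,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    input_x = x$spec$input_shape[1],
    input_y = x$spec$input_shape[2],
    input_z = x$spec$input_shape[3],
    policy = x$policy %||% "all"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
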