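# Helpers for managing model parameters as a flat named list of arrays.
# Names are dot-separated paths ("enc1.conv1.w"); parameter groups map each
# path to one of {encoder, decoder, bottom_two, head}.

nn_flatten <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(v)) out <- c(out, nn_flatten(v, key)) else out[[key]] <- v
  }
  out
}

# Nested view of the flat entries under `prefix`.
nn_sub <- function(flat, prefix) {
  pre <- paste0(prefix, ".")
  keys <- names(flat)[startsWith(names(flat), pre)]
  out <- list()
  for (key in keys) {
    parts <- strsplit(substring(key, nchar(pre) + 1), ".", fixed = TRUE)[[1]]
    out <- nn_assign(out, parts, flat[[key]])
  }
  out
}

nn_assign <- function(x, parts, value) {
  if (length(parts) == 1) {
    x[[parts]] <- value
    return(x)
  }
  if (is.null(x[[parts[1]]])) x[[parts[1]]] <- list()
  x[[parts[1]]] <- nn_assign(x[[parts[1]]], parts[-1], value)
  x
}

getp <- function(flat, prefix) {
  p <- list()
  for (leaf in c("w", "b", "g")) {
    v <- flat[[paste0(prefix, ".", leaf)]]
    if (!is.null(v)) p[[leaf]] <- v
  }
  p
}

# Merge a nested grad list (same leaf names as params) into a flat grad list.
setg <- function(grads, prefix, nested) {
  add <- nn_flatten(nested, prefix)
  acc_grads(grads, add)
}

#' Derive a per-seed integer stream deterministically from a master seed.
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}
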