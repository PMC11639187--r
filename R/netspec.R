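#' Build a V-Net-style encoder-decoder layer specification
#'
#' Describes a 3D encoder-decoder segmentation network as a flat table of
#' convolution layers, sufficient for exact parameter counting: an input
#' convolution, encoder stages of repeated spatial convolutions joined by
#' strided down-transition convolutions that double the channel count, a
#' mirrored decoder with up-transition (transposed) convolutions and
#' skip-concatenation merges, and a 1x1x1 output convolution. No tensors
#' are ever executed; the object is a descriptor only.
#'
#' @param channels Channel schedule per stage (default 16..256).
#' @param convs_per_stage Spatial convolutions per stage (same length).
#' @param kernel Spatial kernel size (odd).
#' @param in_channels,out_channels Network input/output channels.
#' @param bias Include a bias term per output channel?
#' @param name Spec name.
#' @return A `network_spec`: list with `layers` (tibble: `stage`,
#'   `block_type`, `kernel`, `in_channels`, `out_channels`, `bias`,
#'   `skip_in`) and `meta`.
#' @export
build_vnet <- function(channels = c(16, 32, 64, 128, 256),
                       convs_per_stage = c(1, 2, 3, 3, 3),
                       kernel = 3, in_channels = 1, out_channels = 2,
                       bias = TRUE, name = "vnet") {
  ns <- length(channels)
  if (ns < 1L) stop("channel schedule must be nonempty", call. = FALSE)
  if (length(convs_per_stage) != ns) {
    stop("`convs_per_stage` must match the channel schedule length",
         call. = FALSE)
  }
  if (kernel < 1 || kernel %% 2 == 0) stop("kernel must be odd >= 1",
                                           call. = FALSE)
  lay <- function(stage, type, k, ci, co, skip = FALSE) {
    tibble::tibble(stage = stage, block_type = type, kernel = k,
                   in_channels = ci, out_channels = co, bias = bias,
                   skip_in = skip)
  }
  rows <- list(lay("input", "input", kernel, in_channels, channels[1]))
  for (i in seq_len(ns)) {
    for (j in seq_len(convs_per_stage[i])) {
      rows[[length(rows) + 1L]] <-
        lay(paste0("enc", i), "down_block", kernel, channels[i], channels[i])
    }
    if (i < ns) {
      rows[[length(rows) + 1L]] <-
        lay(paste0("down", i), "down_transition", 2, channels[i],
            channels[i + 1])
    }
  }
  if (ns > 1L) {
    for (i in (ns - 1L):1L) {
      rows[[length(rows) + 1L]] <-
        lay(paste0("up", i), "up_transition", 2, channels[i + 1], channels[i])
      for (j in seq_len(convs_per_stage[i])) {
        skip <- j == 1L  # concatenated encoder features double the input
        rows[[length(rows) + 1L]] <-
          lay(paste0("dec", i), "up_block", kernel,
              if (skip) 2 * channels[i] else channels[i], channels[i], skip)
      }
    }
  }
  rows[[length(rows) + 1L]] <- lay("output", "output", 1, channels[1],
                                   out_channels)
  spec <- structure(list(layers = dplyr::bind_rows(rows),
                         meta = list(name = name, channels = channels,
                                     convs_per_stage = convs_per_stage,
                                     kernel = kernel, derived = FALSE,
                                     reduction_factor = NA_real_)),
                    class = "network_spec")
  validate_network(spec)
  spec
}

#' Validate channel continuity of a network spec
#'
#' Within every stage each layer's input channel count must equal the
#' previous layer's output count; the first layer of an up-block stage may
#' instead declare a skip-concatenation merge (`skip_in`), doubling its
#' input. Across stages, a layer's input must equal the previous layer's
#' output (doubled under `skip_in`).
#'
#' @param spec A `network_spec`.
#' @return `spec`, invisibly; errors on a continuity violation.
#' @export
validate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  ly <- spec$layers
  if (nrow(ly) == 0L) return(invisible(spec))
  if (any(ly$kernel < 1) || any(ly$in_channels < 1) ||
      any(ly$out_channels < 1)) {
    stop("kernel and channel counts must be >= 1", call. = FALSE)
  }
  for (i in seq_len(nrow(ly))[-1]) {
    expected <- ly$out_channels[i - 1]
    if (ly$skip_in[i]) expected <- 2 * expected
    if (ly$in_channels[i] != expected) {
      stop(sprintf(
        "channel continuity broken at layer %d (%s): in %d, expected %d",
        i, ly$stage[i], ly$in_channels[i], expected), call. = FALSE)
    }
  }
  invisible(spec)
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", x$meta$name, "-", nrow(x$layers), "layers,",
      format(count_parameters(x), big.mark = ","), "parameters\n")
  invisible(x)
}

#' Exact parameter count of a layer spec
#'
#' Each convolution contributes `k^3 * in * out` weights plus `out` bias
#' terms when biased. Normalization/activation layers carry no counted
#' parameters in this calculus.
#'
#' @param s A `network_spec`.
#' @return Integer-valued parameter total (double to avoid overflow).
#' @examples
#' count_parameters(build_vnet(channels = 16, convs_per_stage = 1))
#' @export
count_parameters <- function(s) {
  stopifnot(inherits(s, "network_spec"))
  ly <- s$layers
  if (nrow(ly) == 0L) return(0)
  sum(ly$kernel^3 * ly$in_channels * ly$out_channels +
        ifelse(ly$bias, ly$out_channels, 0))
}

#' Apply the bottleneck substitution to derive a compressed network
#'
#' Every spatial convolution inside a down-block or up-block (kernel > 1)
#' is replaced by a three-layer bottleneck: a 1x1x1 convolution reducing
#' channels by the factor `r`, the spatial convolution at the reduced
#' width, and a 1x1x1 convolution restoring the original output channels.
#' Stage input/output interfaces are preserved, so the substitution is
#' interface-neutral; transitions and the input/output convolutions are
#' untouched. Applying the substitution twice is an error.
#'
#' @param v A `network_spec` (not already derived).
#' @param reduction_factor Bottleneck channel reduction `r >= 1`; channel
#'   counts not divisible by `r` are reduced with `ceiling` and a warning.
#' @return A derived `network_spec`.
#' @export
to_vbnet <- function(v, reduction_factor = 4) {
  stopifnot(inherits(v, "network_spec"))
  r <- reduction_factor
  if (r < 1) stop("`reduction_factor` must be >= 1", call. = FALSE)
  if (isTRUE(v$meta$derived)) {
    stop("spec is already a derived bottleneck network", call. = FALSE)
  }
  warned <- FALSE
  reduce <- function(c) {
    if (c %% r != 0 && !warned) {
      warning("channel count not divisible by r; using ceiling")
      warned <<- TRUE
    }
    as.numeric(ceiling(c / r))
  }
  out <- list()
  for (i in seq_len(nrow(v$layers))) {
    ly <- v$layers[i, ]
    if (ly$block_type %in% c("down_block", "up_block") && ly$kernel > 1) {
      ci <- ly$in_channels; co <- ly$out_channels
      cir <- reduce(ci); cor_ <- reduce(co)
      out[[length(out) + 1L]] <- dplyr::mutate(ly, kernel = 1,
                                               out_channels = cir)
      out[[length(out) + 1L]] <- dplyr::mutate(ly, in_channels = cir,
                                               out_channels = cor_,
                                               skip_in = FALSE)
      out[[length(out) + 1L]] <- dplyr::mutate(ly, kernel = 1,
                                               in_channels = cor_,
                                               skip_in = FALSE)
    } else {
      out[[length(out) + 1L]] <- ly
    }
  }
  structure(list(layers = dplyr::bind_rows(out),
                 meta = utils::modifyList(v$meta, list(
                   name = paste0(v$meta$name, "_bottleneck"),
                   derived = TRUE, reduction_factor = r))),
            class = "network_spec")
}

#' Parameter reduction of a compressed network
#'
#' `(1 - params_compressed / params_baseline) x 100`.
#'
#' @param vnet Baseline `network_spec`.
#' @param vbnet Compressed `network_spec`.
#' @return Reduction in percent.
#' @examples
#' v <- build_vnet()
#' reduction_fraction(v, to_vbnet(v, 4))
#' @export
reduction_fraction <- function(vnet, vbnet) {
  pv <- count_parameters(vnet)
  if (pv == 0) stop("baseline network has zero parameters", call. = FALSE)
  (1 - count_parameters(vbnet) / pv) * 100
}

#' Serialize a network spec to JSON
#'
#' @param s A `network_spec`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
network_spec_json <- function(s, path = NULL) {
  js <- jsonlite::toJSON(list(meta = s$meta, layers = s$layers),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
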