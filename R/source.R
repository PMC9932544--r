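#' Build the brainstem source spatial filter
#'
#' Computes the Moore-Penrose pseudo-inverse of the (channels x 3) brainstem
#' leadfield: a 3 x channels matrix whose rows give each electrode's weighted
#' contribution to the x/y/z source orientations (`SWF = pinv(L) %*% sensor`).
#' Because source analysis runs on common-average-referenced data, the
#' leadfield columns are average-referenced before inversion by default, which
#' makes the inversion exact for average-referenced sensor data.
#'
#' @param leadfield channels x 3 matrix with channel row names.
#' @param average_reference average-reference the leadfield columns first
#'   (the analysis convention; disable only for raw algebraic use).
#' @return A `spatial_filter`: list with `matrix` (3 x channels, rows x/y/z),
#'   `leadfield` (the possibly centered leadfield it inverts), and
#'   `channel_labels`.
#' @export
build_spatial_filter <- function(leadfield, average_reference = TRUE) {
  L <- unclass(leadfield)
  stopifnot(is.matrix(L), ncol(L) == 3)
  if (average_reference) L <- sweep(L, 2, colMeans(L))
  qrL <- qr(L)
  if (qrL$rank < 3) {
    stop("leadfield is rank-deficient after referencing (rank ", qrL$rank,
         ", condition number ", format(kappa(L), digits = 4), ")")
  }
  W <- MASS::ginv(L)
  rownames(W) <- c("x", "y", "z")
  colnames(W) <- rownames(leadfield)
  structure(list(matrix = W, leadfield = L,
                 channel_labels = rownames(leadfield),
                 source_label = "brainstem/IC regional source"),
            class = "spatial_filter")
}

#' Transform sensor epochs to brainstem source waveforms
#'
#' Applies the spatial filter to every trial of common-average-referenced
#' FFR-band epochs and retains the z (vertical) orientation only; the x and y
#' orientations contribute little to the FFR and are discarded.
#'
#' @param epochs multichannel `ffr_epochs` (trials x channels x samples).
#' @param filter a [build_spatial_filter()] result.
#' @return A `source_epochs`: `data` is trials x samples (z orientation), with
#'   `fs`, `window`, and trial `info` carried through.
#' @export
to_source <- function(epochs, filter) {
  stopifnot(inherits(epochs, "ffr_epochs"), inherits(filter, "spatial_filter"))
  if (length(dim(epochs$data)) != 3)
    stop("to_source needs multichannel epochs (trials x channels x samples)")
  if (!identical(epochs$reference, "common-average"))
    stop("epochs must be common-average referenced before source inversion")
  miss <- setdiff(filter$channel_labels, epochs$channel_labels)
  if (length(miss))
    stop("epochs lack filter channel(s): ", paste(miss, collapse = ", "))
  ord <- match(filter$channel_labels, epochs$channel_labels)
  z <- filter$matrix["z", ]
  d <- epochs$data
  out <- matrix(0, dim(d)[1], dim(d)[3])
  for (k in seq_along(ord))
    out <- out + z[k] * d[, ord[k], ]
  structure(list(data = out, fs = epochs$fs, window = epochs$window,
                 info = epochs$info, kind = "source_z"),
            class = c("source_epochs", "ffr_epochs"))
}
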