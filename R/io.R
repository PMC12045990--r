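#' Read a creep trace from CSV
#'
#' Expects columns `time_s` and `length_um`; the pipette geometry and
#' suction either come from identically named columns (`rp_um`,
#' `pressure_pa`, `phi`, constant within the file) or from the function
#' arguments.
#'
#' @param file CSV path.
#' @param pipette_radius,pressure,wall_factor metadata overriding any
#'   embedded columns.
#' @param label condition label (defaults to the file name).
#' @return a [creep_trace()].
#' @export
read_creep_trace <- function(file, pipette_radius = NULL, pressure = NULL,
                             wall_factor = 2.1, label = NULL) {
  d <- utils::read.csv(file)
  if (!all(c("time_s", "length_um") %in% names(d))) {
    stop_invalid("CSV must contain columns time_s and length_um")
  }
  rp <- pipette_radius %||% d$rp_um[1]
  dp <- pressure %||% d$pressure_pa[1]
  phi <- if ("phi" %in% names(d)) d$phi[1] else wall_factor
  if (is.null(rp) || is.null(dp)) {
    stop_invalid("pipette_radius and pressure must be given or embedded")
  }
  creep_trace(d$time_s, d$length_um, pipette_radius = rp, pressure = dp,
              wall_factor = phi,
              label = label %||% tools::file_path_sans_ext(basename(file)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a grayscale TIFF as a signal image
#'
#' Thin wrapper over the tiff package for loading an immunofluorescence
#' section; multi-channel images are averaged to one intensity plane.
#'
#' @param file TIFF path.
#' @param organoid_mask logical matrix, or `NULL` to take every pixel
#'   above `mask_quantile` of the intensity range as tissue.
#' @param mask_quantile used only when no mask is given.
#' @inheritParams signal_image
#' @return a [signal_image()].
#' @export
read_signal_image <- function(file, organoid_mask = NULL,
                              mask_quantile = 0.05, pixel_size = 1,
                              threshold = NULL, label = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF files requires the 'tiff' package")
  }
  img <- tiff::readTIFF(file)
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  if (is.null(organoid_mask)) {
    organoid_mask <- img > stats::quantile(img, mask_quantile)
  }
  signal_image(img, organoid_mask, pixel_size = pixel_size,
               threshold = threshold,
               label = label %||% tools::file_path_sans_ext(basename(file)))
}

#' Write a table of SLS fits to CSV
#'
#' @param fits list of `sls_fit` objects.
#' @param file output path (`NULL` returns the data.frame only).
#' @return the fit table, invisibly when written.
#' @export
sls_fit_table <- function(fits, file = NULL) {
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    label = f$label, k0_Pa = f$k0, kst_Pa = f$k_st, tau_s = f$tau,
    k1_Pa = f$k1, k2_Pa = f$k2, mu_Pas = f$mu,
    r_squared = f$r_squared, n_points = f$n_points)))
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
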