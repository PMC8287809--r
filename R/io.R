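#' Write a shape ensemble to CSV (with a JSON config sidecar)
#'
#' The authoritative plain-text interchange format for tracked or
#' simulated filament shapes: CSV with header `frame,point,x_nm,y_nm`,
#' 0-based frame and point indices, points ordered from the clamped end
#' (point 0), coordinates in nanometres. A sidecar `<path>.json` records
#' the fully resolved simulation config (including the seed) and the
#' package version, so a simulated ensemble can be regenerated
#' bit-identically.
#'
#' @param ensemble A `shape_ensemble`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shape_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "shape_ensemble"))
  rows <- lapply(seq_along(ensemble$frames), function(f) {
    m <- ensemble$frames[[f]]
    data.frame(frame = f - 1L, point = seq_len(nrow(m)) - 1L,
               x_nm = m[, 1] * 1e9, y_nm = m[, 2] * 1e9)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(format(tab, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(
    format = "mtflex shape ensemble v1",
    provenance = ensemble$provenance,
    n_frames = length(ensemble$frames),
    precision_nm = if (is.na(ensemble$precision)) NULL else
      ensemble$precision * 1e9,
    package_version = as.character(utils::packageVersion("mtflex"))
  )
  if (!is.null(ensemble$config)) {
    cfg <- ensemble$config
    meta$config <- list(length_um = cfg$length * 1e6,
                        kappa_1e23 = cfg$kappa * 1e23,
                        temperature_K = cfg$temperature,
                        n_frames = cfg$n_frames,
                        n_modes = cfg$n_modes,
                        spacing_nm = cfg$spacing * 1e9,
                        precision_nm = cfg$precision * 1e9,
                        seed = cfg$seed)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a shape ensemble from CSV
#'
#' Reads the shape CSV schema written by [write_shape_ensemble()]
#' (columns `frame,point,x_nm,y_nm`), converting coordinates to metres.
#' Frames are ordered by frame index and points by point index; the
#' provenance is tagged `"external"`. Varying point counts per frame are
#' accepted (external trackers report different lengths per frame), but
#' every frame needs at least 3 points.
#'
#' @param path CSV path.
#' @return A `shape_ensemble`.
#' @export
read_shape_ensemble <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path)
  need <- c("frame", "point", "x_nm", "y_nm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("shape CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("no frames in ", path, call. = FALSE)
  bad <- which(!stats::complete.cases(tab[need]))
  if (length(bad)) {
    stop("non-numeric or missing values at row ", bad[1], call. = FALSE)
  }
  frames <- lapply(split(tab, tab$frame), function(fr) {
    if (is.unsorted(fr$point, strictly = TRUE)) {
      stop("non-monotone point indices in frame ", fr$frame[1],
           call. = FALSE)
    }
    if (nrow(fr) < 3L) {
      stop("frame ", fr$frame[1], " has fewer than 3 points",
           call. = FALSE)
    }
    cbind(x = fr$x_nm * 1e-9, y = fr$y_nm * 1e-9)
  })
  frames <- frames[order(as.numeric(names(frames)))]
  shape_ensemble(unname(frames), provenance = "external")
}

#' Read per-group scalar measurements
#'
#' Reads a CSV with columns `group` and `value` into a named list of
#' numeric vectors suitable for [steel_dwass()].
#'
#' @param path CSV path.
#' @return Named list of numeric vectors, in first-appearance order of
#'   the groups.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path)
  if (!all(c("group", "value") %in% names(tab))) {
    stop("group CSV needs columns 'group' and 'value'", call. = FALSE)
  }
  if (any(!is.finite(tab$value))) {
    stop("non-numeric values at row ",
         which(!is.finite(tab$value))[1], call. = FALSE)
  }
  split(tab$value, factor(tab$group, levels = unique(tab$group)))
}

#' Write a rigidity fit as JSON (plus a per-mode TSV)
#'
#' @param fit A `rigidity_fit`.
#' @param path Output JSON path; the per-mode table goes to
#'   `<path>.permode.tsv`.
#' @return `path`, invisibly.
#' @export
write_rigidity_fit <- function(fit, path) {
  stopifnot(inherits(fit, "rigidity_fit"))
  out <- list(kappa_Nm2 = fit$kappa,
              kappa_1e23 = fit$kappa * 1e23,
              slope_m = fit$slope,
              effective_length_um = fit$effective_length * 1e6,
              n_max = fit$n_max,
              temperature_K = fit$temperature,
              method = fit$method,
              r_squared = fit$r_squared,
              n_frames = fit$n_frames,
              package_version =
                as.character(utils::packageVersion("mtflex")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.table(fit$per_mode, paste0(path, ".permode.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
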