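#' 3D dose distribution on a voxel grid
#'
#' @param grid a \code{voxel_grid}.
#' @param dose 3D numeric array of absorbed dose in Gy, finite and
#'   non-negative, with dim equal to the grid shape.
#' @return object of class \code{dose_grid}.
#' @export
dose_grid <- function(grid, dose) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.array(dose) || !identical(as.integer(dim(dose)), grid$shape))
    stop("dose array shape does not match grid")
  storage.mode(dose) <- "double"
  if (anyNA(dose) || any(!is.finite(dose)))
    stop("dose must be finite everywhere")
  if (any(dose < 0)) stop("dose must be non-negative everywhere")
  structure(list(grid = grid, dose = dose), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %d x %d x %d, max %.2f Gy, mean %.3f Gy\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              max(x$dose), mean(x$dose)))
  invisible(x)
}
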