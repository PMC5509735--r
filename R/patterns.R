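#' Image grids for PRE stimulation
#'
#' An image grid is a small matrix of pixel intensities in [0, 1] presented
#' to the PRE (retina) layer: 1 opens the corresponding synapse gate at
#' full amplitude, 0 keeps it closed, intermediate values encode gray tones
#' as graded gate amplitudes. Pixels map to PREs in row-major order with a
#' top-left origin (pixel (0,0) is PRE 1 in R's 1-based indexing).
#'
#' @param values numeric matrix with entries in [0, 1].
#' @return an object of class \code{"image_grid"} (a matrix).
#' @examples
#' image_grid(diag(4))
#' @export
image_grid <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (any(values < 0 | values > 1))
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  structure(values, class = c("image_grid", "matrix"))
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("%d x %d image grid (%g active pixels)\n",
              nrow(x), ncol(x), sum(x > 0)))
  m <- unclass(x)
  print(m, digits = 3)
  invisible(x)
}

#' @export
plot.image_grid <- function(x, main = NULL, ...) {
  m <- unclass(x)
  # image() draws column-major from bottom; flip so the plot matches print
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                  col = grDevices::gray(seq(1, 0, length.out = 64)),
                  zlim = c(0, 1), main = main, ...)
  graphics::box()
  invisible(x)
}

#' Flatten an image grid to the PRE activation vector
#'
#' Row-major, top-left origin: the value for PRE n (1-based) is pixel
#' (row = (n-1) %/% ncol, col = (n-1) %% ncol) in 0-based coordinates.
#'
#' @param image an \code{\link{image_grid}} or numeric matrix.
#' @return numeric vector of length \code{nrow * ncol}.
#' @export
as_pre_vector <- function(image) {
  as.vector(t(unclass(image)))
}

# Registry of built-in binary patterns; each entry: grid size and the
# 0-based (row, col) coordinates of the active pixels.
.builtin_patterns <- list(
  diag4       = list(n = 4L, px = cbind(0:3, 0:3)),
  antidiag4   = list(n = 4L, px = cbind(0:3, 3:0)),
  corners4    = list(n = 4L, px = cbind(c(0L, 0L, 3L, 3L), c(0L, 3L, 0L, 3L))),
  top_bar3    = list(n = 3L, px = cbind(c(0L, 0L, 0L), 0:2)),
  bottom_bar3 = list(n = 3L, px = cbind(c(2L, 2L, 2L), 0:2)),
  left_bar3   = list(n = 3L, px = cbind(0:2, c(0L, 0L, 0L))),
  right_bar3  = list(n = 3L, px = cbind(0:2, c(2L, 2L, 2L)))
)

#' Built-in stimulus patterns
#'
#' The pattern library used by the learning and tracking experiments.
#' \code{"diag4"} is the 4-pixel main diagonal of the 4x4 grid (the static
#' training pattern); \code{"antidiag4"} and \code{"corners4"} are 4-pixel
#' stand-ins for the second and third training images, which are only
#' defined graphically in the source experiments - any 4-pixel image
#' reproduces the same learning logic. \code{"top_bar3"} and
#' \code{"bottom_bar3"} are the two 3-pixel bars of the 3x3 two-neuron
#' tracking experiment; \code{"left_bar3"}/\code{"right_bar3"} are their
#' 90-degree rotations.
#'
#' @param name pattern identifier (see Details).
#' @return an \code{\link{image_grid}}.
#' @examples
#' builtin_pattern("diag4")
#' names_builtin_patterns()
#' @export
builtin_pattern <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      is.na(match(name, names(.builtin_patterns))))
    stop(sprintf("unknown pattern name '%s'; known: %s", name,
                 paste(names(.builtin_patterns), collapse = ", ")),
         call. = FALSE)
  spec <- .builtin_patterns[[name]]
  m <- matrix(0, spec$n, spec$n)
  m[spec$px + 1L] <- 1
  image_grid(m)
}

#' @rdname builtin_pattern
#' @export
names_builtin_patterns <- function() names(.builtin_patterns)

#' Random noise frame
#'
#' Each pixel is independently active with probability \code{density}
#' (per-pixel Bernoulli). The stochastic training protocol uses sparse
#' noise (3\% by default) so that frames presented right after a fire
#' depress background synapses without triggering spurious fires.
#'
#' @param nrow,ncol grid size.
#' @param density per-pixel activation probability in [0, 1].
#' @return a binary \code{\link{image_grid}}.
#' @export
make_noise <- function(nrow, ncol = nrow, density = 0.03) {
  stopifnot(nrow >= 1, ncol >= 1)
  if (density < 0 || density > 1)
    stop("density must lie in [0, 1]", call. = FALSE)
  image_grid(matrix(as.numeric(stats::runif(nrow * ncol) < density),
                    nrow, ncol))
}

# Border cycle of the 3x3 grid, counter-clockwise in image coordinates
# (y down), as 0-based (row, col): top row left-to-right, right column
# down, bottom row right-to-left, left column up.
.perimeter_cycle <- cbind(
  row = c(0L, 0L, 0L, 1L, 2L, 2L, 2L, 1L),
  col = c(0L, 1L, 2L, 2L, 2L, 1L, 0L, 0L)
)

#' Shift a 3x3 image along the border cycle
#'
#' Every active border pixel advances \code{steps} positions
#' counter-clockwise along the 8-cell border cycle of the 3x3 grid
#' ((0,0) -> (0,1) -> (0,2) -> (1,2) -> (2,2) -> (2,1) -> (2,0) -> (1,0)
#' in 0-based (row, col); counter-clockwise with the y axis pointing
#' down). The center pixel does not move. Eight steps are the identity and
#' the active-pixel count is preserved; pixel values (gray levels) travel
#' with their pixels.
#'
#' @param image a 3x3 \code{\link{image_grid}}.
#' @param steps integer number of one-cell shifts (may be negative).
#' @return the shifted \code{\link{image_grid}}.
#' @examples
#' shift_perimeter(builtin_pattern("top_bar3"), 4)  # the bottom bar
#' @export
shift_perimeter <- function(image, steps) {
  m <- unclass(image)
  if (!is.matrix(m) || nrow(m) != 3L || ncol(m) != 3L)
    stop("shift_perimeter requires a 3x3 image", call. = FALSE)
  stopifnot(length(steps) == 1L, steps == round(steps))
  s <- ((steps %% 8L) + 8L) %% 8L
  out <- m
  idx <- .perimeter_cycle + 1L
  vals <- m[idx]
  out[idx] <- vals[((seq_len(8L) - 1L - s) %% 8L) + 1L]
  image_grid(out)
}

#' Gray-scale stimulus
#'
#' Wraps a grid of gray levels in [0, 1] for graded-amplitude stimulation:
#' during training each level scales the PRE gate amplitude, so a light
#' pixel (level near 1) is potentiated to a high conductance while a dark
#' pixel yields a low conductance (see \code{\link{gray_lrs_map}}); a
#' level-0 pixel keeps its gate closed and is never potentiated.
#'
#' @param levels numeric matrix of gray levels in [0, 1].
#' @return an \code{\link{image_grid}}.
#' @export
gray_pattern <- function(levels) {
  image_grid(levels)
}

#' Read / write pattern grids as plain text
#'
#' Plain-text grids are whitespace-separated rows of values in [0, 1]
#' (0/1 for binary patterns, decimals for gray levels).
#'
#' @param path file path.
#' @return \code{read_pattern} returns an \code{\link{image_grid}}.
#' @export
read_pattern <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  image_grid(m)
}

#' @rdname read_pattern
#' @param image an \code{\link{image_grid}} to write.
#' @export
write_pattern <- function(image, path) {
  utils::write.table(unclass(image), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
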