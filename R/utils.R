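# Classed conditions: the CLI maps these onto its exit codes, and tests can
# assert on the class rather than on message text.

stop_validation <- function(msg, ...) {
  stop(structure(class = c("foldeval_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_geometry <- function(msg, ...) {
  stop(structure(class = c("foldeval_geometry_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_format <- function(msg, ...) {
  stop(structure(class = c("foldeval_format_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_undefined <- function(msg, ...) {
  stop(structure(class = c("foldeval_undefined_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Wrap an angle into (-pi, pi]
#'
#' All angles in the package live on the half-open interval (-pi, pi], so the
#' trans configuration is always +pi, never -pi.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length, wrapped into (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi))
#' @export
wrap_angle <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

#' Convert between degrees and radians
#'
#' @param x numeric vector of angles.
#' @return the converted angles.
#' @rdname angle-units
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname angle-units
#' @export
rad2deg <- function(x) x * 180 / pi

# 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop_geometry("cannot normalize a (near-)zero vector")
  a / n
}

check_point <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 3 || !all(is.finite(p)))
    stop_validation("%s must be a finite numeric 3-vector", what)
  as.numeric(p)
}
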