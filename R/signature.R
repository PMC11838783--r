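#' Constant-curvature model space component
#'
#' A component is one factor of a product manifold: a sphere
#' \eqn{S^d_C} (constant positive curvature), a hyperbolic space
#' \eqn{H^d_C} in the hyperboloid model (constant negative curvature), or a
#' Euclidean space \eqn{E^d}. The curvature scale `C` parameterizes the
#' squared radius of the constraint surface: spherical points satisfy
#' \eqn{\sum_i p_i^2 = C} and hyperboloid points satisfy
#' \eqn{-p_0^2 + \sum_{i \ge 1} p_i^2 = -C} with \eqn{p_0 > 0}. Curved
#' components are embedded in an ambient space of one extra dimension, so a
#' component of manifold dimension `dim` has `dim + 1` ambient coordinates
#' (spherical/hyperbolic) or `dim` (Euclidean).
#'
#' @param space_type one of `"spherical"`, `"hyperbolic"`, `"euclidean"`.
#' @param dim manifold dimension, a positive integer.
#' @param curvature curvature scale `C > 0`; ignored for Euclidean
#'   components.
#' @return an object of class `mc_component`.
#' @examples
#' mc_component("hyperbolic", 2)
#' mc_component("spherical", 3, curvature = 2)
#' @export
mc_component <- function(space_type = c("spherical", "hyperbolic", "euclidean"),
                         dim, curvature = 1) {
  space_type <- match.arg(space_type)
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1 || dim != round(dim))
    stop("'dim' must be a positive integer")
  if (space_type != "euclidean") {
    if (!is.numeric(curvature) || length(curvature) != 1L || curvature <= 0)
      stop("'curvature' must be a positive real for curved components")
  } else {
    curvature <- NA_real_
  }
  structure(
    list(space_type = space_type, dim = as.integer(dim),
         curvature = curvature),
    class = "mc_component"
  )
}

#' Ambient coordinate count of a component
#'
#' Spherical and hyperbolic components carry one extra ambient dimension;
#' Euclidean components do not.
#'
#' @param component an [mc_component].
#' @return integer ambient dimension.
#' @export
ambient_dim <- function(component) {
  stopifnot(inherits(component, "mc_component"))
  if (component$space_type == "euclidean") component$dim else component$dim + 1L
}

#' Product-manifold signature
#'
#' A signature is an ordered list of components defining a Cartesian product
#' of model spaces, e.g. \eqn{H^2_1 \times S^3_1 \times E^2}. The total
#' manifold dimension is the sum of the component dimensions.
#'
#' @param ... [mc_component] objects, or a single list of them.
#' @return an object of class `mc_signature`.
#' @examples
#' sig <- mc_signature(mc_component("hyperbolic", 2), mc_component("euclidean", 3))
#' total_dim(sig)
#' @export
mc_signature <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1L]]) &&
      !inherits(comps[[1L]], "mc_component"))
    comps <- comps[[1L]]
  if (length(comps) == 0L)
    stop("a signature needs at least one component")
  ok <- vapply(comps, inherits, logical(1), what = "mc_component")
  if (!all(ok)) stop("all signature elements must be 'mc_component' objects")
  structure(list(components = comps), class = "mc_signature")
}

#' @rdname mc_signature
#' @param signature an `mc_signature`.
#' @export
total_dim <- function(signature) {
  stopifnot(inherits(signature, "mc_signature"))
  sum(vapply(signature$components, function(cm) cm$dim, integer(1)))
}

#' @export
length.mc_signature <- function(x) length(x$components)

#' @export
print.mc_component <- function(x, ...) {
  cat(format_component(x), "\n")
  invisible(x)
}

#' @export
print.mc_signature <- function(x, ...) {
  cat("<mc_signature> ", format_signature(x), "  (total dim ",
      total_dim(x), ")\n", sep = "")
  invisible(x)
}

format_component <- function(cm) {
  code <- c(spherical = "S", hyperbolic = "H", euclidean = "E")[[cm$space_type]]
  if (cm$space_type == "euclidean") paste0(code, cm$dim)
  else paste0(code, cm$dim, "_", format(cm$curvature, trim = TRUE))
}

#' Serialize / parse compact signature strings
#'
#' Signatures are written as `"H2_1.0 x S3_1.0 x E2"`: a one-letter space
#' code, the manifold dimension, and (for curved spaces) an underscore and
#' the curvature scale; components are joined by `" x "`.
#'
#' @param signature an [mc_signature].
#' @return `format_signature`: a character scalar; `parse_signature`: an
#'   [mc_signature].
#' @examples
#' parse_signature("H2_1.0 x S3_0.5 x E2")
#' @export
format_signature <- function(signature) {
  stopifnot(inherits(signature, "mc_signature"))
  paste(vapply(signature$components, format_component, character(1)),
        collapse = " x ")
}

#' @rdname format_signature
#' @param x a signature string such as `"H50_1.0 x E50"`.
#' @export
parse_signature <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toks <- trimws(strsplit(x, "x", fixed = TRUE)[[1L]])
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) stop("empty signature string")
  comps <- lapply(toks, function(tk) {
    m <- regmatches(tk, regexec("^([SHE])([0-9]+)(?:_([0-9.eE+-]+))?$", tk))[[1L]]
    if (length(m) == 0L) stop("cannot parse signature token: '", tk, "'")
    type <- c(S = "spherical", H = "hyperbolic", E = "euclidean")[[m[2L]]]
    dim <- as.integer(m[3L])
    curv <- if (nzchar(m[4L])) as.numeric(m[4L]) else 1
    if (type == "euclidean") mc_component(type, dim)
    else mc_component(type, dim, curvature = curv)
  })
  mc_signature(comps)
}
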