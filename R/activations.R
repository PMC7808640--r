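#' Inner activation functions
#'
#' A transformative adaptive activation function (TAAF) wraps a fixed *inner*
#' activation `f` in four trainable per-unit parameters,
#' `g(y) = alpha * f(beta * y + gamma) + delta`.  This constructor returns the
#' inner function together with its analytic derivative; the hyperbolic
#' tangent and the logistic sigmoid are the two sigmoidal inner functions used
#' throughout the package, and `identity` gives plain linear units.
#'
#' @param kind One of `"tanh"`, `"sigmoid"`, `"identity"`.
#' @return An object of class `inner_activation`: a list with elements
#'   `kind`, `value` (the function) and `derivative`.
#' @examples
#' f <- inner_activation("sigmoid")
#' f$value(0)       # 0.5
#' f$derivative(0)  # 0.25
#' @export
inner_activation <- function(kind = c("tanh", "sigmoid", "identity")) {
  kind <- match.arg(kind)
  fns <- switch(kind,
    tanh = list(
      value = tanh,
      derivative = function(y) 1 - tanh(y)^2
    ),
    sigmoid = list(
      value = stats::plogis,
      derivative = function(y) {
        s <- stats::plogis(y)
        s * (1 - s)
      }
    ),
    identity = list(
      value = function(y) y,
      derivative = function(y) y * 0 + 1  # ones, preserving shape
    )
  )
  structure(list(kind = kind, value = fns$value, derivative = fns$derivative),
            class = "inner_activation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_inner <- function(inner) {
  if (inherits(inner, "inner_activation")) return(inner)
  inner_activation(inner)
}

TAAF_PARAM_NAMES <- c("alpha", "beta", "gamma", "delta")

#' Per-unit TAAF parameter set
#'
#' Bundles the four per-unit parameter vectors of a TAAF layer together with
#' the *adaptivity mask*: the subset of \{alpha, beta, gamma, delta\} that is
#' trainable.  Parameters outside the mask stay frozen at their current value
#' during training.
#'
#' @param alpha,beta,gamma,delta Numeric vectors of identical length (one
#'   entry per unit).
#' @param mask Character subset of `c("alpha","beta","gamma","delta")`;
#'   defaults to all four (the full TAAF).
#' @return An object of class `taaf_parameters`.
#' @seealso [init_taaf()] for the canonical initialization.
#' @export
taaf_parameters <- function(alpha, beta, gamma, delta,
                            mask = TAAF_PARAM_NAMES) {
  n <- length(alpha)
  if (!all(lengths(list(beta, gamma, delta)) == n)) {
    stop_dimension("alpha, beta, gamma, delta must have identical length")
  }
  mask <- validate_mask(mask)
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma), delta = as.numeric(delta), mask = mask),
    class = "taaf_parameters"
  )
}

validate_mask <- function(mask) {
  mask <- as.character(mask)
  if (!all(mask %in% TAAF_PARAM_NAMES)) {
    stop_argument(sprintf(
      "adaptivity mask entries must be among %s",
      paste(TAAF_PARAM_NAMES, collapse = ", ")))
  }
  # canonical order (alpha, beta, gamma, delta), no duplicates
  TAAF_PARAM_NAMES[TAAF_PARAM_NAMES %in% mask]
}

#' @export
print.taaf_parameters <- function(x, ...) {
  cat(sprintf("<taaf_parameters: %d unit%s, trainable: {%s}>\n",
              length(x$alpha), if (length(x$alpha) == 1) "" else "s",
              paste(x$mask, collapse = ",")))
  invisible(x)
}

#' @export
length.taaf_parameters <- function(x) length(x$alpha)

#' Initialize TAAF parameters
#'
#' Fresh TAAF parameters are always `alpha = 1`, `beta = 1`, `gamma = 0`,
#' `delta = 0` in every unit, so that at initialization the TAAF reproduces
#' its inner activation function exactly and a TAAF network starts from the
#' same function as the corresponding fixed-activation network.
#'
#' @param n_units Number of units in the layer (`>= 1`).
#' @param mask Trainable subset of the four parameters; the empty set
#'   (`character(0)`) gives a permanently frozen TAAF, i.e. the plain inner
#'   activation.
#' @return A [taaf_parameters()] object.
#' @export
init_taaf <- function(n_units, mask = TAAF_PARAM_NAMES) {
  if (!is_count(n_units)) stop_argument("n_units must be a positive integer")
  n_units <- as.integer(n_units)
  taaf_parameters(alpha = rep(1, n_units), beta = rep(1, n_units),
                  gamma = rep(0, n_units), delta = rep(0, n_units),
                  mask = mask)
}

# broadcast a per-unit parameter vector against a batch matrix or a plain
# vector of pre-activations; n_units == 1 recycles over a vector batch
bcast_param <- function(p, y) {
  if (is.matrix(y)) {
    if (length(p) != ncol(y)) {
      stop_dimension("pre-activation column count must equal the number of TAAF units")
    }
    matrix(p, nrow(y), ncol(y), byrow = TRUE)
  } else {
    if (length(p) != length(y) && length(p) != 1L) {
      stop_dimension("pre-activation length must equal the number of TAAF units")
    }
    p
  }
}

#' Evaluate a TAAF
#'
#' Computes `g(y) = alpha * f(beta * y + gamma) + delta` element-wise.
#' `y` may be a vector (one pre-activation per unit) or a batch matrix with
#' samples in rows and units in columns; per-unit semantics are unchanged by
#' batching.  A single-unit parameter set recycles over a vector of
#' pre-activations.  Non-finite parameters propagate to the output; nothing
#' is clamped.
#'
#' @param y Numeric vector or samples-by-units matrix of pre-activations.
#' @param params A [taaf_parameters()] object.
#' @param inner An [inner_activation()] object or its kind string.
#' @return Numeric vector or matrix shaped like `y`.
#' @examples
#' p <- init_taaf(1)
#' taaf_value(0.7, p, "tanh") == tanh(0.7)
#' @export
taaf_value <- function(y, params, inner) {
  inner <- as_inner(inner)
  a <- bcast_param(params$alpha, y)
  b <- bcast_param(params$beta, y)
  g <- bcast_param(params$gamma, y)
  d <- bcast_param(params$delta, y)
  a * inner$value(b * y + g) + d
}

#' Analytic partial derivatives of a TAAF
#'
#' Returns the five partial derivatives of `g(y) = alpha * f(beta*y + gamma)
#' + delta` with respect to the pre-activation and each of the four
#' parameters, evaluated element-wise:
#' \deqn{\partial g/\partial y = \alpha\beta f'(\beta y + \gamma),\quad
#'       \partial g/\partial\alpha = f(\beta y + \gamma),\quad
#'       \partial g/\partial\beta = \alpha y f'(\beta y + \gamma),}
#' \deqn{\partial g/\partial\gamma = \alpha f'(\beta y + \gamma),\quad
#'       \partial g/\partial\delta = 1.}
#' These closed forms are the backpropagation contract for TAAF layers.
#'
#' @inheritParams taaf_value
#' @return A list with elements `value`, `d_y`, `d_alpha`, `d_beta`,
#'   `d_gamma`, `d_delta`, each shaped like `y`.
#' @export
taaf_partials <- function(y, params, inner) {
  inner <- as_inner(inner)
  a <- bcast_param(params$alpha, y)
  b <- bcast_param(params$beta, y)
  g <- bcast_param(params$gamma, y)
  d <- bcast_param(params$delta, y)
  u <- b * y + g
  f <- inner$value(u)
  fp <- inner$derivative(u)
  one <- y * 0 + 1
  list(
    value   = a * f + d,
    d_y     = a * b * fp,
    d_alpha = f,
    d_beta  = a * y * fp,
    d_gamma = a * fp,
    d_delta = one
  )
}

#' Enumerate the 16 constrained TAAF variants
#'
#' All subsets of \{alpha, beta, gamma, delta\} as adaptivity masks, in a
#' deterministic order: by subset size, then lexicographically in the
#' canonical parameter order (alpha, beta, gamma, delta).  The empty subset
#' is the plain inner activation; the full subset is the unconstrained TAAF;
#' `{alpha}` alone is the trainable-amplitude activation and `{beta}` alone
#' the slope-varying activation, the two classical special cases the TAAF
#' generalizes.
#'
#' @return A list of 16 character vectors (masks), named by the compact
#'   label of the subset (e.g. `"ab"` for \{alpha, beta\}; `"none"` for the
#'   empty set).
#' @export
taaf_variants <- function() {
  out <- list()
  for (k in 0:4) {
    if (k == 0) {
      out <- c(out, list(character(0)))
    } else {
      sets <- utils::combn(TAAF_PARAM_NAMES, k, simplify = FALSE)
      out <- c(out, sets)  # combn emits lexicographic order already
    }
  }
  labels <- vapply(out, function(m) {
    if (length(m) == 0) "none" else
      paste(c(alpha = "a", beta = "b", gamma = "g", delta = "d")[m],
            collapse = "")
  }, character(1))
  names(out) <- labels
  out
}

#' Sigmoid reparameterization of a tanh TAAF
#'
#' `tanh(u) = 2 * sigmoid(2u) - 1`, so any TAAF with hyperbolic-tangent inner
#' function equals a TAAF with logistic-sigmoid inner function under the
#' parameter map `(alpha, beta, gamma, delta) -> (2 alpha, 2 beta, 2 gamma,
#' delta - alpha)`.  In particular the plain logistic sigmoid is the
#' tanh-TAAF `(1/2, 1/2, 0, 1/2)`: the tanh and sigmoid network families are
#' the same family under different TAAF initializations.
#'
#' @param tanh_params A [taaf_parameters()] object interpreted with
#'   `inner = "tanh"`.
#' @return A [taaf_parameters()] object which, with `inner = "sigmoid"`,
#'   is pointwise equal to the input TAAF.  The adaptivity mask is carried
#'   over unchanged.
#' @export
equivalent_sigmoid_params <- function(tanh_params) {
  taaf_parameters(
    alpha = 2 * tanh_params$alpha,
    beta  = 2 * tanh_params$beta,
    gamma = 2 * tanh_params$gamma,
    delta = tanh_params$delta - tanh_params$alpha,
    mask  = tanh_params$mask
  )
}

#' Plot TAAF unit response curves
#'
#' Draws `g(y)` over a grid for each unit of a parameter set, with the inner
#' activation as reference.
#'
#' @inheritParams taaf_value
#' @param from,to Grid range.
#' @param n Grid size.
#' @return A ggplot object.
#' @export
plot_taaf <- function(params, inner, from = -5, to = 5, n = 201) {
  inner <- as_inner(inner)
  grid <- seq(from, to, length.out = n)
  k <- length(params)
  df <- purrr::map_dfr(seq_len(k), function(i) {
    pi <- taaf_parameters(params$alpha[i], params$beta[i],
                          params$gamma[i], params$delta[i], params$mask)
    tibble::tibble(unit = factor(i), y = grid,
                   g = taaf_value(grid, pi, inner))
  })
  ref <- tibble::tibble(y = grid, g = inner$value(grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$g,
                                   colour = .data$unit)) +
    ggplot2::geom_line(data = ref, ggplot2::aes(x = .data$y, y = .data$g),
                       inherit.aes = FALSE, linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pre-activation y", y = "g(y)",
                  title = sprintf("TAAF over %s inner activation", inner$kind),
                  subtitle = "dashed: inner activation") +
    ggplot2::theme_minimal()
}
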