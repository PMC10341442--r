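#' Quadratic oxidant/antioxidant balance model of ROS production
#'
#' The net rate of reactive-oxygen-species (ROS) accumulation is modeled as the
#' balance of an oxidant system producing ROS at rate \eqn{F_{os}(C) = a C^2}
#' and an antioxidant system removing them at rate \eqn{F_{aos}(C) = b C},
#' plus an oxygen-independent baseline \eqn{F_0}:
#' \deqn{\frac{dC_{ROS}}{dt} = F(C) = a C^2 - b C + F_0,}
#' with C the oxygen concentration in arbitrary units tracking oxygen pressure
#' PO2 (mmHg). For `a > 0` the parabola has a unique minimum at
#' \eqn{C_{opt} = b/(2a)} with minimal rate \eqn{F_{min} = F_0 - b^2/(4a)}:
#' there is an optimal (hypoxemic) oxygen level at which ROS production is
#' lowest, while both anoxemia (C → 0) and normoxemia (large C) produce more.
#'
#' @param a oxidant performance constant (rate·conc⁻²); must be > 0 for a
#'   minimum to exist.
#' @param b antioxidant performance constant (rate·conc⁻¹); non-negative.
#' @param f0 baseline ROS production rate; unrestricted.
#' @return A list of class `ros_params`.
#' @examples
#' p <- ros_params(a = 0.02, b = 2, f0 = 55)
#' ros_optimum(p)   # C_opt = 50, F_min = 5
#' @name ros_model
#' @export
ros_params <- function(a, b, f0) {
  if (!is_number(a) || !is_number(b) || !is_number(f0))
    abort_rbc("a, b, f0 must be finite numbers", "validation")
  if (b < 0)
    abort_rbc("antioxidant constant b must be non-negative", "validation")
  structure(list(a = a, b = b, f0 = f0), class = "ros_params")
}

#' @export
print.ros_params <- function(x, ...) {
  cat(sprintf("<ros_params> F(C) = %.4g C^2 - %.4g C + %.4g\n", x$a, x$b, x$f0))
  invisible(x)
}

#' Net ROS production rate at an oxygen concentration
#'
#' Evaluates \eqn{F(C) = a C^2 - b C + F_0}.
#'
#' @param c_o2 oxygen concentration(s), non-negative (arbitrary units tracking
#'   PO2 in mmHg).
#' @param params a [ros_params()].
#' @return Numeric rate(s), same length as `c_o2`.
#' @export
ros_rate <- function(c_o2, params) {
  stopifnot(inherits(params, "ros_params"))
  c_o2 <- as.numeric(c_o2)
  if (anyNA(c_o2) || any(c_o2 < 0))
    abort_rbc("oxygen concentration must be non-negative", "domain")
  params$a * c_o2^2 - params$b * c_o2 + params$f0
}

#' Oxidant-system ROS production rate
#'
#' The production half of the balance: \eqn{F_{os}(C) = a C^2}.
#' @inheritParams ros_rate
#' @return Numeric rate(s).
#' @export
ros_oxidant_rate <- function(c_o2, params) {
  stopifnot(inherits(params, "ros_params"))
  c_o2 <- as.numeric(c_o2)
  if (anyNA(c_o2) || any(c_o2 < 0))
    abort_rbc("oxygen concentration must be non-negative", "domain")
  params$a * c_o2^2
}

#' Antioxidant-system ROS elimination rate
#'
#' The removal half of the balance: \eqn{F_{aos}(C) = b C}. The net balance
#' satisfies `ros_rate(c) == ros_oxidant_rate(c) - ros_antioxidant_rate(c) + f0`.
#' @inheritParams ros_rate
#' @return Numeric rate(s).
#' @export
ros_antioxidant_rate <- function(c_o2, params) {
  stopifnot(inherits(params, "ros_params"))
  c_o2 <- as.numeric(c_o2)
  if (anyNA(c_o2) || any(c_o2 < 0))
    abort_rbc("oxygen concentration must be non-negative", "domain")
  params$b * c_o2
}

#' Optimal oxygen level of the ROS balance
#'
#' Closed-form vertex of the quadratic: \eqn{C_{opt} = b/(2a)},
#' \eqn{F_{min} = F_0 - b^2/(4a)}. Requires `a > 0` (convex parabola).
#'
#' @param params a [ros_params()].
#' @return A list of class `ros_optimum` with `c_opt` and `f_min`.
#' @export
ros_optimum <- function(params) {
  stopifnot(inherits(params, "ros_params"))
  if (params$a <= 0)
    abort_rbc("no minimum exists: the oxidant constant a must be positive",
              "no_minimum")
  structure(list(c_opt = params$b / (2 * params$a),
                 f_min = params$f0 - params$b^2 / (4 * params$a)),
            class = "ros_optimum")
}

#' @export
print.ros_optimum <- function(x, ...) {
  cat(sprintf("<ros_optimum> C_opt = %.4g, F_min = %.4g\n", x$c_opt, x$f_min))
  invisible(x)
}

#' Sample the ROS-rate curve over an oxygen grid
#'
#' Tabulates \eqn{F(C)} for plotting, with the analytic optimum and optional
#' user-supplied normoxemia/anoxemia reference points annotated. The model is
#' qualitative; no numeric coordinates for the reference points are implied,
#' so annotations are taken from the caller only.
#'
#' @param params a [ros_params()].
#' @param c_grid non-empty, non-negative oxygen concentrations.
#' @param normoxemia,anoxemia optional reference oxygen levels to annotate.
#' @return A [tibble::tibble()] with columns `c_o2`, `ros_rate` and a logical
#'   `at_optimum` marking the grid point nearest `c_opt` (when `a > 0`);
#'   attributes `optimum`, `normoxemia`, `anoxemia` carry the annotations.
#' @export
ros_curve <- function(params, c_grid = seq(0, 100, by = 1),
                      normoxemia = NULL, anoxemia = NULL) {
  stopifnot(inherits(params, "ros_params"))
  c_grid <- as.numeric(c_grid)
  if (length(c_grid) == 0L)
    abort_rbc("c_grid must be non-empty", "validation")
  f <- ros_rate(c_grid, params)
  tab <- tibble::tibble(c_o2 = c_grid, ros_rate = f, at_optimum = FALSE)
  opt <- NULL
  if (params$a > 0) {
    opt <- ros_optimum(params)
    tab$at_optimum <- seq_along(c_grid) == which.min(abs(c_grid - opt$c_opt))
  }
  ann <- function(c0) if (is.null(c0)) NULL else
    list(c_o2 = c0, ros_rate = ros_rate(c0, params))
  attr(tab, "optimum") <- opt
  attr(tab, "normoxemia") <- ann(normoxemia)
  attr(tab, "anoxemia") <- ann(anoxemia)
  tab
}
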