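# Macrophage-response functions f(L) -------------------------------------
#
# f(L) is the influx of macrophages prompted by the local ox-LDL
# concentration.  The physiological default is sigmoidal (bounded, monotone
# increasing, saturating).  An identity family exists for algebra-level
# tests, and a "pinned" family lets the user dictate the value and slope of
# f at a chosen concentration -- including a negative slope, which is the
# pathological regime used in the instability experiments.

#' Macrophage response functions
#'
#' Constructors for the response function \eqn{f(L)} giving the macrophage
#' influx as a function of the local oxidised-LDL concentration \eqn{L}.
#' Three families are available:
#'
#' * `response_identity()`: \eqn{f(L) = L}; useful for exact-arithmetic tests.
#' * `response_logistic(a, b, s, c)`: \eqn{f(L) = a + b / (1 + e^{-s(L - c)})},
#'   the saturating sigmoid used as the physiological default.
#' * `response_pinned(L_star, value, slope)`: a logistic re-parameterised so
#'   that \eqn{f(L^*)} and \eqn{f'(L^*)} take the requested values exactly,
#'   with the slope of either sign.  The steepness is chosen as
#'   `max(1, 4 |slope| / value)` which guarantees \eqn{f \ge value/2 > 0}
#'   everywhere, so the non-negativity invariant holds for any admissible pin.
#'
#' All families are defined on \eqn{[0, \infty)} (the identity and logistic
#' on all of \eqn{\mathbb{R}}; the stored domain restricts evaluation to
#' physically meaningful concentrations, with `domain[1] = -Inf` for the
#' identity family so signed test inputs remain usable).
#'
#' @param a,b,s,c Logistic offset, range, steepness and centre. `b`, `s`
#'   must be positive.
#' @param L_star Pin concentration (positive).
#' @param value Required \eqn{f(L^*)} (positive).
#' @param slope Required \eqn{f'(L^*)}; any sign.
#' @return An object of class `ps_response` with fields `family`,
#'   `parameters` and `domain`.
#' @examples
#' rf <- response_logistic(a = 0, b = 2, s = 1, c = 0)
#' evaluate_response(rf, 0)   # value 1, derivative 0.5
#' @name response
NULL

new_response <- function(family, parameters, domain) {
  structure(list(family = family, parameters = parameters, domain = domain),
            class = "ps_response")
}

#' @rdname response
#' @export
response_identity <- function() {
  new_response("identity", list(), c(-Inf, Inf))
}

#' @rdname response
#' @export
response_logistic <- function(a = 0, b = 1, s = 1, c = 0) {
  check_scalar(a, "a", nonneg = TRUE)
  check_scalar(b, "b", positive = TRUE)
  check_scalar(s, "s", positive = TRUE)
  check_scalar(c, "c")
  new_response("logistic", list(a = a, b = b, s = s, c = c), c(0, Inf))
}

#' @rdname response
#' @export
response_pinned <- function(L_star, value, slope) {
  check_scalar(L_star, "L_star", positive = TRUE)
  check_scalar(value, "value", positive = TRUE)
  check_scalar(slope, "slope")
  # f(L) = A + B/(1 + exp(-s(L - L_star))): f(L*) = A + B/2, f'(L*) = B*s/4.
  s <- max(1, 4 * abs(slope) / value)
  B <- 4 * slope / s
  A <- value - B / 2
  new_response("pinned",
               list(a = A, b = B, s = s, c = L_star,
                    L_star = L_star, value = value, slope = slope),
               c(0, Inf))
}

#' @export
print.ps_response <- function(x, ...) {
  cat("<ps_response> family:", x$family, "\n")
  if (length(x$parameters))
    cat("  parameters:",
        paste(names(x$parameters),
              signif(unlist(x$parameters), 6), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Evaluate a response function and its derivative
#'
#' @param rf A [response] object.
#' @param L Concentration(s) at which to evaluate; must lie in `rf$domain`.
#' @return A list with numeric `value` (\eqn{f(L) \ge 0}) and `derivative`
#'   (\eqn{f'(L)}), each the length of `L`.
#' @export
evaluate_response <- function(rf, L) {
  if (!inherits(rf, "ps_response"))
    stop_ps("plaquestab_config_error", "'rf' is not a ps_response")
  if (!is.numeric(L) || anyNA(L))
    stop_ps("plaquestab_domain_error", "'L' must be numeric and non-missing")
  if (any(L < rf$domain[1] | L > rf$domain[2]))
    stop_ps("plaquestab_domain_error",
            "L outside response domain [%g, %g]", rf$domain[1], rf$domain[2])
  p <- rf$parameters
  switch(rf$family,
    identity = list(value = L, derivative = rep(1, length(L))),
    logistic = ,
    pinned = {
      # sigmoid in a numerically safe form (no overflow for large |L|)
      u <- p$s * (L - p$c)
      sig <- ifelse(u >= 0, 1 / (1 + exp(-u)), exp(u) / (1 + exp(u)))
      list(value = p$a + p$b * sig,
           derivative = p$b * p$s * sig * (1 - sig))
    },
    stop_ps("plaquestab_config_error", "unknown response family '%s'",
            rf$family)
  )
}
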