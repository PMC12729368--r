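#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_invalid <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("`", name, "` must be a single positive finite number")
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_invalid("`", name, "` must lie in [0, 1]")
  invisible(x)
}

rms <- function(x) sqrt(mean(x^2))

#' @noRd
# Dirichlet(alpha) draw via normalized gammas; used for episode splitting and
# severity-profile sampling.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# Convert simulated seconds to nominal hours under a timeline compression
# factor (simulated-seconds carry `compression` nominal seconds each).
sim_s_to_nominal_h <- function(t_s, compression) t_s * compression / 3600

nominal_h_to_sim_s <- function(t_h, compression) t_h * 3600 / compression
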