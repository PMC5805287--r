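# Wavelet activations and the forward response of a wavelet neural network.

# Dilation floor: alpha is initialised in [0, 1] and may reach 0; the wavelet
# argument divides by max(alpha, .alpha_min) so it stays finite.
.alpha_min <- 1e-3

# Integer codes shared with the compiled forward pass.
wavelet_codes <- c(morlet = 1L, mexican_hat = 2L, gauss1 = 3L, haar = 4L)

check_wavelet_arg <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t))) {
    stop("invalid wavelet argument", call. = FALSE)
  }
  invisible(t)
}

#' Wavelet activation functions
#'
#' The hidden units (wavelons) of a wavelet neural network use wavelet basis
#' functions as activations.  Four are available: the Morlet wavelet
#' \eqn{\psi(t) = \cos(5t)\,e^{-t^2/2}}, the Mexican hat
#' \eqn{\psi(t) = (1 - t^2)\,e^{-t^2/2}}, the first derivative of a Gaussian
#' \eqn{\psi(t) = -t\,e^{-t^2/2}}, and the Haar wavelet (1 on \eqn{[0, 1/2)},
#' \eqn{-1} on \eqn{[1/2, 1)}, 0 elsewhere).  Morlet and Mexican hat are even
#' functions; gauss1 is odd.  All are bounded and return finite values for any
#' finite argument.
#'
#' @param t Numeric vector of dimensionless wavelet arguments; must be finite.
#' @return Numeric vector of the same length as `t`.
#' @examples
#' mexican_hat(0)        # 1
#' mexican_hat(1)        # 0
#' morlet(0)             # 1
#' curve(morlet, -4, 4)
#' @name wavelets
NULL

#' @rdname wavelets
#' @export
morlet <- function(t) {
  check_wavelet_arg(t)
  cos(5 * t) * exp(-t^2 / 2)
}

#' @rdname wavelets
#' @export
mexican_hat <- function(t) {
  check_wavelet_arg(t)
  (1 - t^2) * exp(-t^2 / 2)
}

#' @rdname wavelets
#' @export
gauss1 <- function(t) {
  check_wavelet_arg(t)
  -t * exp(-t^2 / 2)
}

#' @rdname wavelets
#' @export
haar <- function(t) {
  check_wavelet_arg(t)
  ifelse(t >= 0 & t < 0.5, 1, ifelse(t >= 0.5 & t < 1, -1, 0))
}

#' Evaluate a wavelet function by name
#'
#' @param id One of `"morlet"`, `"mexican_hat"`, `"gauss1"`, `"haar"`.
#' @param t Numeric vector of arguments.
#' @return Numeric vector `psi(t)`.
#' @export
wavelet_eval <- function(id, t) {
  switch(id,
    morlet      = morlet(t),
    mexican_hat = mexican_hat(t),
    gauss1      = gauss1(t),
    haar        = haar(t),
    stop("unknown wavelet function: ", id, call. = FALSE)
  )
}

#' Response of a single wavelon to one input record
#'
#' A wavelon reads the features selected by its input slots.  For each active
#' slot `n` (switch `c_n = 1`) the wavelet argument is
#' `z_n = (w_n * x - beta_n) / max(alpha_n, 1e-3)`, and the rotation parameter
#' couples consecutive active slots cyclically:
#' `z'_n = z_n + R_n * z_succ(n)` (with `z' = z` when a single slot is
#' active).  The response is the product of `psi(z'_n)` over the active slots.
#' A wavelon with no active slot, or with its activity flag `ot = 0`, is
#' silent and returns 0.
#'
#' This is the scalar reference implementation; batch prediction via
#' [predict.wnn_genome()] uses a compiled kernel computing the same quantity.
#'
#' @param genome A [wnn_genome][init_genome] object.
#' @param m Index of the wavelon within the genome.
#' @param x Numeric feature vector of length `genome$n_features`.
#' @return A scalar response.
#' @export
wavelon_response <- function(genome, m, x) {
  stopifnot(inherits(genome, "wnn_genome"), m >= 1L, m <= genome$n_wavelons)
  if (length(x) != genome$n_features) {
    stop("feature vector length ", length(x), " does not match genome (",
         genome$n_features, " features)", call. = FALSE)
  }
  if (genome$ot[m] == 0L) return(0)
  act <- which(genome$switch[, m] == 1L)
  if (length(act) == 0L) return(0)
  z <- (genome$w[act, m] * x[genome$feat[act, m]] - genome$beta[act, m]) /
    pmax(genome$alpha[act, m], .alpha_min)
  if (length(act) > 1L) {
    z <- z + genome$rotation[act, m] * z[c(seq_along(z)[-1L], 1L)]
  }
  prod(wavelet_eval(genome$wavelet_set[genome$psi[m]], z))
}

#' Raw network output for one input record
#'
#' The output neuron sums the weighted responses of the active wavelons, the
#' shortcut connections running directly from each input to the output, and
#' the bias:
#' `y(x) = theta + sum_m wt_m * Psi_m(x) + sum_f a_f * x_f`.
#'
#' @inheritParams wavelon_response
#' @param x Numeric feature vector.
#' @return A scalar network output.
#' @seealso [classify()] for thresholded class labels,
#'   [predict.wnn_genome()] for batch prediction.
#' @export
network_output <- function(genome, x) {
  stopifnot(inherits(genome, "wnn_genome"))
  if (length(x) != genome$n_features) {
    stop("feature vector length ", length(x), " does not match genome (",
         genome$n_features, " features)", call. = FALSE)
  }
  act <- which(genome$ot == 1L)
  psi_sum <- 0
  for (m in act) {
    psi_sum <- psi_sum + genome$wt[m] * wavelon_response(genome, m, x)
  }
  genome$theta + psi_sum + sum(genome$a * x)
}

#' Classify one input record
#'
#' Class labels are encoded 0 = control, 1 = diseased; training targets are
#' the labels themselves, so the decision threshold on the raw output is 0.5
#' (the boundary is assigned to class 1).
#'
#' @inheritParams network_output
#' @return Integer label, 0 or 1.
#' @export
classify <- function(genome, x) {
  as.integer(network_output(genome, x) >= 0.5)
}

#' Batch prediction for a wavelet neural network
#'
#' @param object A [wnn_genome][init_genome].
#' @param newdata A [wnn_dataset()] or a numeric feature matrix.
#' @param type `"response"` for raw outputs, `"class"` for 0/1 labels.
#' @param ... Unused.
#' @return Numeric vector of outputs, or integer labels.
#' @export
predict.wnn_genome <- function(object, newdata,
                               type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "wnn_dataset")) newdata$features else as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop("newdata has ", ncol(X), " features; genome expects ",
         object$n_features, call. = FALSE)
  }
  out <- wnn_forward_cpp(
    X, object$feat, object$switch, object$w, object$alpha, object$beta,
    object$rotation, wavelet_codes[object$wavelet_set[object$psi]],
    object$wt, object$ot, object$a, object$theta, .alpha_min
  )
  if (type == "class") as.integer(out >= 0.5) else out
}
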