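#' Recurrent cell parameter containers
#'
#' `rnn_params()` holds the weights of a simple recurrent cell: input-to-hidden
#' `W_xh`, hidden-to-hidden `W_hh`, hidden-to-output `W_hy` and hidden bias
#' `b`; the hidden nonlinearity is the hyperbolic tangent and the output
#' nonlinearity the logistic sigmoid. `lstm_params()` holds the four gate
#' weight sets of an LSTM cell: input gate (`W_xi`, `W_hi`, `b_i`), forget
#' gate (`W_xf`, `W_hf`, `b_f`), output gate (`W_xo`, `W_ho`, `b_o`) and
#' candidate (`W_xc`, `W_hc`, `b_c`).
#'
#' All input-side matrices are `hidden x input`, hidden-side matrices
#' `hidden x hidden`, and biases length `hidden`, so that steps act on column
#' state vectors.
#'
#' @param input_dim,hidden_dim,output_dim dimensions.
#' @param init initial weight scale; entries drawn uniform on `[-init, init]`.
#' @return a parameter list of class `rnn_params` / `lstm_params`.
#' @name recurrent-params
NULL

#' @rdname recurrent-params
#' @export
rnn_params <- function(input_dim, hidden_dim, output_dim, init = 0.1) {
  u <- function(nr, nc) matrix(runif(nr * nc, -init, init), nr, nc)
  structure(list(W_xh = u(hidden_dim, input_dim), W_hh = u(hidden_dim, hidden_dim),
                 W_hy = u(output_dim, hidden_dim), b = numeric(hidden_dim)),
            class = "rnn_params")
}

#' @rdname recurrent-params
#' @export
lstm_params <- function(input_dim, hidden_dim, init = 0.1) {
  u <- function(nr, nc) matrix(runif(nr * nc, -init, init), nr, nc)
  structure(list(W_xi = u(hidden_dim, input_dim), W_hi = u(hidden_dim, hidden_dim), b_i = numeric(hidden_dim),
                 W_xf = u(hidden_dim, input_dim), W_hf = u(hidden_dim, hidden_dim), b_f = numeric(hidden_dim),
                 W_xo = u(hidden_dim, input_dim), W_ho = u(hidden_dim, hidden_dim), b_o = numeric(hidden_dim),
                 W_xc = u(hidden_dim, input_dim), W_hc = u(hidden_dim, hidden_dim), b_c = numeric(hidden_dim)),
            class = "lstm_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One step of the simple recurrent cell
#'
#' Computes the state update
#' `h_t = tanh(W_xh x_t + W_hh h_{t-1} + b)` and output
#' `y_t = sigmoid(W_hy h_t)`.
#'
#' @param params an [rnn_params()] list.
#' @param x_t input vector at time t.
#' @param h_prev hidden state at time t-1.
#' @return list with `h` and `y`.
#' @export
rnn_step <- function(params, x_t, h_prev) {
  stopifnot(inherits(params, "rnn_params"))
  if (length(x_t) != ncol(params$W_xh) || length(h_prev) != ncol(params$W_hh))
    stop("dimension mismatch", call. = FALSE)
  h <- tanh(as.vector(params$W_xh %*% x_t + params$W_hh %*% h_prev + params$b))
  y <- sigmoid(as.vector(params$W_hy %*% h))
  list(h = h, y = y)
}

#' One step of the LSTM cell
#'
#' The gate updates:
#' `i_t = sigmoid(W_xi x_t + W_hi h_{t-1} + b_i)`,
#' `f_t = sigmoid(W_xf x_t + W_hf h_{t-1} + b_f)`,
#' `o_t = sigmoid(W_xo x_t + W_ho h_{t-1} + b_o)`,
#' memory `c_t = f_t * c_{t-1} + i_t * tanh(W_xc x_t + W_hc h_{t-1} + b_c)`
#' and output `h_t = o_t * tanh(c_t)` (all products element-wise).
#'
#' @param params an [lstm_params()] list.
#' @param x_t input vector at time t.
#' @param h_prev,c_prev hidden state and memory cell at time t-1.
#' @return list with `h`, `c` and the gate activations `i`, `f`, `o`.
#' @export
lstm_step <- function(params, x_t, h_prev, c_prev) {
  stopifnot(inherits(params, "lstm_params"))
  if (length(x_t) != ncol(params$W_xi) || length(h_prev) != ncol(params$W_hi) ||
      length(c_prev) != length(h_prev))
    stop("dimension mismatch", call. = FALSE)
  i_t <- sigmoid(as.vector(params$W_xi %*% x_t + params$W_hi %*% h_prev + params$b_i))
  f_t <- sigmoid(as.vector(params$W_xf %*% x_t + params$W_hf %*% h_prev + params$b_f))
  o_t <- sigmoid(as.vector(params$W_xo %*% x_t + params$W_ho %*% h_prev + params$b_o))
  g_t <- tanh(as.vector(params$W_xc %*% x_t + params$W_hc %*% h_prev + params$b_c))
  c_t <- f_t * c_prev + i_t * g_t
  h_t <- o_t * tanh(c_t)
  list(h = h_t, c = c_t, i = i_t, f = f_t, o = o_t)
}
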