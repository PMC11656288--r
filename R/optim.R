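# Stochastic gradient descent with classical momentum (v <- mu v + g;
# p <- p - lr v), applied to a named subset of parameters. Momentum 0.9 is
# the field-standard default for V-Net training; set it to 0 for plain SGD.

sgd_state <- function(lr, momentum = 0.9) {
  structure(list(lr = lr, momentum = momentum, v = list()),
            class = "sgd_state")
}

sgd_step <- function(params, grads, state, names = NULL) {
  nms <- if (is.null(names)) base::names(grads) else names
  for (nm in nms) {
    g <- grads[[nm]]
    if (is.null(g)) next
    v <- state$v[[nm]]
    if (is.null(v)) v <- g * 0
    v <- state$momentum * v + g
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - state$lr * v
  }
  list(params = params, state = state)
}
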