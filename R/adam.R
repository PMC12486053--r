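# Adaptive-moment gradient descent on nested lists of parameter arrays.

adam_init <- function(params) {
  list(m = tree_map1(function(x) x * 0, params),
       v = tree_map1(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(state, params, grads, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  mhat <- tree_map1(function(m) m / c1, state$m)
  vhat <- tree_map1(function(v) v / c2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(`-`, params, upd)
  list(state = state, params = params)
}
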