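# Minimal fully-connected network with manual backpropagation: the value
# network behind the deep Q-learning solver (3 hidden ReLU layers of 24
# units, linear output, SGD on squared TD error). Kept deliberately small
# and dependency-free; all state is plain matrices so networks copy by
# value (target-network snapshots are plain assignments).

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  nl <- length(sizes) - 1
  for (l in seq_len(nl)) {
    # He initialisation for the ReLU layers; the value head starts at zero
    # so initial action values are unbiased (ties break to the first action)
    W[[l]] <- if (l == nl) {
      matrix(0, sizes[l], sizes[l + 1])
    } else {
      matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1])
    }
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, X) {
  nl <- length(net$W)
  acts <- vector("list", nl + 1)
  acts[[1]] <- X
  for (l in seq_len(nl)) {
    Z <- acts[[l]] %*% net$W[[l]] + matrix(net$b[[l]], nrow(X),
                                           length(net$b[[l]]), byrow = TRUE)
    acts[[l + 1]] <- if (l < nl) pmax(Z, 0) else Z
  }
  acts
}

mlp_predict <- function(net, X) {
  mlp_forward(net, X)[[length(net$W) + 1]]
}

# One SGD step on 0.5 * sum (Q[sel] - target)^2 where `sel` is the action
# column per row. Returns the updated network or NULL on non-finite loss.
mlp_td_step <- function(net, X, actions, targets, lr, td_clip = Inf) {
  nl <- length(net$W)
  acts <- mlp_forward(net, X)
  out <- acts[[nl + 1]]
  n <- nrow(X)
  delta <- matrix(0, n, ncol(out))
  idx <- cbind(seq_len(n), actions)
  err <- out[idx] - targets
  if (!all(is.finite(err))) return(NULL)
  # clipped TD error (Huber-style): keeps the large terminal rewards from
  # destabilising plain SGD
  err <- pmax(-td_clip, pmin(td_clip, err))
  delta[idx] <- err / n
  for (l in rev(seq_len(nl))) {
    gW <- t(acts[[l]]) %*% delta
    gb <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (acts[[l]] > 0)
    }
    net$W[[l]] <- net$W[[l]] - lr * gW
    net$b[[l]] <- net$b[[l]] - lr * gb
  }
  net
}
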