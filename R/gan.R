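# Minimal GAN on the one-hot adjacency-matrix layout. Generator and
# discriminator are 4-layer fully connected networks (three hidden layers
# plus the output map) with rectifier activations, trained with the
# non-saturating form of the standard minimax objective and Adam. Small
# enough that plain base-R matrix arithmetic with hand-written
# backpropagation is fast on a single CPU.

#' GAN hyperparameters
#'
#' @param latent_dim dimension of the standard-normal latent input
#'   (default 8).
#' @param hidden_g,hidden_d hidden-layer widths of generator and
#'   discriminator (three each; with the output layer both networks have 4
#'   fully connected layers).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size minibatch size (default 128).
#' @param output generator output activation: \code{"softmax"} (default)
#'   applies a per-cell softmax over each channel block so generator output
#'   lives on the same simplex scale as the one-hot training data (the
#'   molecular-GAN convention); \code{"linear"} leaves raw scores.
#' @param hard_fakes logical (default \code{TRUE}): present generated
#'   samples to the discriminator as discretized one-hot matrices (per-cell
#'   argmax, gradient passed straight through the hardening), so the
#'   discriminator compares real and generated molecules in the same
#'   representation it receives for the training data.
#' @param seed integer seed controlling parameter initialization.
#' @return An object of class \code{gan_config}.
#' @export
gan_config <- function(latent_dim = 8L, hidden_g = c(64L, 128L, 256L),
                       hidden_d = c(256L, 128L, 64L),
                       learning_rate = 1e-4, batch_size = 128L,
                       output = c("softmax", "linear"), hard_fakes = TRUE,
                       seed = 1L) {
  output <- match.arg(output)
  if (latent_dim < 1L)
    condition_stop("molevolve_config_error", "latent_dim must be >= 1")
  if (learning_rate <= 0)
    condition_stop("molevolve_config_error", "learning_rate must be > 0")
  if (batch_size < 1L)
    condition_stop("molevolve_config_error", "batch_size must be >= 1")
  if (length(hidden_g) != 3L || length(hidden_d) != 3L ||
      any(c(hidden_g, hidden_d) < 1L))
    condition_stop("molevolve_config_error",
                   "hidden_g and hidden_d need 3 positive widths each")
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_g = as.integer(hidden_g),
                 hidden_d = as.integer(hidden_d),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 output = output,
                 hard_fakes = isTRUE(hard_fakes),
                 seed = as.integer(seed),
                 activation = "relu"),
            class = "gan_config")
}

#' @export
print.gan_config <- function(x, ...) {
  cat(sprintf(
    "<gan_config> latent %d | G %s | D %s | lr %g | batch %d | seed %d\n",
    x$latent_dim, paste(x$hidden_g, collapse = "-"),
    paste(x$hidden_d, collapse = "-"), x$learning_rate, x$batch_size,
    x$seed))
  invisible(x)
}

# He-normal initialization of one dense network
init_mlp <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                 sd = sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
}

n_params <- function(tpl) tpl$offsets[length(tpl$offsets)]

#' Initialize a GAN
#'
#' Builds generator (latent to layout) and discriminator (layout to one real
#' score) with freshly seeded parameters and zeroed Adam state.
#' Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{gan_config}}.
#' @param layout_len flattened one-hot length, i.e.
#'   \code{\link{layout_length}(max_atoms)}.
#' @param max_atoms matrix edge length the layout belongs to.
#' @return An object of class \code{gan_state}.
#' @export
gan_init <- function(cfg, layout_len, max_atoms) {
  if (layout_len != layout_length(max_atoms))
    condition_stop("molevolve_config_error",
                   sprintf("layout_len %d does not match max_atoms %d (%d)",
                           layout_len, max_atoms, layout_length(max_atoms)))
  set.seed(cfg$seed)
  g <- init_mlp(c(cfg$latent_dim, cfg$hidden_g, layout_len))
  d <- init_mlp(c(layout_len, cfg$hidden_d, 1L))
  tpl_g <- net_template(g)
  tpl_d <- net_template(d)
  structure(list(g = g, d = d,
                 th_g = flatten_net(g), th_d = flatten_net(d),
                 output = cfg$output,
                 hard_fakes = isTRUE(cfg$hard_fakes),
                 tpl_g = tpl_g, tpl_d = tpl_d,
                 adam = list(g_m = numeric(n_params(tpl_g)),
                             g_v = numeric(n_params(tpl_g)),
                             d_m = numeric(n_params(tpl_d)),
                             d_v = numeric(n_params(tpl_d)),
                             t_g = 0L, t_d = 0L),
                 epoch = 0L, max_atoms = as.integer(max_atoms),
                 layout_len = as.integer(layout_len),
                 version = 2L),
            class = "gan_state")
}

#' @export
print.gan_state <- function(x, ...) {
  cat(sprintf("<gan_state> layout %d (max_atoms %d), %d epochs trained\n",
              x$layout_len, x$max_atoms, x$epoch))
  invisible(x)
}

relu <- function(x) x * (x > 0)

# forward pass storing activations; hidden layers relu, output linear
mlp_forward <- function(net, X) {
  acts <- vector("list", length(net) + 1L)
  acts[[1L]] <- X
  n <- nrow(X)
  for (l in seq_along(net)) {
    Z <- acts[[l]] %*% net[[l]]$W
    Z <- Z + rep(net[[l]]$b, each = n)
    acts[[l + 1L]] <- if (l < length(net)) relu(Z) else Z
  }
  acts
}

# backward pass: dOut is the gradient at the (linear) output; returns
# gradients per layer plus the gradient w.r.t. the input
mlp_backward <- function(net, acts, dOut) {
  L <- length(net)
  grads <- vector("list", L)
  delta <- dOut
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    dIn <- tcrossprod(delta, net[[l]]$W)
    if (l > 1L) dIn <- dIn * (acts[[l]] > 0)   # relu mask of layer l-1 output
    delta <- dIn
  }
  list(grads = grads, dInput = delta)
}

# parameter flattening: Adam runs on single vectors, which avoids R-level
# per-parameter bookkeeping in the hot loop
net_template <- function(net) {
  dims <- lapply(net, function(l) dim(l$W))
  nb <- vapply(net, function(l) length(l$b), integer(1))
  sizes <- vapply(seq_along(net), function(l)
    prod(dims[[l]]) + nb[l], numeric(1))
  list(dims = dims, nb = nb, offsets = c(0, cumsum(sizes)))
}

flatten_net <- function(net) {
  unlist(lapply(net, function(l) c(l$W, l$b)), use.names = FALSE)
}

unflatten_net <- function(theta, tpl) {
  lapply(seq_along(tpl$dims), function(l) {
    o <- tpl$offsets[l]
    nw <- prod(tpl$dims[[l]])
    list(W = matrix(theta[(o + 1):(o + nw)], tpl$dims[[l]][1L],
                    tpl$dims[[l]][2L]),
         b = theta[(o + nw + 1):(o + nw + tpl$nb[l])])
  })
}

# one Adam step on flattened parameters; returns list(theta, m, v)
adam_step_flat <- function(theta, m, v, grad, t, lr,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- m * beta1 + (1 - beta1) * grad
  v <- v * beta2 + (1 - beta2) * grad * grad
  theta <- theta - lr * (m / (1 - beta1^t)) /
    (sqrt(v / (1 - beta2^t)) + eps)
  list(theta = theta, m = m, v = v)
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

# The one-hot layout groups columns into contiguous channel blocks (5 per
# atom slot, then 4 per atom pair). For per-cell operations the layout is
# reshaped into two tall matrices with one row per (sample, cell) and one
# column per channel, so softmax/argmax run as a handful of vectorized calls
# instead of a loop over blocks.
to_chunks <- function(raw, L) {
  n <- nrow(raw)
  P <- (L * (L - 1L)) %/% 2L
  na <- N_ATOM_TYPES * L
  A <- raw[, seq_len(na), drop = FALSE]
  atoms <- matrix(aperm(array(A, c(n, N_ATOM_TYPES, L)), c(1L, 3L, 2L)),
                  n * L, N_ATOM_TYPES)
  bonds <- NULL
  if (P > 0L) {
    B <- raw[, (na + 1L):ncol(raw), drop = FALSE]
    bonds <- matrix(aperm(array(B, c(n, N_BOND_TYPES, P)), c(1L, 3L, 2L)),
                    n * P, N_BOND_TYPES)
  }
  list(atoms = atoms, bonds = bonds, n = n, L = L, P = P)
}

from_chunks <- function(ch) {
  A <- matrix(aperm(array(ch$atoms, c(ch$n, ch$L, N_ATOM_TYPES)),
                    c(1L, 3L, 2L)), ch$n, N_ATOM_TYPES * ch$L)
  if (ch$P == 0L) return(A)
  B <- matrix(aperm(array(ch$bonds, c(ch$n, ch$P, N_BOND_TYPES)),
                    c(1L, 3L, 2L)), ch$n, N_BOND_TYPES * ch$P)
  cbind(A, B)
}

chunk_softmax <- function(M) {
  if (is.null(M)) return(NULL)
  mx <- M[, 1L]
  for (j in 2:ncol(M)) mx <- pmax(mx, M[, j])
  E <- exp(M - mx)
  E / rowSums(E)
}

chunk_harden <- function(M) {
  if (is.null(M)) return(NULL)
  H <- matrix(0, nrow(M), ncol(M))
  H[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))] <- 1
  H
}

# per-cell softmax over the channel blocks of the one-hot layout
softmax_blocks <- function(Z, L) {
  ch <- to_chunks(Z, L)
  ch$atoms <- chunk_softmax(ch$atoms)
  ch$bonds <- chunk_softmax(ch$bonds)
  from_chunks(ch)
}

# backprop through the per-cell softmax: dZ = Y * (dY - sum(dY * Y)) per cell
softmax_blocks_grad <- function(Y, dY, L) {
  cy <- to_chunks(Y, L)
  cd <- to_chunks(dY, L)
  g <- function(Yc, dYc) {
    if (is.null(Yc)) return(NULL)
    Yc * (dYc - rowSums(Yc * dYc))
  }
  cd$atoms <- g(cy$atoms, cd$atoms)
  cd$bonds <- g(cy$bonds, cd$bonds)
  from_chunks(cd)
}

# per-cell argmax hardening to one-hot (what the discriminator sees when
# hard_fakes is on; gradients are passed straight through)
harden_blocks <- function(Y, L) {
  ch <- to_chunks(Y, L)
  ch$atoms <- chunk_harden(ch$atoms)
  ch$bonds <- chunk_harden(ch$bonds)
  from_chunks(ch)
}

# generator forward returning both pre-activation stack and final output
gen_forward <- function(state, Z) {
  acts <- mlp_forward(state$g, Z)
  out <- acts[[length(state$g) + 1L]]
  if (identical(state$output, "softmax"))
    out <- softmax_blocks(out, state$max_atoms)
  list(acts = acts, out = out)
}

#' Train the GAN for one epoch
#'
#' One pass over the population in shuffled minibatches. Per batch the
#' discriminator takes one Adam step on the minimax loss (real up, fake
#' down) and the generator one step on the non-saturating generator loss.
#'
#' @param state a \code{\link{gan_state}}.
#' @param pop a \code{\link{training_population}} (its cached one-hot
#'   encodings are the real data), or a numeric matrix of one-hot rows.
#' @param cfg the \code{\link{gan_config}} used at init.
#' @return The updated state; attribute \code{losses} holds the epoch-mean
#'   generator and discriminator losses.
#' @export
gan_train_epoch <- function(state, pop, cfg) {
  X <- if (is.matrix(pop)) pop else pop$onehot
  n <- nrow(X)
  if (is.null(n) || n == 0L)
    stop("gan_train_epoch: empty population", call. = FALSE)
  idx <- sample.int(n)
  starts <- seq(1L, n, by = cfg$batch_size)
  d_losses <- numeric(0); g_losses <- numeric(0)
  for (s in starts) {
    rows <- idx[s:min(s + cfg$batch_size - 1L, n)]
    B <- length(rows)
    real <- X[rows, , drop = FALSE]

    # --- discriminator step
    Z <- matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
    fake <- gen_forward(state, Z)$out
    if (state$hard_fakes) fake <- harden_blocks(fake, state$max_atoms)
    acts_r <- mlp_forward(state$d, real)
    acts_f <- mlp_forward(state$d, fake)
    s_r <- acts_r[[length(state$d) + 1L]]
    s_f <- acts_f[[length(state$d) + 1L]]
    d_loss <- mean(softplus(-s_r)) + mean(softplus(s_f))
    if (!is.finite(d_loss))
      condition_stop("molevolve_training_diverged",
                     sprintf("non-finite discriminator loss at epoch %d",
                             state$epoch + 1L))
    gr_r <- mlp_backward(state$d, acts_r,
                         (sigmoid(s_r) - 1) / B)$grads
    gr_f <- mlp_backward(state$d, acts_f, sigmoid(s_f) / B)$grads
    grad_d <- flatten_net(gr_r) + flatten_net(gr_f)
    state$adam$t_d <- state$adam$t_d + 1L
    upd <- adam_step_flat(state$th_d, state$adam$d_m,
                          state$adam$d_v, grad_d, state$adam$t_d,
                          cfg$learning_rate)
    state$th_d <- upd$theta
    state$d <- unflatten_net(upd$theta, state$tpl_d)
    state$adam$d_m <- upd$m
    state$adam$d_v <- upd$v

    # --- generator step (non-saturating: push D(fake) up)
    Z <- matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
    gf <- gen_forward(state, Z)
    d_in <- if (state$hard_fakes) harden_blocks(gf$out, state$max_atoms)
            else gf$out
    acts_d <- mlp_forward(state$d, d_in)
    s_f <- acts_d[[length(state$d) + 1L]]
    g_loss <- mean(softplus(-s_f))
    if (!is.finite(g_loss))
      condition_stop("molevolve_training_diverged",
                     sprintf("non-finite generator loss at epoch %d",
                             state$epoch + 1L))
    dFake <- mlp_backward(state$d, acts_d, (sigmoid(s_f) - 1) / B)$dInput
    if (identical(state$output, "softmax"))
      dFake <- softmax_blocks_grad(gf$out, dFake, state$max_atoms)
    gr_g <- mlp_backward(state$g, gf$acts, dFake)$grads
    state$adam$t_g <- state$adam$t_g + 1L
    upd <- adam_step_flat(state$th_g, state$adam$g_m,
                          state$adam$g_v, flatten_net(gr_g),
                          state$adam$t_g, cfg$learning_rate)
    state$th_g <- upd$theta
    state$g <- unflatten_net(upd$theta, state$tpl_g)
    state$adam$g_m <- upd$m
    state$adam$g_v <- upd$v

    d_losses <- c(d_losses, d_loss)
    g_losses <- c(g_losses, g_loss)
  }
  state$epoch <- state$epoch + 1L
  attr(state, "losses") <- c(g = mean(g_losses), d = mean(d_losses))
  state
}

# raw generator output for n latent draws (n x layout matrix)
gan_sample_raw <- function(state, n) {
  ld <- nrow(state$g[[1L]]$W)
  Z <- matrix(stats::rnorm(n * ld), n, ld)
  gen_forward(state, Z)$out
}

#' Sample molecules from the generator
#'
#' Draws standard-normal latent vectors, maps them through the generator
#' and discretizes each output into a molecular graph (per-cell argmax).
#'
#' @param state a trained (or fresh) \code{\link{gan_state}}.
#' @param n number of samples.
#' @return List of \code{n} \code{\link{mol_graph}} objects.
#' @export
gan_sample <- function(state, n) {
  stopifnot(n >= 1L)
  discretize(gan_sample_raw(state, n), state$max_atoms)
}

#' Pretrain a GAN on a fixed population
#'
#' Convenience wrapper: initializes a GAN and trains it for a number of
#' plain epochs on the population. The returned state can seed several
#' \code{\link{gan_evolve}} runs (e.g. one per strategy) so that all
#' conditions start from the same trained generator, exactly as a shared
#' burn-in inside \code{gan_evolve} would produce.
#'
#' @param pop a \code{\link{training_population}}.
#' @param cfg a \code{\link{gan_config}} (its seed drives initialization and
#'   the training stream).
#' @param epochs number of training epochs.
#' @return A \code{\link{gan_state}}.
#' @export
gan_pretrain <- function(pop, cfg, epochs) {
  state <- gan_init(cfg, layout_length(pop$max_atoms), pop$max_atoms)
  set.seed(cfg$seed)
  for (ep in seq_len(epochs)) state <- gan_train_epoch(state, pop, cfg)
  state
}

#' Discriminator scores for molecules
#'
#' @param state a \code{\link{gan_state}}.
#' @param x one-hot matrix, \code{molecule_set} or list of
#'   \code{\link{mol_graph}} objects.
#' @return Numeric vector of raw realness scores (higher = more like the
#'   training data).
#' @export
gan_discriminate <- function(state, x) {
  X <- if (is.matrix(x)) x
  else if (inherits(x, "molecule_set")) x$onehot
  else one_hot_matrix(x, state$max_atoms)
  drop(mlp_forward(state$d, X)[[length(state$d) + 1L]])
}

#' Save / load a GAN state
#'
#' The checkpoint is a single serialized archive (R RDS, version tagged in
#' the object) holding parameters, optimizer state and the epoch counter.
#'
#' @param state a \code{\link{gan_state}}.
#' @param path file path.
#' @return \code{gan_save} returns \code{path} invisibly; \code{gan_load}
#'   the restored \code{gan_state}.
#' @export
gan_save <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname gan_save
#' @export
gan_load <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "gan_state"))
  state
}
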