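# Parameter containers, initialization and the Adam optimizer for the
# decoding-policy networks. Parameters live in a flat named list of
# numeric matrices/vectors; gradients accumulate in an environment under
# the same names.

#' Policy network configuration
#'
#' Architecture hyperparameters of the decoding policies. Defaults mirror
#' the reference architecture: 16-dim atom embeddings, six graph-convolution
#' layers of widths 32, 64, 128, 128, 256, 256 with receptive field 3, a
#' two-layer fully connected trunk (256, 512), action heads with hidden
#' width 128, and for MolRNN a three-layer GRU stack of width 512. Desk-scale
#' experiments shrink these freely.
#'
#' @param model \code{"rnn"} (MolRNN) or \code{"mp"} (MolMP)
#' @param embed_dim atom embedding width
#' @param conv_widths integer vector of graph-convolution output widths
#' @param receptive_field largest path distance D aggregated by a layer
#' @param fc_widths widths of the two fully connected trunk layers
#' @param head_hidden hidden width of the per-atom action head
#' @param rnn_widths widths of the molecule-level GRU layers (MolRNN)
#' @param cond_dim length of the conditional code (0 = unconditional)
#' @return list of class \code{molgen_config}
#' @export
molgen_config <- function(model = c("rnn", "mp"),
                          embed_dim = 16L,
                          conv_widths = c(32L, 64L, 128L, 128L, 256L, 256L),
                          receptive_field = 3L,
                          fc_widths = c(256L, 512L),
                          head_hidden = 128L,
                          rnn_widths = c(512L, 512L, 512L),
                          cond_dim = 0L) {
  model <- match.arg(model)
  stopifnot(receptive_field >= 1L, embed_dim >= 1L, length(conv_widths) >= 1L,
            length(fc_widths) == 2L, cond_dim >= 0L)
  structure(list(model = model, embed_dim = as.integer(embed_dim),
                 conv_widths = as.integer(conv_widths),
                 receptive_field = as.integer(receptive_field),
                 fc_widths = as.integer(fc_widths),
                 head_hidden = as.integer(head_hidden),
                 rnn_widths = as.integer(rnn_widths),
                 cond_dim = as.integer(cond_dim)),
            class = "molgen_config")
}

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

# Initialize all policy parameters for a vocabulary of size n_a.
# Uses the current RNG state.
policy_init_params <- function(cfg, n_a, n_b = 4L) {
  P <- list()
  d0 <- cfg$embed_dim
  P$emb_type <- glorot(d0, n_a)
  P$emb_latest <- stats::rnorm(d0, sd = 0.1)
  widths <- c(d0, cfg$conv_widths)
  L <- length(cfg$conv_widths)
  for (l in seq_len(L)) {
    din <- widths[l]; dout <- widths[l + 1]
    P[[paste0("W", l)]] <- glorot(dout, din)
    P[[paste0("bconv", l)]] <- numeric(dout)
    for (b in seq_len(n_b)) P[[paste0("Th", l, "_", b)]] <- glorot(dout, din)
    if (cfg$receptive_field >= 2L)
      for (d in 2:cfg$receptive_field)
        P[[paste0("Ph", l, "_", d)]] <- glorot(dout, din)
    if (cfg$cond_dim > 0L) P[[paste0("Psi", l)]] <- glorot(dout, cfg$cond_dim)
  }
  skip <- sum(cfg$conv_widths)
  f1 <- cfg$fc_widths[1]; f2 <- cfg$fc_widths[2]
  P$U1 <- glorot(f1, skip); P$c1 <- numeric(f1)
  P$U2 <- glorot(f2, f1);   P$c2 <- numeric(f2)
  gd <- if (cfg$model == "rnn") cfg$rnn_widths[length(cfg$rnn_widths)] else f2
  hh <- cfg$head_hidden
  P$V1 <- glorot(hh, f2 + gd); P$d1 <- numeric(hh)
  P$V2 <- glorot(n_a * n_b + n_b, hh); P$d2 <- numeric(n_a * n_b + n_b)
  P$wstar <- glorot(1, gd); P$dstar <- 0
  P$ilogit <- numeric(n_a)
  if (cfg$cond_dim > 0L) P$icond <- glorot(n_a, cfg$cond_dim)
  if (cfg$model == "rnn") {
    xin <- 2 * f2
    for (j in seq_along(cfg$rnn_widths)) {
      hw <- cfg$rnn_widths[j]
      for (gate in c("z", "r", "h")) {
        P[[paste0("gruW", gate, j)]] <- glorot(hw, xin)
        P[[paste0("gruU", gate, j)]] <- glorot(hw, hw)
        P[[paste0("grub", gate, j)]] <- numeric(hw)
      }
      xin <- hw
    }
  }
  P
}

n_params <- function(P) sum(vapply(P, length, integer(1)))

grads_new <- function() new.env(parent = emptyenv())

grad_acc <- function(gr, name, val) {
  cur <- gr[[name]]
  if (is.null(cur)) gr[[name]] <- val else gr[[name]] <- cur + val
  invisible(NULL)
}

grads_scale <- function(gr, s) {
  for (nm in ls(gr)) gr[[nm]] <- gr[[nm]] * s
  invisible(NULL)
}

adam_new <- function(P) {
  list(m = lapply(P, function(x) x * 0), v = lapply(P, function(x) x * 0),
       t = 0L)
}

adam_step <- function(P, gr, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in ls(gr)) {
    g <- gr[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    P[[nm]] <- P[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = P, state = st)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
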