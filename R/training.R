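# Model fitting (Adam with the inverse-time/exponential learning-rate
# schedule), fine-tuning, and the generation loop.

#' Training configuration
#'
#' Optimization hyperparameters. Defaults mirror the reference setup: Adam
#' (beta1 0.9, beta2 0.999, eps 1e-8), initial learning rate 0.001 decayed
#' at rate 0.001 every 100 iterations, 5 epochs, mini-batches of 200.
#' The decay phrase admits two standard readings; both are provided:
#' \code{"inverse_time"} uses lr0 / (1 + decay * floor(t / every)),
#' \code{"exponential"} uses lr0 * (1 - decay)^floor(t / every).
#'
#' @param lr initial learning rate
#' @param lr_decay decay rate applied every \code{decay_every} iterations
#' @param decay_every iteration period of the decay schedule
#' @param epochs passes over the corpus
#' @param batch_size molecules per mini-batch
#' @param schedule \code{"inverse_time"} or \code{"exponential"}
#' @return list of class \code{train_config}
#' @export
train_config <- function(lr = 0.001, lr_decay = 0.001, decay_every = 100L,
                         epochs = 5L, batch_size = 200L,
                         schedule = c("inverse_time", "exponential")) {
  schedule <- match.arg(schedule)
  stopifnot(lr > 0, lr_decay >= 0, decay_every >= 1L, epochs >= 0L,
            batch_size >= 1L)
  structure(list(lr = lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), schedule = schedule),
            class = "train_config")
}

#' Fine-tuning configuration used for focused sub-corpora
#' @param ... overrides passed to \code{\link{train_config}}
#' @return a \code{train_config}
#' @export
fine_tune_config <- function(...) {
  defaults <- list(lr = 1e-4, lr_decay = 0.002, epochs = 10L)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

schedule_lr <- function(tc, iter) {
  steps <- floor((iter - 1L) / tc$decay_every)
  if (tc$schedule == "inverse_time") tc$lr / (1 + tc$lr_decay * steps)
  else tc$lr * (1 - tc$lr_decay)^steps
}

# precompute per-step graph features of a route (big win when routes are
# reused across epochs, i.e. alpha = 1)
route_with_feats <- function(route, vocab, D) {
  route$feats <- lapply(route$steps, function(s) {
    if (nrow(s$graph$atoms) == 0L) NULL
    else graph_features(s$graph, vocab, D)
  })
  route
}

#' Fit a sequential molecular-graph generative model
#'
#' Trains a decoding policy (MolMP or MolRNN) on a corpus of molecules by
#' minimizing the importance-weighted negative log-likelihood over decoding
#' routes drawn from q_alpha. Returns a classed model object with
#' \code{print}, \code{summary}, \code{coef}, \code{logLik}, \code{plot},
#' \code{predict} and \code{simulate} methods; \code{simulate} generates
#' molecules.
#'
#' @param corpus character vector of SMILES, one molecule each
#' @param model \code{"rnn"} (MolRNN, default) or \code{"mp"} (MolMP)
#' @param condition optional numeric matrix of conditional codes, one row
#'   per corpus molecule; enables the conditional architecture
#' @param config a \code{\link{molgen_config}}; defaults to the reference
#'   architecture for the chosen model (with \code{cond_dim} taken from
#'   \code{condition})
#' @param loss a \code{\link{loss_config}}
#' @param train a \code{\link{train_config}}
#' @param vocab optional pre-built \code{\link{build_vocab}} result
#' @param seed integer seed controlling initialization and route sampling
#' @param verbose print per-iteration loss
#' @return object of class \code{molgen}
#' @export
molgen <- function(corpus, model = c("rnn", "mp"), condition = NULL,
                   config = NULL, loss = loss_config(),
                   train = train_config(), vocab = NULL, seed = 1L,
                   verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(length(corpus) >= 1L)
  set.seed(seed)
  if (is.null(vocab)) vocab <- build_vocab(corpus)
  cond_dim <- if (is.null(condition)) 0L else ncol(condition)
  if (!is.null(condition)) {
    condition <- as.matrix(condition)
    stopifnot(nrow(condition) == length(corpus))
  }
  if (is.null(config)) config <- molgen_config(model = model,
                                               cond_dim = cond_dim)
  stopifnot(config$model == model, config$cond_dim == cond_dim)
  P <- policy_init_params(config, nrow(vocab))
  fitted <- train_policy(P, config, vocab, corpus, condition, loss, train,
                         verbose)
  structure(list(params = fitted$params, config = config, vocab = vocab,
                 loss = loss, train = train, trace = fitted$trace,
                 corpus = corpus,
                 corpus_canonical = unique(canonical_smiles(corpus)),
                 condition = condition, seed = seed, call = match.call()),
            class = "molgen")
}

train_policy <- function(P, cfg, vocab, corpus, condition, loss, tc,
                         verbose = FALSE) {
  graphs <- lapply(corpus, graph_from_smiles)
  deterministic <- loss$alpha == 1
  canon <- NULL
  if (deterministic) {
    canon <- lapply(graphs, function(g)
      route_with_feats(canonical_route(g), vocab, cfg$receptive_field))
  }
  n <- length(graphs)
  adam <- adam_new(P)
  trace <- list()
  iter <- 0L
  if (tc$epochs > 0L) for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n)]
      iter <- iter + 1L
      gr <- grads_new()
      bundle <- list(params = P, config = cfg, vocab = vocab)
      losses <- numeric(length(idx))
      for (q in seq_along(idx)) {
        i <- idx[q]
        cvec <- if (is.null(condition)) NULL else condition[i, ]
        routes <- if (deterministic) list(canon[[i]]) else NULL
        losses[q] <- iw_nll_grad(bundle, graphs[[i]], loss, cvec, gr,
                                 routes = routes, weight = 1 / length(idx))
      }
      loss_val <- mean(losses)
      if (!is.finite(loss_val))
        stop("non-finite training loss at iteration ", iter,
             " (lr = ", schedule_lr(tc, iter), ")", call. = FALSE)
      lr <- schedule_lr(tc, iter)
      upd <- adam_step(P, gr, adam, lr)
      P <- upd$params; adam <- upd$state
      trace[[iter]] <- data.frame(iteration = iter, epoch = ep,
                                  loss = loss_val, lr = lr)
      if (verbose) message(sprintf("iter %d  loss %.4f  lr %.2e", iter,
                                   loss_val, lr))
    }
  }
  list(params = P,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(iteration = integer(0), epoch = integer(0),
                               loss = numeric(0), lr = numeric(0)))
}

#' Fine-tune a fitted model on a focused sub-corpus
#'
#' Continues optimization from the fitted parameters with the fine-tuning
#' schedule (default: learning rate 1e-4, decay 0.002 per 100 iterations,
#' 10 epochs). The sub-corpus must be covered by the model's vocabulary.
#'
#' @param object a fitted \code{molgen}
#' @param corpus character vector of SMILES to focus on
#' @param condition optional condition matrix (rows match \code{corpus})
#' @param train a \code{\link{train_config}}; default
#'   \code{fine_tune_config()}
#' @param loss loss configuration; defaults to the original fit's
#' @param seed integer seed
#' @return the updated \code{molgen} object
#' @export
fine_tune <- function(object, corpus, condition = NULL,
                      train = fine_tune_config(), loss = NULL, seed = 1L) {
  stopifnot(inherits(object, "molgen"), length(corpus) >= 1L)
  if (is.null(loss)) loss <- object$loss
  if (!is.null(condition)) condition <- as.matrix(condition)
  set.seed(seed)
  fitted <- train_policy(object$params, object$config, object$vocab, corpus,
                         condition, loss, train)
  object$params <- fitted$params
  object$trace <- rbind(object$trace,
                        transform(fitted$trace,
                                  iteration = iteration +
                                    max(0L, object$trace$iteration)))
  object
}

#' Generation configuration
#' @param max_steps cap on decoding transitions per molecule (>= 2)
#' @param temperature softmax temperature on the action scores
#' @return list of class \code{generation_config}
#' @export
generation_config <- function(max_steps = 100L, temperature = 1) {
  stopifnot(max_steps >= 2L, temperature > 0)
  structure(list(max_steps = as.integer(max_steps), temperature = temperature),
            class = "generation_config")
}

#' Generate molecules from a fitted model
#'
#' Iteratively samples transitions from the policy until termination or the
#' step cap. At sampling time, connect actions targeting \code{v*} itself
#' or atoms already bonded to \code{v*} are masked (structurally impossible
#' moves); chemical validity is not enforced during decoding and is
#' assessed only on the finished graph.
#'
#' @param model a fitted \code{molgen}
#' @param n number of molecules to sample
#' @param condition a condition vector applied to every sample, or a matrix
#'   with \code{n} rows
#' @param gen a \code{\link{generation_config}}
#' @param seed optional integer seed
#' @return data.frame with columns \code{smiles} (canonical SMILES, NA when
#'   invalid), \code{status} (\code{ok}, \code{invalid_chemistry},
#'   \code{step_cap}) and \code{n_atoms}; the generated graphs are attached
#'   as attribute \code{graphs}
#' @export
generate <- function(model, n = 1L, condition = NULL,
                     gen = generation_config(), seed = NULL) {
  stopifnot(inherits(model, "molgen"))
  if (!is.null(seed)) set.seed(seed)
  P <- model$params; cfg <- model$config; vocab <- model$vocab
  n_a <- nrow(vocab); n_b <- 4L
  if (!is.null(condition)) {
    condition <- if (is.matrix(condition)) condition
                 else matrix(condition, nrow = n, ncol = length(condition),
                             byrow = TRUE)
    stopifnot(nrow(condition) == n, ncol(condition) == cfg$cond_dim)
  }
  graphs <- vector("list", n)
  status <- character(n)
  smiles <- rep(NA_character_, n)
  for (s in seq_len(n)) {
    cvec <- if (is.null(condition)) NULL else condition[s, ]
    res <- generate_one(P, cfg, vocab, cvec, gen)
    graphs[[s]] <- res$graph
    status[s] <- res$status
    if (res$status != "step_cap") {
      smi <- tryCatch(smiles_from_graph(res$graph),
                      error = function(e) NA_character_)
      if (is.na(smi)) status[s] <- "invalid_chemistry" else smiles[s] <- smi
    }
  }
  out <- data.frame(smiles = smiles, status = status,
                    n_atoms = vapply(graphs, n_atoms, integer(1)))
  attr(out, "graphs") <- graphs
  out
}

generate_one <- function(P, cfg, vocab, cvec, gen) {
  n_a <- nrow(vocab); n_b <- 4L
  lp0 <- init_policy_logp(P, cvec)
  ai <- sample.int(n_a, 1L, prob = exp(lp0))
  g <- apply_transition(molgraph(), t_init(vocab$symbol[ai], vocab$nh[ai],
                                           vocab$charge[ai]))
  state <- if (cfg$model == "rnn") rnn_state_new(cfg) else NULL
  steps <- 1L
  repeat {
    if (steps >= gen$max_steps) return(list(graph = g, status = "step_cap"))
    po <- policy_forward(P, cfg, vocab, g, cvec, state)
    state <- po$state
    n <- po$n
    sc <- c(as.vector(po$log_append), po$log_term) / gen$temperature
    p <- exp(sc - logsumexp(sc))
    # mask structurally impossible connects: v* itself and existing partners
    vstar <- g$latest
    blocked <- vstar
    if (nrow(g$bonds) > 0) {
      bb <- g$bonds
      blocked <- c(blocked, bb$j[bb$i == vstar], bb$i[bb$j == vstar])
    }
    nrowY <- n_a * n_b + n_b
    for (v in blocked)
      p[(v - 1L) * nrowY + (n_a * n_b + 1L):(n_a * n_b + n_b)] <- 0
    p <- p / sum(p)
    pick <- sample.int(length(p), 1L, prob = p)
    steps <- steps + 1L
    if (pick == length(p)) return(list(graph = g, status = "ok"))
    col <- (pick - 1L) %/% nrowY + 1L
    row <- (pick - 1L) %% nrowY + 1L
    if (row <= n_a * n_b) {
      a <- (row - 1L) %% n_a + 1L
      b <- (row - 1L) %/% n_a + 1L
      g <- apply_transition(g, t_append(col, vocab$symbol[a], vocab$nh[a],
                                        vocab$charge[a], b))
    } else {
      b <- row - n_a * n_b
      g <- apply_transition(g, t_connect(col, b))
    }
  }
}

# --- S3 methods -----------------------------------------------------------

#' @export
print.molgen <- function(x, ...) {
  cat(sprintf("Sequential graph generative model (%s)\n",
              if (x$config$model == "rnn") "MolRNN" else "MolMP"))
  cat(sprintf("  vocabulary: %d atom types; %s\n", nrow(x$vocab),
              if (x$config$cond_dim > 0)
                sprintf("conditional (code length %d)", x$config$cond_dim)
              else "unconditional"))
  cat(sprintf("  parameters: %d;  trained %d iterations (alpha = %.2f, k = %d)\n",
              n_params(x$params), nrow(x$trace), x$loss$alpha, x$loss$k))
  if (nrow(x$trace) > 0)
    cat(sprintf("  final training loss: %.4f\n",
                x$trace$loss[nrow(x$trace)]))
  invisible(x)
}

#' @export
summary.molgen <- function(object, ...) {
  structure(list(model = object), class = "summary.molgen")
}

#' @export
print.summary.molgen <- function(x, ...) {
  m <- x$model
  print(m)
  cfg <- m$config
  cat(sprintf("  architecture: embed %d | conv %s (D = %d) | fc %s | head %d%s\n",
              cfg$embed_dim, paste(cfg$conv_widths, collapse = "-"),
              cfg$receptive_field, paste(cfg$fc_widths, collapse = "-"),
              cfg$head_hidden,
              if (cfg$model == "rnn")
                paste0(" | gru ", paste(cfg$rnn_widths, collapse = "-"))
              else ""))
  if (nrow(m$trace) > 0) {
    cat("  loss trace quartiles:\n")
    print(stats::quantile(m$trace$loss))
  }
  invisible(x)
}

#' @export
coef.molgen <- function(object, ...) object$params

#' @export
logLik.molgen <- function(object, ...) {
  graphs <- lapply(object$corpus, graph_from_smiles)
  bundle <- as_policy_bundle(object)
  ll <- sum(vapply(seq_along(graphs), function(i) {
    cvec <- if (is.null(object$condition)) NULL else object$condition[i, ]
    route_score(bundle, canonical_route(graphs[[i]]), cvec)$logp
  }, numeric(1)))
  structure(ll, df = n_params(object$params), nobs = length(object$corpus),
            class = "logLik")
}

#' @export
plot.molgen <- function(x, ...) {
  if (nrow(x$trace) == 0) stop("no training trace to plot", call. = FALSE)
  graphics::plot(x$trace$iteration, x$trace$loss, type = "l",
                 xlab = "iteration", ylab = "negative log-likelihood",
                 main = "Training loss", ...)
  invisible(x)
}

#' Per-molecule log-likelihood estimates
#'
#' \code{type = "canonical"} scores the deterministic canonical route
#' (a lower bound on log p(G)); \code{type = "iw"} returns the
#' importance-weighted estimate under the model's loss configuration.
#'
#' @param object a fitted \code{molgen}
#' @param newdata character vector of SMILES
#' @param type \code{"canonical"} or \code{"iw"}
#' @param condition optional condition matrix (rows match \code{newdata})
#' @param ... unused
#' @return numeric vector of log-likelihood values
#' @export
predict.molgen <- function(object, newdata, type = c("canonical", "iw"),
                           condition = NULL, ...) {
  type <- match.arg(type)
  bundle <- as_policy_bundle(object)
  vapply(seq_along(newdata), function(i) {
    g <- graph_from_smiles(newdata[i])
    cvec <- if (is.null(condition)) NULL else condition[i, ]
    if (type == "canonical")
      route_score(bundle, canonical_route(g), cvec)$logp
    else -iw_nll(bundle, g, object$loss, cvec)
  }, numeric(1))
}

#' Simulate molecules from a fitted model
#'
#' @param object a fitted \code{molgen}
#' @param nsim number of molecules
#' @param seed optional integer seed
#' @param condition optional condition vector or matrix
#' @param gen a \code{\link{generation_config}}
#' @param ... unused
#' @return the \code{\link{generate}} data.frame
#' @export
simulate.molgen <- function(object, nsim = 1, seed = NULL, condition = NULL,
                            gen = generation_config(), ...) {
  generate(object, n = nsim, condition = condition, gen = gen, seed = seed)
}
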