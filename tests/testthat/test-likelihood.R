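# Likelihood machinery: per-route scoring, the importance-weighted bound,
# and the enumeration oracle.

test_that("route log-probability matches step-by-step accumulation", {
  vocab <- small_vocab()
  for (model in c("mp", "rnn")) {
    bundle <- random_policy(tiny_config(model), vocab, seed = 3L)
    g <- graph_from_smiles("CC(=O)N")
    route <- canonical_route(g)
    # independent accumulation using raw forward passes
    n_a <- nrow(vocab)
    state <- if (model == "rnn") molgraphgen:::rnn_state_new(bundle$config)
             else NULL
    manual <- 0
    for (k in seq_along(route$steps)) {
      tr <- route$steps[[k]]$transition
      if (k == 1L) {
        lp <- molgraphgen:::init_policy_logp(bundle$params)
        ai <- vocab_index(vocab, data.frame(symbol = tr$symbol, nh = tr$nh,
                                            charge = tr$charge))
        manual <- manual + lp[ai]
        next
      }
      po <- molgraphgen:::policy_forward(bundle$params, bundle$config, vocab,
                                         route$steps[[k]]$graph, state = state)
      state <- po$state
      manual <- manual + switch(tr$tag,
        terminate = po$log_term,
        append = po$log_append[(tr$bond - 1L) * n_a +
          vocab_index(vocab, data.frame(symbol = tr$symbol, nh = tr$nh,
                                        charge = tr$charge)), tr$anchor],
        connect = po$log_append[n_a * 4L + tr$bond, tr$target])
    }
    expect_equal(route_logp(bundle, route), as.numeric(manual),
                 tolerance = 1e-12)
  }
})

test_that("a single-atom molecule scores as init plus terminate", {
  vocab <- small_vocab()
  bundle <- random_policy(tiny_config("mp"), vocab, seed = 9L)
  g <- graph_from_smiles("C")
  route <- canonical_route(g)
  lp_init <- molgraphgen:::init_policy_logp(bundle$params)
  ai <- vocab_index(vocab, g$atoms)
  po <- molgraphgen:::policy_forward(bundle$params, bundle$config, vocab,
                                     apply_transition(molgraph(), t_init("C")))
  expect_equal(route_logp(bundle, route),
               as.numeric(lp_init[ai] + po$log_term), tolerance = 1e-12)
})

test_that("alpha = 1 importance weighting is the deterministic exact NLL", {
  vocab <- small_vocab()
  bundle <- random_policy(tiny_config("rnn"), vocab, seed = 4L)
  g <- graph_from_smiles("CCO")
  set.seed(1); l1 <- iw_nll(bundle, g, loss_config(alpha = 1))
  set.seed(999); l2 <- iw_nll(bundle, g, loss_config(alpha = 1))
  expect_identical(l1, l2)
  expect_equal(l1, -route_logp(bundle, canonical_route(g)),
               tolerance = 1e-12)
  # identical routes collapse the log-mean-exp to the single-route value
  l5 <- iw_nll(bundle, g, loss_config(alpha = 1, k = 5))
  expect_equal(l5, l1, tolerance = 1e-12)
})

test_that("the importance-weighted estimate agrees with enumeration", {
  vocab <- small_vocab()
  bundle <- random_policy(tiny_config("mp"), vocab, seed = 21L)
  set.seed(55)
  for (smi in c("CCO", "C=O", "CCC")) {
    g <- graph_from_smiles(smi)
    exact <- enumerate_logp(bundle, g)
    cache <- new.env(parent = emptyenv())
    memo <- new.env(parent = emptyenv())
    k <- 3000
    lw <- numeric(k)
    for (i in seq_len(k)) {
      r <- sample_route(g, 0.6, cache = cache)
      key <- molgraphgen:::route_key(r)
      lp <- memo[[key]]
      if (is.null(lp)) {
        lp <- route_logp(bundle, r)
        memo[[key]] <- lp
      }
      lw[i] <- lp - r$log_q
    }
    w <- exp(lw)
    z <- (mean(w) - exp(exact)) / (stats::sd(w) / sqrt(k))
    expect_lt(abs(z), 3)
  }
})

test_that("the bound holds and total probability mass is below one", {
  vocab <- small_vocab()
  bundle <- random_policy(tiny_config("mp"), vocab, seed = 6L)
  g <- graph_from_smiles("CCO")
  exact <- enumerate_logp(bundle, g)
  set.seed(10)
  cache <- new.env(parent = emptyenv())
  ests <- vapply(1:300, function(i)
    -iw_nll(bundle, g, loss_config(alpha = 0.6, k = 3), cache = cache),
    numeric(1))
  # Jensen: the importance-weighted lower bound sits below log p(G)
  expect_lt(mean(ests), exact)
  expect_gt(mean(ests), exact - 2)  # and not absurdly loose here

  # total mass over all molecules of <= 2 atoms cannot exceed one
  n_a <- nrow(vocab)
  mass <- 0
  for (a in seq_len(n_a)) {
    g1 <- molgraph(vocab[a, , drop = FALSE])
    mass <- mass + exp(enumerate_logp(bundle, g1))
  }
  for (a in seq_len(n_a)) for (b in seq_len(n_a)) for (t in 1:3) {
    if (b < a) next
    g2 <- molgraph(rbind(vocab[a, ], vocab[b, ]),
                   data.frame(i = 1L, j = 2L, type = t))
    mass <- mass + exp(enumerate_logp(bundle, g2))
  }
  expect_lte(mass, 1)
  expect_gt(mass, 0)
})

test_that("transitions outside the vocabulary raise a typed error", {
  vocab <- build_vocab(c("CCO"))
  bundle <- random_policy(tiny_config("mp"), vocab, seed = 2L)
  g <- graph_from_smiles("CCN")
  expect_error(route_logp(bundle, canonical_route(g)),
               class = "molgraphgen_vocab_error")
})
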