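# Decoding policies: joint normalization, equivariance, locality,
# conditional sensitivity, recurrent history dependence, and exactness of
# the hand-written gradients.

test_that("policy outputs are jointly normalized for both architectures", {
  vocab <- small_vocab()
  graphs <- lapply(c("C", "CCO", "c1ccccc1", "CC(=O)N"), graph_from_smiles)
  graphs <- lapply(graphs, function(g) { g$latest <- n_atoms(g); g })
  for (model in c("mp", "rnn")) {
    for (cond in c(0L, 3L)) {
      bundle <- random_policy(tiny_config(model, cond = cond), vocab)
      cvec <- if (cond > 0) c(0.3, -1, 2) else NULL
      state <- NULL
      for (g in graphs) {
        po <- molgraphgen:::policy_forward(bundle$params, bundle$config,
                                           vocab, g, cvec, state)
        state <- po$state
        expect_lt(abs(policy_mass(po) - 1), 1e-6)
        expect_true(all(exp(po$log_append) > 0))  # exponential heads
        expect_gt(exp(po$log_term), 0)
      }
    }
  }
})

test_that("policy outputs are permutation-equivariant", {
  vocab <- small_vocab()
  g <- graph_from_smiles("CC(=O)N")
  g$latest <- 2L
  bundle <- random_policy(tiny_config("mp"), vocab)
  po <- molgraphgen:::policy_forward(bundle$params, bundle$config, vocab, g)
  set.seed(8)
  perm <- sample(n_atoms(g))
  gp <- permute_molgraph(g, perm)
  pop <- molgraphgen:::policy_forward(bundle$params, bundle$config, vocab, gp)
  for (v in seq_len(n_atoms(g)))
    expect_equal(pop$log_append[, perm[v]], po$log_append[, v],
                 tolerance = 1e-10)
  expect_equal(pop$log_term, po$log_term, tolerance = 1e-10)
})

test_that("receptive field limits information flow in the trunk", {
  # with one conv layer and D = 1, the trunk output of an atom cannot see
  # atoms at distance >= 2
  vocab <- small_vocab()
  cfg <- molgen_config(model = "mp", embed_dim = 4L, conv_widths = 6L,
                       receptive_field = 1L, fc_widths = c(6L, 6L),
                       head_hidden = 4L)
  set.seed(5)
  P <- molgraphgen:::policy_init_params(cfg, nrow(vocab))
  g1 <- graph_from_smiles("CCCO")  # O at distance 3 from atom 1
  g2 <- graph_from_smiles("CCCN")
  g1$latest <- 1L; g2$latest <- 1L
  t1 <- molgraphgen:::trunk_forward(
    P, cfg, molgraphgen:::graph_features(g1, vocab, cfg$receptive_field))
  t2 <- molgraphgen:::trunk_forward(
    P, cfg, molgraphgen:::graph_features(g2, vocab, cfg$receptive_field))
  expect_equal(t1$F2[, 1], t2$F2[, 1], tolerance = 1e-12)
  expect_equal(t1$F2[, 2], t2$F2[, 2], tolerance = 1e-12)
  # the far end differs, so the graphs are genuinely distinct
  expect_gt(max(abs(t1$F2[, 4] - t2$F2[, 4])), 0)
})

test_that("conditional code enters iff the conditional weights are nonzero", {
  vocab <- small_vocab()
  bundle <- random_policy(tiny_config("mp", cond = 2L), vocab)
  g <- graph_from_smiles("CCO"); g$latest <- 3L
  po1 <- molgraphgen:::policy_forward(bundle$params, bundle$config, vocab, g,
                                      c(1, 0))
  po2 <- molgraphgen:::policy_forward(bundle$params, bundle$config, vocab, g,
                                      c(0, 1))
  expect_gt(max(abs(po1$log_append - po2$log_append)), 1e-6)

  P0 <- bundle$params
  for (nm in grep("^Psi", names(P0), value = TRUE)) P0[[nm]][] <- 0
  po3 <- molgraphgen:::policy_forward(P0, bundle$config, vocab, g, c(1, 0))
  po4 <- molgraphgen:::policy_forward(P0, bundle$config, vocab, g, c(0, 1))
  expect_equal(po3$log_append, po4$log_append, tolerance = 1e-12)
})

test_that("the latest-atom flag changes the embedding", {
  vocab <- small_vocab()
  bundle <- random_policy(tiny_config("mp"), vocab)
  g <- graph_from_smiles("CCC")
  ga <- g; ga$latest <- 1L
  gb <- g; gb$latest <- 3L
  poa <- molgraphgen:::policy_forward(bundle$params, bundle$config, vocab, ga)
  pob <- molgraphgen:::policy_forward(bundle$params, bundle$config, vocab, gb)
  expect_gt(max(abs(poa$log_append - pob$log_append)), 1e-8)
})

test_that("MolRNN output depends on the decoding history", {
  vocab <- small_vocab()
  bundle <- random_policy(tiny_config("rnn"), vocab)
  g <- graph_from_smiles("CCO")
  # the same graph state scored under two different recurrent histories
  g3 <- g; g3$latest <- 3L
  s0 <- molgraphgen:::rnn_state_new(bundle$config)
  g1 <- apply_transition(molgraph(), t_init("C"))
  step1 <- molgraphgen:::policy_forward(bundle$params, bundle$config, vocab,
                                        g1, state = s0)
  withhist <- molgraphgen:::policy_forward(bundle$params, bundle$config,
                                           vocab, g3, state = step1$state)
  nohist <- molgraphgen:::policy_forward(bundle$params, bundle$config,
                                         vocab, g3, state = s0)
  expect_gt(max(abs(withhist$log_append - nohist$log_append)), 1e-8)

  # zero recurrent weights: the GRU state stays at its fixed point and the
  # policy reduces to a history-free map
  P0 <- bundle$params
  for (nm in grep("^gru", names(P0), value = TRUE)) P0[[nm]][] <- 0
  b0 <- list(params = P0, config = bundle$config, vocab = vocab)
  g1 <- g; g1$latest <- 1L
  s0 <- molgraphgen:::rnn_state_new(bundle$config)
  poA <- molgraphgen:::policy_forward(P0, bundle$config, vocab, g1, state = s0)
  poB <- molgraphgen:::policy_forward(P0, bundle$config, vocab, g1,
                                      state = poA$state)
  expect_equal(poA$log_append, poB$log_append, tolerance = 1e-12)
})

test_that("initial-atom distribution is a proper categorical", {
  vocab <- small_vocab()
  bundle <- random_policy(tiny_config("mp"), vocab)
  p <- init_distribution(bundle$params)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p > 0))
  Pu <- bundle$params; Pu$ilogit[] <- 0
  expect_equal(unname(init_distribution(Pu)),
               rep(1 / nrow(vocab), nrow(vocab)), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  vocab <- small_vocab()
  g <- graph_from_smiles("CC(=O)N")
  for (model in c("mp", "rnn")) {
    bundle <- random_policy(tiny_config(model), vocab, seed = 31L)
    set.seed(77)
    route <- sample_route(g, 0.7)
    gr <- molgraphgen:::grads_new()
    molgraphgen:::route_nll_grad(bundle, route, NULL, gr, weight = 1)
    eps <- 1e-5
    set.seed(78)
    for (nm in sample(ls(gr), 12)) {
      x <- bundle$params[[nm]]
      ii <- sample(length(x), 1)
      bp <- bundle; bp$params[[nm]][ii] <- bp$params[[nm]][ii] + eps
      bm <- bundle; bm$params[[nm]][ii] <- bm$params[[nm]][ii] - eps
      num <- (-molgraphgen:::route_score(bp, route, NULL)$logp +
                molgraphgen:::route_score(bm, route, NULL)$logp) / (2 * eps)
      ana <- gr[[nm]][ii]
      expect_equal(ana, num, tolerance = 1e-3,
                   label = paste("grad", model, nm))
    }
  }
})
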