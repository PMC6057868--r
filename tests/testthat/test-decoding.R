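# Decoding scheme: transition application, canonical routes, the
# alpha-randomized route sampler, and the |E| + 2 length law.

test_that("transitions apply structurally and reject misuse", {
  g1 <- apply_transition(molgraph(), t_init("C"))
  expect_equal(n_atoms(g1), 1L)
  expect_equal(g1$latest, 1L)

  g2 <- apply_transition(g1, t_append(1L, "C", bond = 1L))
  expect_equal(n_atoms(g2), 2L)
  expect_equal(n_bonds(g2), 1L)
  expect_equal(g2$latest, 2L)

  chain <- apply_transition(g2, t_append(2L, "C", bond = 1L))
  ring <- apply_transition(chain, t_connect(1L, 1L))
  expect_equal(n_bonds(ring), 3L)          # cyclopropane skeleton
  expect_equal(ring$latest, 3L)            # connect leaves v* unchanged

  expect_error(apply_transition(g1, t_init("C")),
               class = "molgraphgen_transition_error")
  expect_error(apply_transition(g2, t_connect(1L, 1L)),
               class = "molgraphgen_transition_error")  # bond exists
  expect_error(apply_transition(g2, t_connect(2L, 1L)),
               class = "molgraphgen_transition_error")  # target is v*
  expect_error(apply_transition(g1, t_append(5L, "C")),
               class = "molgraphgen_transition_error")
})

test_that("route length equals |E| + 2", {
  bz <- graph_from_smiles("c1ccccc1")
  expect_equal(route_length(bz), 8L)
  expect_equal(length(canonical_route(bz)$steps), 8L)

  me <- graph_from_smiles("C")
  expect_equal(route_length(me), 2L)
  expect_equal(length(canonical_route(me)$steps), 2L)

  cim <- graph_from_smiles("CC1=C(N=CN1)CSCCNC(=NC)NC#N")
  expect_equal(route_length(cim), n_bonds(cim) + 2L)
  expect_equal(length(canonical_route(cim)$steps), route_length(cim))

  disc <- molgraph(data.frame(symbol = c("C", "C"), nh = 0L, charge = 0L))
  expect_error(route_length(disc), "disconnected")
  expect_error(canonical_route(disc), "disconnected")
})

test_that("canonical routes are deterministic and replay to the molecule", {
  for (smi in bundled_corpus()[1:10]) {
    g <- graph_from_smiles(smi)
    r1 <- canonical_route(g)
    r2 <- canonical_route(g)
    expect_identical(molgraphgen:::route_key(r1), molgraphgen:::route_key(r2))
    expect_equal(r1$log_q, 0)
    expect_identical(smiles_from_graph(replay_route(r1)),
                     canonical_smiles(smi))
  }
})

test_that("sampled routes always replay to the molecule with length |E|+2", {
  mols <- bundled_corpus()[c("cimetidine", "aspirin", "nicotine", "imidazole",
                             "piperidine")]
  set.seed(99)
  for (rep in 1:40) {
    smi <- sample(mols, 1)
    g <- graph_from_smiles(smi)
    alpha <- runif(1)
    r <- sample_route(g, alpha)
    expect_equal(length(r$steps), n_bonds(g) + 2L)
    expect_identical(smiles_from_graph(replay_route(r)),
                     canonical_smiles(smi))
    expect_lte(r$log_q, 0)
  }
})

test_that("alpha = 1 reduces q_alpha to the canonical route", {
  g <- graph_from_smiles("CC(=O)Nc1ccc(O)cc1")
  set.seed(1)
  r <- sample_route(g, 1)
  expect_identical(molgraphgen:::route_key(r),
                   molgraphgen:::route_key(canonical_route(g)))
  expect_equal(r$log_q, 0)

  # methane admits a unique route regardless of alpha
  me <- graph_from_smiles("C")
  set.seed(2)
  r2 <- sample_route(me, 0.3)
  expect_equal(length(r2$steps), 2L)
  expect_equal(r2$log_q, 0)
})

test_that("q_alpha is a probability distribution over distinct routes", {
  # on a 3-atom molecule the route set is enumerable; empirical sampling
  # must realize routes whose exact q-probabilities sum to one
  g <- graph_from_smiles("CCO")
  cache <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  set.seed(7)
  for (i in 1:4000) {
    r <- sample_route(g, 0.5, cache = cache)
    seen[[molgraphgen:::route_key(r)]] <- r$log_q
  }
  mass <- sum(exp(unlist(as.list(seen))))
  expect_equal(length(ls(seen)), length(enumerate_routes(g)))
  expect_equal(mass, 1, tolerance = 1e-12)
})

test_that("route enumeration matches hand counts", {
  # symmetric 3-chain: start at an end (1 route) or in the middle (1 route)
  expect_length(enumerate_routes(graph_from_smiles("CCC")), 2L)
  # asymmetric 3-chain: 1 (from C end) + 2 (from middle) + 1 (from O end)
  expect_length(enumerate_routes(graph_from_smiles("CCO")), 4L)
  expect_length(enumerate_routes(graph_from_smiles("C")), 1L)
  expect_error(enumerate_routes(graph_from_smiles("c1ccccc1"), max_atoms = 5L),
               "enumeration bound")
})

test_that("route dumps are valid JSON lines", {
  r <- canonical_route(graph_from_smiles("CCO"))
  path <- tempfile(fileext = ".jsonl")
  route_dump(r, path)
  lines <- readLines(path)
  expect_length(lines, length(r$steps))
  rec <- jsonlite::fromJSON(lines[2])
  expect_true(rec$action_tag %in% c("init", "append", "connect", "terminate"))
  expect_true(nzchar(rec$cumulative_smiles))
})
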