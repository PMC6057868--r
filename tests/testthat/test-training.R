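# Optimization loop, schedules, fine-tuning, and the sampling loop.

test_that("learning-rate schedules follow their stated forms", {
  tc <- train_config(lr = 0.001, lr_decay = 0.001, decay_every = 100L)
  expect_equal(molgraphgen:::schedule_lr(tc, 1), 0.001)
  expect_equal(molgraphgen:::schedule_lr(tc, 100), 0.001)
  expect_equal(molgraphgen:::schedule_lr(tc, 101), 0.001 / 1.001)
  expect_equal(molgraphgen:::schedule_lr(tc, 301), 0.001 / 1.003)
  te <- train_config(lr = 0.001, lr_decay = 0.001, decay_every = 100L,
                     schedule = "exponential")
  expect_equal(molgraphgen:::schedule_lr(te, 201), 0.001 * 0.999^2)
})

test_that("zero epochs leave the parameters untouched", {
  set.seed(5)
  m <- molgen("CCO", model = "mp", config = tiny_config("mp"),
              loss = loss_config(alpha = 1),
              train = train_config(epochs = 0L), seed = 7)
  set.seed(7)
  build_vocab("CCO")  # consume the same RNG stream as molgen does
  P0 <- molgraphgen:::policy_init_params(m$config, nrow(m$vocab))
  expect_equal(m$params, P0, tolerance = 1e-15)
  expect_equal(nrow(m$trace), 0L)
})

test_that("training is deterministic at alpha = 1 under a fixed seed", {
  m1 <- molgen(c("CCO", "CCN"), model = "mp", config = tiny_config("mp"),
               loss = loss_config(alpha = 1),
               train = train_config(epochs = 10L, batch_size = 2L), seed = 3)
  m2 <- molgen(c("CCO", "CCN"), model = "mp", config = tiny_config("mp"),
               loss = loss_config(alpha = 1),
               train = train_config(epochs = 10L, batch_size = 2L), seed = 3)
  expect_identical(m1$trace$loss, m2$trace$loss)
  expect_equal(m1$params, m2$params, tolerance = 0)
})

test_that("a tiny model overfits a one-molecule corpus", {
  m <- fixture("overfit_cco",
    molgen("CCO", model = "rnn", config = tiny_config("rnn"),
           loss = loss_config(alpha = 1),
           train = train_config(epochs = 150L, batch_size = 1L,
                                lr = 0.005), seed = 2))
  expect_lt(tail(m$trace$loss, 1), head(m$trace$loss, 1) / 3)
  s <- simulate(m, nsim = 50, seed = 11)
  tab <- sort(table(s$smiles), decreasing = TRUE)
  expect_identical(names(tab)[1], "CCO")     # the corpus molecule is modal
})

test_that("simulate returns statuses consistent with its outputs", {
  m <- fixture("overfit_cco",
    molgen("CCO", model = "rnn", config = tiny_config("rnn"),
           loss = loss_config(alpha = 1),
           train = train_config(epochs = 150L, batch_size = 1L,
                                lr = 0.005), seed = 2))
  s <- simulate(m, nsim = 40, seed = 4)
  expect_true(all(s$status %in% c("ok", "invalid_chemistry", "step_cap")))
  expect_true(all(!is.na(s$smiles[s$status == "ok"])))
  expect_true(all(is.na(s$smiles[s$status != "ok"])))
  # a step cap of 2 permits single-atom outputs only
  s2 <- simulate(m, nsim = 20, seed = 5, gen = generation_config(max_steps = 2))
  expect_true(all(s2$n_atoms[s2$status == "ok"] == 1L))
})

test_that("sampled initial atoms follow the learned init distribution", {
  m <- fixture("overfit_cco",
    molgen("CCO", model = "rnn", config = tiny_config("rnn"),
           loss = loss_config(alpha = 1),
           train = train_config(epochs = 150L, batch_size = 1L,
                                lr = 0.005), seed = 2))
  p <- init_distribution(m)
  s <- simulate(m, nsim = 400, seed = 8, gen = generation_config(max_steps = 2))
  first <- vapply(attr(s, "graphs"), function(g)
    paste(g$atoms$symbol[1], g$atoms$nh[1], g$atoms$charge[1]), character(1))
  emp <- table(factor(first, levels = names(p))) / length(first)
  expect_lt(max(abs(as.numeric(emp) - as.numeric(p))),
            3 * sqrt(0.25 / 400) + 0.02)
})

test_that("fine-tuning shifts generation toward the sub-corpus", {
  base <- molgen(c("CCO", "CCN"), model = "rnn", config = tiny_config("rnn"),
                 loss = loss_config(alpha = 1),
                 train = train_config(epochs = 80L, batch_size = 2L,
                                      lr = 0.005), seed = 13)
  before <- simulate(base, nsim = 120, seed = 21)
  ft <- fine_tune(base, "CCN", train = fine_tune_config(epochs = 60L,
                                                        lr = 0.005),
                  seed = 14)
  after <- simulate(ft, nsim = 120, seed = 21)
  expect_gt(mean(after$smiles == "CCN", na.rm = TRUE),
            mean(before$smiles == "CCN", na.rm = TRUE))
  # degenerate fine-tuning inputs
  expect_error(fine_tune(base, character(0)))
  noop <- fine_tune(base, "CCN",
                    train = fine_tune_config(epochs = 0L), seed = 1)
  expect_equal(noop$params, base$params, tolerance = 0)
  # vocabulary mismatch is a typed error
  expect_error(fine_tune(base, "CCS", train = fine_tune_config(epochs = 1L)),
               class = "molgraphgen_vocab_error")
})

test_that("training with randomized routes (alpha < 1) optimizes the bound", {
  m <- molgen(c("CCO", "CCN"), model = "mp", config = tiny_config("mp"),
              loss = loss_config(alpha = 0.8, k = 2L),
              train = train_config(epochs = 25L, batch_size = 2L,
                                   lr = 0.01), seed = 19)
  expect_equal(nrow(m$trace), 25L)
  expect_true(all(is.finite(m$trace$loss)))
  expect_lt(mean(tail(m$trace$loss, 5)), mean(head(m$trace$loss, 5)))
})

test_that("checkpoints round trip and validate their vocabulary", {
  m <- fixture("overfit_cco",
    molgen("CCO", model = "rnn", config = tiny_config("rnn"),
           loss = loss_config(alpha = 1),
           train = train_config(epochs = 150L, batch_size = 1L,
                                lr = 0.005), seed = 2))
  path <- tempfile(fileext = ".rds")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  expect_equal(m2$params, m$params, tolerance = 0)
  expect_identical(simulate(m2, nsim = 5, seed = 3)$smiles,
                   simulate(m, nsim = 5, seed = 3)$smiles)
  # tampered vocabulary is rejected
  obj <- readRDS(path)
  obj$model$vocab$nh[1] <- obj$model$vocab$nh[1] + 1L
  saveRDS(obj, path)
  expect_error(read_checkpoint(path), "hash mismatch")
  expect_error(read_checkpoint(system.file("python", "props.py",
                                           package = "molgraphgen")))
})

test_that("model methods print, plot and score coherently", {
  m <- fixture("overfit_cco",
    molgen("CCO", model = "rnn", config = tiny_config("rnn"),
           loss = loss_config(alpha = 1),
           train = train_config(epochs = 150L, batch_size = 1L,
                                lr = 0.005), seed = 2))
  expect_output(print(m), "MolRNN")
  expect_output(print(summary(m)), "architecture")
  expect_type(coef(m), "list")
  ll <- logLik(m)
  expect_s3_class(ll, "logLik")
  expect_lt(as.numeric(ll), 0)
  pr <- predict(m, c("CCO", "CO"))
  expect_length(pr, 2L)
  expect_gt(pr[1], pr[2])   # the training molecule is more likely
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})
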