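# Shared helpers: desk-scale architectures, small corpora, and utilities
# used across test files. Everything is generated in code under fixed
# seeds; nothing is loaded from disk.

tiny_config <- function(model = "mp", cond = 0L, conv = c(8L, 12L),
                        D = 2L, rnn = 16L) {
  molgen_config(model = model, embed_dim = 6L, conv_widths = conv,
                receptive_field = D, fc_widths = c(10L, 12L),
                head_hidden = 8L, rnn_widths = rnn, cond_dim = cond)
}

# memoized expensive fixtures (per test run)
.fix_env <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (is.null(.fix_env[[name]])) .fix_env[[name]] <- force(expr)
  .fix_env[[name]]
}

small_corpus <- function() {
  c("CCO", "CC(=O)N", "c1ccccc1", "CCN", "CC(C)O", "C=O", "CCC", "CO")
}

small_vocab <- function() fixture("small_vocab", build_vocab(small_corpus()))

random_policy <- function(cfg, vocab, seed = 42L) {
  set.seed(seed)
  list(params = molgraphgen:::policy_init_params(cfg, nrow(vocab)),
       config = cfg, vocab = vocab)
}

# reorder atoms of a molgraph by a permutation (new_index = perm[old_index])
permute_molgraph <- function(g, perm) {
  inv <- order(perm)
  atoms <- g$atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- g$bonds
  if (nrow(bonds) > 0) {
    bonds$i <- perm[bonds$i]
    bonds$j <- perm[bonds$j]
  }
  molgraph(atoms, bonds,
           latest = if (is.na(g$latest)) NA_integer_ else perm[g$latest])
}

# total probability mass of a policy forward pass
policy_mass <- function(po) sum(exp(po$log_append)) + exp(po$log_term)
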