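# Shared fixtures, built in code. Expensive artifacts (simulations, trained
# models) are computed lazily once per test run and cached here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A minimal hand-written CSM data.frame with known TT/TD/DD structure.
toy_csms <- function() {
  data.frame(
    csm_id = paste0("c", 1:6),
    run_id = "r1", scan = 1:6,
    peptide_a = c("AKLR", "MKDE", "KFGY", "AKLR", "WKDS", "HKTE"),
    peptide_b = c("GKSE", "LKPR", "DKAW", "GKSE", "YKQN", "FKLM"),
    link_pos_a = c(2L, 2L, 1L, 2L, 2L, 2L),
    link_pos_b = c(2L, 2L, 2L, 2L, 2L, 2L),
    charge = c(3L, 4L, 3L, 4L, 5L, 3L),
    score = c(20, 18, 15, 12, 8, 5),
    is_target_a = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    is_target_b = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    is_entrapment_a = FALSE, is_entrapment_b = FALSE,
    proteins_a = c("P1", "P2", "P3", "P1", "P4", "P5"),
    proteins_b = c("P1", "P3", "P4", "P1", "P5", "P6"),
    link_class = c("self", "heteromeric", "heteromeric", "self",
                   "heteromeric", "heteromeric"),
    scx_fraction = c(3L, 5L, 2L, 7L, 4L, 9L),
    hsax_fraction = c(2L, 8L, 4L, 6L, 10L, 1L),
    rp_rt = c(35.2, 60.1, 48.7, 72.3, 55.0, 40.4),
    stringsAsFactors = FALSE
  )
}

# Small simulated dataset for structural tests (fast).
sim_small <- function() {
  cached("sim_small", {
    cfg <- simConfig(n_csms = 600L, n_proteins = 20L,
                     n_entrapment_proteins = 10L, seed = 101L)
    sim <- simulateCsms(simulateProteins(cfg), defaultRetentionModel(), cfg)
    sim
  })
}

# A tiny trained model on a slice of the small simulation: enough to exercise
# prediction paths, far too small to be accurate.
tiny_model <- function() {
  cached("tiny_model", {
    sim <- sim_small()
    df <- csmData(sim$csms)
    conf <- df[tdClass(sim$csms) == "TT", ][1:120, ]
    alpha <- sim_alphabet(df)
    cfg <- rtModelConfig(max_len = 40L, embedding_dim = 8L,
                         recurrent_units = 8L, subnet_layer_sizes = c(8L, 4L),
                         epochs = 3L, batch_size = 64L, seed = 3L)
    m <- buildModel(cfg, alpha)
    fitModel(m, conf[1:100, ], conf[101:120, ])
  })
}

# Alphabet covering all tokens (incl. link-site variants) of a CSM table.
sim_alphabet <- function(df) {
  toks <- lapply(seq_len(nrow(df)), function(i) {
    c(parsePeptide(df$peptide_a[i], c("ox", "cm"), df$link_pos_a[i]),
      if (nzchar(df$peptide_b[i]))
        parsePeptide(df$peptide_b[i], c("ox", "cm"), df$link_pos_b[i]))
  })
  buildAlphabet(toks)
}

# Full-scale run backing the recovery/calibration checks: 5000 CSMs with the
# default generator conditions, 3-fold CV training, leak-free features and
# SVM rescoring. Built once and shared.
acceptance_run <- function() {
  cached("acceptance_run", {
    cfg <- simConfig(seed = 2024L)
    sim <- simulateCsms(simulateProteins(cfg), defaultRetentionModel(), cfg)
    mcfg <- rtModelConfig(epochs = 40L, seed = 2024L)
    cv <- runCv(sim$csms, mcfg, fdr_cutoff = 0.01, k = 3L, seed = 2024L)
    tri <- cvTriplets(cv, sim$csms)
    fm <- featureMatrix(sim$csms, tri)
    rs <- rescoreCsms(sim$csms, fm, k = 3L, fdr_cutoff = 0.01, seed = 2024L)
    list(sim = sim, cv = cv, tri = tri, features = fm, rescored = rs)
  })
}

# Accepted-TT bookkeeping at a q-value threshold, joined with hidden truth.
accepted_tt <- function(csms, truth, scores = NULL, alpha = 0.05) {
  df <- csmData(csms)
  q <- csmQValues(csms, scores)
  tt <- tdClass(csms) == "TT"
  acc <- which(tt & q <= alpha)
  ti <- match(df$csm_id[acc], truth$csm_id)
  list(
    n = length(acc),
    n_true = sum(truth$is_true[ti]),
    false_prop = mean(!truth$is_true[ti]),
    ent_frac = mean(df$is_entrapment_a[acc] | df$is_entrapment_b[acc]),
    rows = acc
  )
}
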